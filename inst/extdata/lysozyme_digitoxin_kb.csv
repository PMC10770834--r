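# Published binding constants for the lysozyme-digitoxin system from
# double-reciprocal fluorescence fits (Kb in M^-1, temperature in K).
temperature_k,kb
298.15,3.1e4
308.15,3.3e4
318.15,3.6e4
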