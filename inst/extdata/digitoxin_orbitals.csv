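# Published B3LYP frontier-orbital energies (eV) of digitoxin, free and in
# the three docked lysozyme-bound conformers.
label,e_homo,e_lumo
free,-6.507,-0.933
conformer_1,-6.41,-0.911
conformer_2,-6.541,-0.85
conformer_3,-6.509,-1.36
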