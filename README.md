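# bindscope

Quantitative analysis of spectroscopic protein–ligand binding studies,
built around the lysozyme–digitoxin system: binding constants from
fluorescence enhancement titrations, Van 't Hoff thermodynamics with a
sign-based classification of the dominant forces, conceptual-DFT
frontier-orbital reactivity descriptors, geometric protein–ligand contact
profiling from PDB coordinates, and from-scratch molecular-dynamics
trajectory summary statistics. A synthetic-data module generates
titrations, trajectories and complexes with known ground truth, so every
estimator in the chain can be validated end to end without any external
download.

It is aimed at biophysical chemists who run ligand-binding titrations and
companion docking/MD analyses and want the whole numerical chain — from raw
emission spectra to a thermodynamic table — in one scriptable, testable
place.

## The models

**Binding constant.** For 1:1 association with fluorescence enhancement,
the intensity change ΔF = F − F₀ at the analysis wavelength (340 nm for
tryptophan emission) follows the hyperbola ΔF = ΔFmax·Kb·[L]/(1 + Kb·[L]).
Its double-reciprocal (Benesi–Hildebrand-type) linearization

    1/ΔF = 1/ΔFmax + 1/(Kb·[L]) · 1/ΔFmax

is fit by ordinary least squares; Kb = intercept/slope and
ΔFmax = 1/intercept. A direct nonlinear hyperbolic fit is available as a
labelled alternative (`fit_hyperbolic()`).

**Thermodynamics.** Binding constants at several temperatures enter the
Van 't Hoff regression ln Kb = −ΔH/(RT) + ΔS/R, with ΔG(T) = ΔH − TΔS
(and −RT·ln Kb kept as a cross-check). Signs classify the dominant forces:
ΔH > 0, ΔS > 0 → hydrophobic; both negative → hydrogen bonding/van der
Waals; |ΔH| ≈ 0 with ΔS > 0 → electrostatic.

**Reactivity descriptors.** From HOMO/LUMO energies (eV):
ΔE = E_LUMO − E_HOMO, µ = (E_LUMO + E_HOMO)/2, η = ΔE/2, I = −E_HOMO,
A = −E_LUMO, χ = (I + A)/2, ω = µ²/(2η).

**Structure and dynamics.** Hydrogen bonds (donor–acceptor ≤ 3.5 Å,
H–D–A ≤ 30° when hydrogens are explicit) and hydrophobic C–C contacts
(≤ 4.0 Å) per residue; Kabsch SVD superposition; RMSD/RMSF (two-pass
average-structure reference); mass-weighted radius of gyration;
Shrake–Rupley SASA on a deterministic golden-spiral point sphere;
essential-dynamics covariance trace and leading modes. Summaries are
reported in nm / nm², matching MD convention.

## Worked example

```r
library(bindscope)

# Thermodynamics from measured binding constants (K -> M^-1)
th <- vant_hoff(c("298.15" = 3.1e4, "308.15" = 3.3e4, "318.15" = 3.6e4))
print(th)
#> thermo_result: dH = 5.9 kJ/mol, dS = 105.7 J/(mol K), forces: hydrophobic
#>   T = 298.15 K: Kb = 3.1e+04 M^-1, dG = -25.6 kJ/mol (direct -25.6)
#>   T = 308.15 K: Kb = 3.3e+04 M^-1, dG = -26.7 kJ/mol (direct -26.7)
#>   T = 318.15 K: Kb = 3.6e+04 M^-1, dG = -27.7 kJ/mol (direct -27.8)
```

Positive ΔH and ΔS mark hydrophobic association; the negative ΔG values
say binding is spontaneous at all three temperatures and strengthens on
heating.

```r
# Frontier-orbital descriptors of free digitoxin
compute_descriptors(orbital_energies(-6.507, -0.933, "free digitoxin"))
#> fmo_descriptors [free digitoxin]: gap 5.574 eV, mu -3.72, eta 2.787,
#>   chi 3.72, omega 2.482669537

# A synthetic complex with known planted contacts, profiled per residue
gc <- generate_complex(n_hbonds = 2, n_hydrophobic = 3, seed = 7)
interaction_summary(gc$structure)
#> contact_profile: 2 hydrogen bonds, 3 hydrophobic contacts
#>   chain residue_number residue_name n_hbond n_hydrophobic
#> 1     A              1          GLY       1             0
#> 2     A              2          GLY       1             0
#> 3     A              3          ALA       0             1
#> 4     A              4          ALA       0             1
#> 5     A              5          ALA       0             1

# A noisy synthetic titration, fit back at 340 nm
g <- generate_titration(titration_design(noise_cv = 0.01, seed = 11))
fit_double_reciprocal(delta_f_series(g$series[["298.15"]]), 340, 298.15)
#> binding_fit: Kb = 4.185e+04 M^-1, dFmax = 1063 a.u., R2 = 0.9983
#>   (n = 10, 340 nm, 298.15 K)
```

The last fit illustrates a real property of the double-reciprocal
estimator: even with R² = 0.998, 1% intensity noise moves Kb by tens of
percent, because the reciprocal transform amplifies noise at low ligand
concentrations (see the methods vignette).

End-to-end runs over files go through `run_config()` plus
`run_binding_pipeline()`, `run_fmo_pipeline()` and
`run_trajectory_pipeline()`, which write diff-able tab-separated reports
with a provenance header (seed, package version, config hash).

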