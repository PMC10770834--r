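---
title: "Methods and design choices in bindscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in bindscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindscope)
```

bindscope implements the numerical chain of a fluorescence-based
protein–ligand binding study — the lysozyme–digitoxin system is its
motivating case — together with companion structure and
molecular-dynamics summary analyses. This vignette explains the models,
the assumptions behind them, the tunable parameters, and the places where
a design choice was genuinely open and a decision had to be made.

## The binding model and its assumptions

Fluorescence enhancement titrations are modelled as 1:1 association: the
intensity change at the analysis wavelength follows
$\Delta F(c) = \Delta F_{max} K_b c / (1 + K_b c)$ where $c$ is the free
ligand concentration. Two assumptions matter:

* **Free ≈ total ligand.** The double-reciprocal linearization treats the
  total added ligand as the free concentration. This is accurate when the
  protein concentration is well below $1/K_b$ (here $1/K_b \approx 30$ µM,
  so low-micromolar protein already bends the isotherm). Because typical
  titration protocols do not always report the protein concentration, the
  approximation is adopted without a stated validity bound; the synthetic
  generator offers a labelled mass-balance variant
  (`generate_titration(..., mass_balance = TRUE)`) to quantify the bias
  for any assumed protein concentration.
* **Single-site binding, no quenching corrections.** The system shows
  enhancement, not quenching, so no Stern–Volmer analysis or inner-filter
  correction is applied (the ligand does not absorb at the 295 nm
  excitation).

The default fit is **unweighted ordinary least squares in reciprocal
space** ($1/\Delta F$ on $1/c$), matching how such plots are drawn and
reported in practice. This choice is deliberate and has a known cost:
reciprocal transformation amplifies the noise of the smallest
$\Delta F$ values (lowest concentrations), which carry the largest
leverage in $1/c$. A direct hyperbolic `fit_hyperbolic()` is provided as a
clearly labelled alternative; it is never the default because the
reciprocal fit is the field's reporting convention. Pairs with
$\Delta F \le 0$ cannot enter a reciprocal fit and are excluded (and
returned in an attribute) rather than treated as errors; at least three
positive pairs are required.

The analysis wavelength defaults to 340 nm — tryptophan emission, the
convention for lysozyme — but is a parameter, since other systems read at
other wavelengths. Temperatures given in Celsius are converted as
K = °C + 273.15. Intensity lookup between grid points is linear
interpolation with no smoothing: nothing in a generic titration licenses
a band-shape model, and smoothing would correlate noise across
concentrations.

## Van 't Hoff analysis

$\ln K_b$ is regressed on $1/T$; $\Delta H = -R\,\mathrm{slope}$,
$\Delta S = R\,\mathrm{intercept}$, with $R = 8.314$ J mol⁻¹ K⁻¹ exactly.
$\Delta G(T) = \Delta H - T\Delta S$ is the reported route;
$-RT\ln K_b$ is kept per temperature as a cross-check column (the two
differ only by regression residuals). Energies are joules internally and
kilojoules per mole in reports, with one decimal.

Two numerical caveats are worth knowing. First, $\Delta H$ is sensitive to
rounding of the input binding constants: constants printed to two
significant figures can move the slope by several percent while barely
affecting $\Delta S$ or $\Delta G$. Second, with only three temperatures
the regression $R^2$ says little about model adequacy; it is reported (to
four decimals) but should not be over-read.

The force classification follows the standard thermodynamic sign
convention: both $\Delta H$ and $\Delta S$ positive → hydrophobic; both
negative → hydrogen bonding / van der Waals; $|\Delta H|$ below a
threshold with $\Delta S > 0$ → electrostatic. The threshold is 1000 J/mol
(a "near-zero enthalpy" scale, settable); the electrostatic rule is
checked first so that a tiny positive enthalpy with positive entropy is
not over-claimed as hydrophobic. Everything else is `indeterminate`.

## Frontier-orbital descriptors

`compute_descriptors()` evaluates the conceptual-DFT identities exactly as
defined — $\Delta E = E_{LUMO} - E_{HOMO}$, $\mu = (E_{LUMO}+E_{HOMO})/2$,
$\eta = \Delta E/2$, $I = -E_{HOMO}$, $A = -E_{LUMO}$, $\chi = (I+A)/2$,
$\omega = \mu^2/(2\eta)$ — on energies taken in eV as given, with no unit
conversion and no sign reinterpretation. A degenerate pair
($E_{HOMO} = E_{LUMO}$) has zero hardness and an undefined
electrophilicity, and raises an error rather than returning infinity.

## Contact profiling

Hydrogen bonds use the common MD-analysis geometry: heavy-atom
donor–acceptor distance ≤ 3.5 Å between protein N/O/S and ligand N/O.
When explicit hydrogens are present on a candidate partner, that partner
must donate with an H–D–A angle ≤ 30°; structures without hydrogens (the
usual docking output) are judged on distance alone. Hydrophobic contacts
are protein-carbon/ligand-carbon pairs ≤ 4.0 Å; all carbons count. Both
cutoffs are parameters.

The counting convention is **one atom pair = one interaction**, with no
clustering into residue-level "interactions". Visualizer-style engines
that type and merge interactions use unstated conventions, so per-residue
tallies from different tools agree qualitatively (which residues dominate)
rather than exactly. Waters (HOH) are excluded everywhere; HETATM records
otherwise define the ligand set.

## Trajectory observables

All coordinate math is in Å internally; summary units are nm and nm²
(fixed ÷10 / ÷100), the MD reporting convention.

* **Superposition** is Kabsch SVD with determinant sign correction.
  Collinear or two-point selections leave a rotation axis unconstrained;
  the implementation falls back to identity rotation of the centered sets
  (the RMSD is still well defined) instead of failing on a harmless
  degeneracy, and errors only below two selected atoms.
* **RMSD** defaults to backbone atoms when present, else all atoms;
  reference is the first frame unless given.
* **RMSF** uses the two-pass average-structure reference: fit all frames
  to frame 1, average, re-fit to the average, then take per-atom RMS
  deviations from the final average. This matches the behaviour of the
  standard MD tools. Default selection: alpha carbons. Note the fit
  itself absorbs roughly $1/N$ of a single atom's variance, so planted
  amplitudes are recovered slightly low on very small toys.
* **Radius of gyration** is mass-weighted, with masses from an element
  table (H 1.008, C 12.011, N 14.007, O 15.999, S 32.06, P 30.974, …);
  unknown elements are an error, not a silent default.
* **SASA** is Shrake–Rupley with a deterministic golden-spiral sphere of
  960 points per atom (parameter), probe 1.4 Å, radii C 1.70 / N 1.55 /
  O 1.52 / S 1.80 / H 1.20 / P 1.80 Å (overridable). Neighbour search uses
  cell lists, so cost is linear in atoms for compact structures. Two
  numerical consequences: a single atom's area is exact to one
  point-quantum ($4\pi r^2/n$), and the point set is axis-anchored, so
  SASA of a rigidly rotated frame agrees only to the point-set
  quantization (~0.1% at 960 points), not to machine precision.
* **Hydrogen-bond series** applies the contact-profiling criteria between
  two disjoint atom groups per frame.
* **Essential dynamics** builds the $3N \times 3N$ covariance of
  superposed selected coordinates (sample covariance over frames), and
  returns its trace — the total positional variance, an overall mobility
  index — plus sorted eigenvalues and projections on the two leading
  modes. Alpha carbons are the default selection; whether heavier
  selections are wanted is system-dependent, so it is a parameter.

Trajectory input is multi-model PDB or per-frame XYZ text; binary formats
are deliberately out of scope to keep the readers auditable.

## The synthetic-data generators

The generators exist so that every estimator can be scored against known
ground truth:

* `generate_titration()` draws emission spectra on a 300–500 nm grid as a
  Gaussian band (centre 340 nm, width 25 nm) whose peak is
  $F_0 + \Delta F(c)$, with $K_b(T)$ from a chosen $(\Delta H, \Delta S)$
  — defaults 5600 J/mol and 104.8 J/(mol K), which put $K_b$(298.15 K)
  near $3.1\times10^4$ M⁻¹ — over the standard design 0–50 µM in 5 µM
  steps at 25/35/45 °C. Noise is multiplicative Gaussian on every
  intensity (fluorescence noise scales with signal), CV 1% by default.
  The free amplitude scale (baseline 1000 a.u., saturation change
  1200 a.u.) was set once so that double-reciprocal fits of generated
  noisy data show $R^2 \approx 0.995$, the fit quality typical of
  well-behaved real titrations at these conditions.
* `generate_trajectory()` displaces each atom independently per frame by
  a Gaussian with its residue's per-axis amplitude, then applies a random
  rigid-body jitter; the closed-form expected RMSF for a well-anchored
  atom is $\sqrt{3}\,a/10$ nm for per-axis amplitude $a$ in Å.
* `generate_complex()` plants exact hydrogen-bond (2.8–3.2 Å) and
  hydrophobic (3.5–3.9 Å) pairs on minimal single-atom pseudo-residues
  spaced 10 Å apart, with every non-planted protein–ligand distance above
  4.5 Å, so contact precision/recall can be asserted exactly. The
  scaffold is deliberately synthetic — it is a geometric test object, not
  a protein model.

All generators are reproducible from an integer seed
(`withr::with_seed`), and each returns its ground truth alongside the
data.

**What passing tests on synthetic data do and do not show.** The
generators emulate the *statistical* structure the estimators assume:
hyperbolic binding with signal-scaled noise, Gaussian positional
fluctuations, clean planted geometry. Real data add baseline drift,
correlated spectral noise, anharmonic and correlated motions, protonation
ambiguity and force-field error. Recovery on synthetic data therefore
validates the estimators' correctness, not the experimental accuracy of
any particular study.

**A noise-sensitivity fact worth stating plainly:** with 1% multiplicative
noise on intensities, the noise on $\Delta F = F - F_0$ is an absolute
~1.4% of the *total* intensity, which at low concentrations is a large
fraction of $\Delta F$ itself. The unweighted reciprocal fit then shows
median $K_b$ errors on the order of 10% even when $R^2$ exceeds 0.99 —
an inherent property of the double-reciprocal estimator, not an
implementation artefact. Only when the noise scales with $\Delta F$
itself (~1%) does the estimator recover $K_b$ to a few percent. Users who
need tighter recovery at realistic intensity noise should use the
hyperbolic fit and/or replicate titrations.

## Validation problem sizes

The shipped test-suite exercises the chain at sizes chosen to make the
oracles exact and the runs quick: titrations of 11 concentrations at
three temperatures (200 noisy replicates for recovery statistics), helical
toys of 10–80 alpha carbons, trajectories of 8–400 frames, SASA
convergence on a 50-atom toy at 960 vs 3840 sphere points, and
brute-force rotation-grid Kabsch oracles on 4–5-atom toys (golden-spiral
axis grid × 2° angle grid). Pipeline reports embed the seed, package
version and a configuration hash, and re-running the same configuration
byte-reproduces them.

## Known limitations

* No inner-filter or dilution corrections; no multi-site or cooperative
  binding models.
* Contact typing is geometric only — no π-stacking, halogen-bond or
  salt-bridge classes, and no protonation-state assignment.
* The PDB reader covers ATOM/HETATM/MODEL/ENDMDL with standard fixed
  columns; exotic records (altloc ensembles, insertion codes) are not
  modelled.
* SASA treats all atoms as spheres with element radii; no united-atom or
  per-residue parameter sets.
* Secondary-structure assignment and any free-energy estimation are out
  of scope.
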