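---
title: "Phase solubility, stability constants and trajectory descriptors for host-guest inclusion complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase solubility, stability constants and trajectory descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostguest)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind them, the tunable parameters, what the
synthetic generators do and do not emulate, and the numerical choices made
where the design was genuinely open.

## 1. The system and the problem

Cyclodextrins are cyclic oligosaccharides with a hydrophobic cavity and a
hydrophilic exterior. A poorly water-soluble guest (here a flavonoid) can
occupy that cavity, forming a non-covalent 1:1 inclusion complex that
dramatically improves apparent solubility. Two questions drive the
analysis: *how strongly* does each host bind the guest (the stability
constant), and *why* (hydrogen bonding, van der Waals contacts, cohesive
compatibility) — the first answered from bench UV data, the second from
molecular-dynamics trajectories.

## 2. Phase-solubility model

### Calibration

`fit_calibration()` fits the Beer-Lambert line `A = m C + b` by unweighted
ordinary least squares. `r_squared` is the squared Pearson correlation.
The model assumes the instrument response is linear over the measured
range and that errors sit on the absorbance, not the concentration — which
is why absorbance is the response variable.

A note on the reference data shipped with the package
(`study_table("calibration")`): the fitted slope and intercept agree with
the published standard-curve equation to all printed digits, but the
published correlation coefficient (0.9833) does not follow from the eight
printed points; a closed-form OLS/Pearson computation gives 0.98569. The
package (and its tests) report the value the data imply and make no
attempt to force-match the printed one.

### Isotherm and stability constant

`fit_isotherm()` inverts the calibration
(`C = d (A - b)/m`, `d` the dilution factor, default 1), then OLS-fits
solubility against host concentration **with both axes in mM**, so the
slope `K` is dimensionless. For an AL-type (linear) diagram with
`0 < K < 1`, the 1:1 stability constant is

$$K_s = \frac{K}{S_0\,(1-K)} \qquad [\mathrm{M}^{-1}]$$

Unit discipline: concentrations are carried in mM everywhere; the single
mM-to-M conversion (factor $10^{-3}$) happens at the `stability_constant()`
boundary, which expects `S0` in mol/L.

Deliberate choices, each of which was genuinely open:

* **S0 from the fitted intercept**, not from the measured zero-host point.
  The zero-host point stays in the fit; only the intercept enters $K_s$.
  With the packaged tables this choice reproduces the published
  $K_s(\beta\text{-CD}) = 275.5\ \mathrm{M}^{-1}$ exactly; the published
  values for the two derivatised hosts (442.5, 1012.4) are *not* derivable
  from the printed absorbances by any least-squares variant we tried
  (the data give ≈ 444.1 and ≈ 1085.7, most plausibly an intermediate-
  rounding artefact upstream), so only the stability ordering
  DM > HP > β is asserted for them.
* **AL classification threshold**: the source asserts linearity without a
  criterion; the package calls a diagram AL when the isotherm fit has
  `r² >= 0.95` (tunable via `al_r2`). Slopes outside `(0, 1)` are a hard
  error ("not AL"): a slope ≥ 1 makes the 1:1 model degenerate.
* **Negative computed solubilities are retained** (with a warning), not
  clipped: clipping would bias the fit low at small host concentrations.
* **Unweighted OLS** throughout — the experimental design gives no
  replicate variances to weight by.

## 3. Trajectory descriptors

The data model (`md_frame` / `md_trajectory`) stores coordinates exactly
as given, possibly outside the box; wrapping happens only inside distance
computations. This matters because MSD must see *unwrapped* coordinates,
while RDF and hydrogen-bond distances must see *minimum-image* ones. Cells
are orthorhombic only (the studied systems use cubic cells); 0-based atom
indices are used in records, and the native CSV dialect exists because
XYZ/PDB cannot carry partial charges, molecule ids, roles or class labels.

### Mean square displacement

$\mathrm{MSD}(t) = \langle |r_i(t) - r_i(0)|^2 \rangle$. The default uses
every admissible time origin (better statistics; the estimates are
correlated but unbiased), while `origins = "single"` matches the textbook
definition literally with frame 0 as the origin. A consecutive-frame jump
larger than half a cell edge triggers a wrapped-coordinates warning rather
than silently producing a corrupted curve. `estimate_diffusion()` applies
the 3-D Einstein relation `D = slope/6` over a user-chosen lag window;
with Brownian fixtures, lags 10–100 ps avoid both the zero-lag trivial
point and the noisy long-lag tail.

### Radial distribution function

$$g(r) = \frac{dN}{N_\mathrm{ref}\,\rho\,4\pi r^2\,dr}$$

Half-open bins `[r, r + dr)` with `dr = 0.1` Å by default, bin centers
reported, `r_max` capped at half the smallest cell edge (the minimum-image
validity limit). The per-reference-atom normalisation is included even
though the source's printed formula omits it — without it the ideal-gas
limit is not 1, which the interpretation of the curves assumes. Every
frame is weighted equally (all fixture volumes are constant). Peak
positions map to interaction bands: 2.5–3.0 Å hydrogen bonds, 3.0–5.0 Å
strong van der Waals, ≥ 5.0 Å weak van der Waals. Distances below 2.5 Å
fall outside the published bands; `classify_interaction()` reports them as
hydrogen bonds with an "unusually short" warning rather than inventing a
fourth class.

### Hydrogen bonds

The source quantifies hydrogen bonding only through the RDF band, so the
detector's geometric criteria are package choices: H···A ≤ 3.0 Å (the
upper edge of the hydrogen-bond band), D–H···A angle ≥ 120° at the
hydrogen, O donors and acceptors, covalent D–H assignment within 1.2 Å —
all configurable via `hbond_criteria()`. Records carry an
intra/intermolecular flag from `molecule_id`. Over a trajectory,
`count_hbonds()` reports mean ± sd per frame and rounds the mean to the
nearest integer before the concentration formula

$$C_\mathrm{HBs} = \frac{N_\mathrm{HBs}}{N_A V}, \qquad
N_A = 6.02214076\times10^{23}\ \mathrm{mol}^{-1},\ V\ \text{in cm}^3.$$

The published per-system concentration table is internally inconsistent
with this arithmetic (143 bonds in a 19.2 Å cube gives ≈ 3.4 × 10⁻²
mol/cm³, one order of magnitude off the printed value, and the printed
ordering contradicts the accompanying prose). The package therefore
validates the equation against hand arithmetic only and does not assert
those table values anywhere.

### Hydrogen-bond typing

`enumerate_hbond_types()` crosses guest acceptor classes with host
donor-hydrogen classes, then host acceptors with guest donor hydrogens,
labelling types A, B, C, … in that order — the ordering is chosen so the
packaged charge-class table reproduces the published eight-type catalogue
(A:O1–H2 … H:O8–H1) exactly. `rdf_per_type()` produces one curve per type
(the waterfall view); classes absent from a given system yield a flat zero
curve rather than an error.

## 4. Energetics

* `binding_energy()`: $E_\mathrm{bind} = -(E_\mathrm{total} -
  E_\mathrm{guest} - E_\mathrm{host})$, positive favourable. The published
  practice of averaging the last frames of an equilibrated run generalises
  to a configurable trailing window (`binding_energy_from_table()`,
  default 5 frames).
* `pairwise_energy()`: 12-6 Lennard-Jones plus Coulomb
  (k = 332.0637 kcal·Å/(mol·e²)), Lorentz-Berthelot mixing, 12 Å cutoff,
  no tail corrections. This is an explicitly *toy* stand-in for the
  commercial force field used upstream: it exists so that binding-energy
  identities can be tested exactly on pairwise-additive synthetic systems,
  not to reproduce published magnitudes (which depend on an unshared force
  field and trajectories, and are excluded from all assertions).
* `solubility_parameter()`: $\delta = \sqrt{\Delta E / V}$, with the
  alternative input path $\Delta E = \Delta H - RT$
  (R = 1.9872 cal/(mol·K)). Cohesive energy must be non-negative under the
  convention $\Delta E = E_\mathrm{isolated} - E_\mathrm{bulk}$.
* `compatibility()`: the published rules cover |δA − δB| < 1.0
  (compatible), 1.0–3.4 (may be compatible) and > 4.9 (incompatible),
  leaving (3.4, 4.9] unassigned. The package introduces an explicit
  `indeterminate` category for the gap instead of silently extending a
  neighbour; boundary values 1.0 and 3.4 fall into `may_be_compatible`
  and 4.9 into `indeterminate` (the published inequalities are strict).
  The absolute difference is used: the rule text is signed but the
  accompanying table reports positive differences.

## 5. What the synthetic generators emulate — and what they don't

Each generator is a pure function of its parameters and a seed (the
caller's RNG stream is saved and restored), so every analysis can be
checked against known ground truth:

* `simulate_isotherm()` inverts the 1:1 model
  ($K = K_s S_0/(1 + K_s S_0)$) and emulates the bench design: host grid
  0–10 mM in 2 mM steps, calibration 0.02–0.09 mM, the published
  standard-curve coefficients, and 1% *multiplicative* Gaussian noise on
  absorbance (instrument-like relative error; additive concentration noise
  would misrepresent a spectrophotometer).
* `brownian_trajectory()` draws independent Gaussian steps of variance
  `2 D dt` per axis — exactly the process for which MSD = 6Dt.
* `ideal_gas_frames()` is the structureless g(r) ≡ 1 reference.
* `hbond_fixture()` places a known number of valid O–H···O triples
  (H···A ∈ [1.8, 2.9] Å, angle ∈ [150°, 180°]) plus decoys violating
  distance or angle, on a jittered grid with ≥ 12 Å spacing so no
  accidental cross-group bond can form even across periodic boundaries;
  the box must be large enough or generation refuses.
* `two_cluster_system()` returns exact per-component energies by direct
  summation, so the binding-energy identity
  $E_\mathrm{bind} = -E_\mathrm{cross}$ can be asserted to $10^{-8}$
  relative.

What they do **not** emulate: real cyclodextrin geometry, conformational
sampling, solvent, thermostats, or any published force field. A green test
therefore establishes that the *analysis chain* is correct on data whose
truth is known — not that the upstream simulations were.

## 6. Numerical choices and degenerate inputs

* OLS fits run through `stats::lm`; tests cross-check against the
  closed-form sum formulas to $10^{-10}$.
* `r_max` beyond half the smallest cell edge, empty selections, open cells
  where a volume is needed, zero-distance atom pairs, slopes outside
  `(0, 1)`, non-increasing frame times and truncated files are all hard
  errors with messages naming the offending quantity.
* Ties in `rank_by_ks()` keep input order (stable sort by construction).
* RDF histograms use only whole bins (`r_max` is truncated down to a
  multiple of `dr`) so no partially covered bin biases the tail.
* The suite keeps the large property-based checks at the sizes stated
  above (500 × 1000 Brownian, 1000-atom/50-frame ideal gas, 100 detector
  fixtures, 200 isotherm seeds); the whole run takes well under a minute
  on one CPU.

## 7. Known limitations

* Only AL-type (1:1, linear) phase-solubility diagrams are modelled; AP/AN
  curvature, Job plots and higher-order complexes are out of scope.
* Orthorhombic cells only; no triclinic minimum image.
* The hydrogen-bond detector is geometric; no energetic or
  lifetime/autocorrelation criteria.
* The nonbonded model is a toy; binding-energy *magnitudes* from it have
  no physical claim to match any published table.
* The study runner (`run_study()`) orchestrates the stages on files and
  returns a JSON/Markdown report; it deliberately does no plotting beyond
  the per-object `plot()` methods.
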