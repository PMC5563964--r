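---
title: "Quantifying single-cell methane assimilation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell methane assimilation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipquant)
```

## The measurement chain

`sipquant` implements the quantification chain used to attribute bulk
methane consumption in stratified lakes to individual methanotroph
populations. A water sample is incubated with ^13^C-labelled methane;
cells that assimilate methane-derived carbon become enriched in ^13^C.
Three measurements are combined:

1. **Single-cell isotope imaging** (nanoSIMS): per-pixel secondary-ion
   count images for the masses ^12^C, ^13^C and ^32^S, acquired as repeated
   planes over the same field. Regions of interest (ROIs) drawn around
   individual cells yield a ^13^C/^12^C ratio and an atom percent per cell.
2. **FISH morphometry**: lengths, widths and counts of probe-hybridized
   filaments on the same filters give average biovolumes and cell densities.
3. **Bulk tracer chemistry**: the ^13^C atom percent of the dissolved
   inorganic carbon (DIC) pool over time gives whole-community methane
   oxidation rates, and headspace equilibration gives dissolved CH~4~.

The chain converts (1) and (2) into a per-cell and then population-level
methane-carbon uptake rate, which can be compared with (3).

## Ion images and counting statistics

Each acquisition plane is modelled as independent Poisson counts per pixel.
For carbon, a local expected total count density $D$ (counts px^-1^
plane^-1^) splits between isotopes by the local true ^13^C atom fraction
$f$: $N_{13}\sim\mathrm{Pois}(Df)$, $N_{12}\sim\mathrm{Pois}(D(1-f))$.
Sulphur (^32^S) follows the cell's own density and is essentially absent on
cell-free filter, which makes it the structure-rich channel used for
alignment.

Stage drift between planes is corrected by integer-pixel translation:
each plane's corrective shift maximizes the Pearson cross-correlation
against a reference plane, searched exhaustively within a configurable
window (`align_planes()`, default ±10 px). Ties prefer the smallest shift,
so featureless planes stay put. Pixels translated out of frame become `NA`
and are excluded from all sums; sub-pixel drift is out of scope. Planes are
then summed per pixel (`accumulate()`).

For an ROI with accumulated counts $N_{13}$ and $N_{12}$:

$$R = \frac{N_{13}}{N_{12}}, \qquad
  \mathrm{at\%} = 100\,\frac{N_{13}}{N_{12}+N_{13}} = 100\,\frac{R}{1+R},$$

with the counting-statistics standard error from Poisson propagation on the
two sums,

$$\mathrm{SE(at\%)} = 100\sqrt{\frac{N_{13}N_{12}}{(N_{13}+N_{12})^3}},$$

which scales as $1/\sqrt{N}$: doubling the plane count shrinks the SE by
$\sqrt2$. The at% ↔ ratio mapping is exactly invertible and tested to
machine precision.

Two screening rules follow the reported practice:

* **Background comparison** (`evaluate_background()`): the cell-free filter
  in the same field is measured as its own ROI; a cell is called enriched
  when its at% exceeds the pooled background at% by more than $k$ pooled
  standard errors. The reported analysis compared cells against background
  without stating a rule; we adopt the conventional $k = 3$ detection
  threshold and make it configurable.
* **Ratio floor** (`apply_ratio_floor()`): ROIs with $R <$ 0.015 are
  excluded before cohort statistics, mirroring the reported exclusion of
  three weakly labelled filaments from one cohort of 13. The floor is
  applied after accumulation, is idempotent, and the exclusion count is
  recorded.

Cohort enrichment is reported as the arithmetic mean ± sample s.d.
(n − 1 denominator) of per-ROI at% (`summarize_population_atpct()`).
Detector effects (dead time, quasi-simultaneous arrival, charging) are not
modelled; the synthetic data contain none, and measured data should be
corrected upstream. at% values are used raw, without background
subtraction, which matches the magnitudes of the reported per-population
values.

## Morphometry and biovolume

Filaments are treated as cylinders, $V = \pi(w/2)^2 L$, with the measured
width $w$ as the **diameter**. This convention is deliberate: a ca.
45 × 1.5 µm filament gives 79.5 µm³, consistent with reported average
filament biovolumes of 70–90 µm³, whereas reading the width as a radius
would inflate volumes fourfold. Unicellular methanotrophs are spheres,
$V = \pi d^3/6$, with the conventional 2 µm diameter giving 4.19 µm³.
Counts per ml use standard epifluorescence upscaling (mean count per field
of view × filter/FOV area ratio ÷ volume filtered), and the total
population biovolume is the product of average biovolume and density.
Counts refer to start-of-incubation abundances; no growth correction is
applied.

## From enrichment to uptake

With natural ^13^C abundance $a_{nat}$ (default 1.11 at%; configurable, as
the reported analysis does not print its value), the atom percent excess is
$E = \max(\mathrm{at\%} - a_{nat}, 0)$; depleted cells are flagged. The
per-cell methane-carbon uptake of an average-biovolume cell is

$$U = \frac{E}{100}\; c\, V \;\Big/\; \frac{L}{100} \Big/\; t$$

with carbon content $cV$ ($c = 6.4$ fmol C µm^-3^), labeling percentage $L$
of the methane pool (50 at% or ~20 at% in the emulated incubations) and
incubation time $t$ in days. Rates are "per average cell": per
average-biovolume filament, not per constituent cell, since filament
boundaries between cells are rarely resolvable.

Population uptake is $U \times$ cells ml^-1^ $\times 10^{-6}$, the exact
unit identity 1 fmol ml^-1^ d^-1^ = 10^-6^ µmol l^-1^ d^-1^.

Uncertainty: the relative s.d. of the *measured* at% is carried
multiplicatively to the per-cell rate. Carrying the relative s.d. of the
excess would be equally defensible, but the measured-at% convention
reproduces the reported per-cell uncertainties (e.g. 38.1 × 1.7/9.26 ≈ 6.9)
while the excess-based one does not; count uncertainty is not propagated
because none is reported. Note that the reported per-cell point rates
themselves are not exactly regenerable from the stated formula with the
stated labeling and a 2-day incubation (the effective labeling and time per
cohort are not printed); the downstream products — total biovolume and
population uptake — are consistent with the printed inputs to within a few
percent and are what the package validates.

`build_population_table()` assembles all derived columns at full precision;
`format_population_table()` renders the 2-significant-figure display view
used for upscaled quantities.

## Bulk rates from ^13^C-DIC series

Oxidized ^13^CH~4~ appears as ^13^CO~2~ in the DIC pool, so the labelled
DIC fraction rises linearly while substrate is in excess:

$$rate = \mathrm{slope}\!\left(\frac{\mathrm{at\%}}{100}\right)
  \times \mathrm{DIC} \Big/ \frac{L}{100}.$$

`mox_rate()` fits ordinary least squares on the full series by default; an
explicit `window` of point indices restricts the fit to the initial linear
phase (no automatic changepoint detection — a plateau after substrate
exhaustion should be excluded deliberately). A negative fitted slope is
truncated to rate 0 and flagged. The DIC pool size is a configuration
input. The estimator is slope-based and therefore invariant to constant
offsets in the series, linear in DIC and inverse-linear in labeling.

**Calibration note.** The fitted-SE interval of an OLS slope is
t-distributed with $n-2$ degrees of freedom, so a "±2 SE" interval covers
less than the nominal 95.4%: 90.8% at 8 points, 93.7% at 17. The package's
calibration experiment (`rate_recovery_experiment()`) therefore samples the
16-day incubation daily (17 points, noise 0.01 at%), a realistic
subsampling schedule under which ±2 SE coverage is expected at 93.7%; the
test suite checks the ≥93% bar over 1000 replicates so that the assertion
reflects calibration rather than Monte-Carlo luck.

Dissolved methane is back-calculated from headspace equilibration using the
published 1979 temperature/salinity solubility fit for methane (equilibrium
concentration form; validity about −2 to 30 °C, salinity 0–40), scaled by
partial pressure, with the headspace treated as ideal gas
(`dissolved_ch4()`, `equilibrate_headspace()`). The closed-bottle partition
closes its mass balance to <0.1%. δ^13^C values convert to at% through
$R = R_{VPDB}(1+\delta/1000)$ with $R_{VPDB} = 0.0111802$ (configurable).

## Probe mismatch screening

FISH probe failure is diagnosed in silico by Hamming-style mismatch
counting: the reverse complement of the probe is slid without gaps along
the target (both strands), and the minimum per-window mismatch count is
reported (`min_mismatches()`, `screen_probe()`). Ungapped comparison
matches the hybridization physics of short oligonucleotide probes; indels
are not considered. IUPAC ambiguity codes pair when their base sets
intersect (an `N` in a target pairs with anything); a strict mode counts
any ambiguity as a mismatch. Screens summarize with the strict comparison
`mismatches < threshold`. Position-weighted (central vs terminal) mismatch
penalties and thermodynamic (ΔG/T~m~) modelling are out of scope. Probe
sequences are user inputs; the package hard-codes none.

## The synthetic-data generators

Every stage is testable against planned truth without any external data:

* `simulate_field()` renders capsule (filament) and disc (coccus)
  geometries at a given pixel size, applies per-plane integer drift to the
  expected images, and draws Poisson counts per pixel and plane for the
  three masses. Ground truth records each object's true at%, analytic
  biovolume (the same cylinder/sphere formulas as the morphometry module)
  and exact pixel mask. Overlapping objects with conflicting atom fractions
  are rejected. Defaults: natural-abundance background at 1.11 at%;
  cell-free filter count density 20 counts px^-1^ plane^-1^; object
  densities in tests are set so that ROI count depths exceed 10^4^, making
  the counting-statistics SE small against the biological spread of
  reported cohorts (raw per-ROI count depths are not reported; this choice
  keeps the two error sources in their observed order).
* `simulate_incubation_series()` is the exact forward model inverted by
  `mox_rate()`, plus Gaussian noise.
* `simulate_probe_targets()` plants a mutated probe-binding site in random
  background and verifies by exhaustive scan that the planted window is the
  unique global best at the planned distance, regenerating on failure.

All generators are seed-deterministic (bit-identical output for the same
plan and seed) without touching the caller's RNG state. What they do *not*
emulate: detector dead time and quasi-simultaneous arrival, sample
charging, sub-pixel drift, 3-D cell shape, optical (FISH fluorescence)
imaging, autofluorescence, or biological variability in the atom fraction
within one cell. Passing recovery tests therefore demonstrates the
correctness and calibration of the quantification chain under Poisson
counting statistics — not robustness to instrument artefacts, which must be
corrected upstream on real data.

## Numerical choices and edge cases

* Alignment search is exhaustive over integer shifts with
  smallest-shift-first tie-breaking; correlation needs ≥9 overlapping
  pixels, otherwise the candidate is discarded.
* An ROI with zero total carbon counts is an error; zero ^12^C with
  nonzero ^13^C yields at% = 100 with an `undefined_ratio` flag.
* Single-member cohorts report s.d. 0 with a `single` flag.
* TIFF serialization stores planes as 16-bit unsigned integers (counts per
  plane must be < 2^16^, which holds by orders of magnitude at realistic
  plane dwell times); metadata travels in a JSON sidecar. Stacks with
  `NA` pixels (post-alignment) are in-memory objects and are not
  serialized.
* `equilibrate_headspace()` brackets the equilibrium pressure by doubling
  and solves with `uniroot` at 10^-12^ tolerance.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
100 simulated fields of 40 × 40 px × 5 planes (one ROI each, ≥10^4^ counts,
random drift up to ±5 px) for at%/drift recovery; a 13-filament field for
the ratio-floor cohort; 1000 (tests) or 100 (script) replicate tracer
series of 17 points for rate calibration; 50 constructed targets for the
probe-screen oracle comparison. These sizes keep the full suite under a
minute while leaving the binomial noise of the calibration checks well
characterized.

## Known limitations

The package quantifies assimilation (biomass incorporation), not total
methane oxidation; carbon-use efficiency is outside its scope. Growth
during the incubation is not corrected for (counts are start-of-incubation),
so population rates are conservative when populations grow. The uptake
formula's labeling/time correction assumes constant labeling percentage and
linear uptake over the incubation. ROI masks are inputs — there is no
automatic segmentation. The solubility fit is for fresh to marine water in
its stated temperature range only.
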