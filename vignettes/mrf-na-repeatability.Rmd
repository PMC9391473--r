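---
title: "Methods: simulating and scoring repeatability of simultaneous proton MRF / sodium brain MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring repeatability of simultaneous proton MRF / sodium brain MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrfrepeat)
```

This vignette documents the models, parameters and numerical choices
behind `mrfrepeat`. The package reconstructs, as reusable and tested
code, the analysis chain of a brain test–retest study at 7 T in which ten
volunteers were each scanned three times with a simultaneous 3D proton
MRF / sodium acquisition: fingerprint simulation, dictionary matching,
tissue masking and normalization, and the variance-decomposition
repeatability statistics.

## Signal model: EPG simulation of a FISP-type MRF train

Proton MRF estimates PD, T1, T2 and B1⁺ by matching the transient signal
of a variable flip-angle train against a precomputed dictionary. The
package simulates that signal with the extended phase graph (EPG)
formalism, which tracks magnetization as configuration states
(F⁺ₖ, F⁻ₖ, Zₖ) indexed by integer gradient-dephasing order *k*. Three
operators act per TR:

* **RF rotation** (`epg_rf`): the standard 3×3 mixing matrix for flip α
  and phase φ, applied to every order. It conserves
  Σₖ(|F⁺ₖ|² + |F⁻ₖ|² + 2|Zₖ|²); the factor 2 arises because the F⁺/F⁻
  pair double-counts transverse magnetization relative to Z. The test
  suite asserts this invariant to 1e-10 on random states.
* **Relaxation** (`epg_relax`): F states decay with exp(−dt/T2), Zₖ
  (k > 0) with exp(−dt/T1), and Z₀ regrows toward m0.
* **Gradient shift** (`epg_shift`): the unbalanced spoiler moves F⁺
  orders up and F⁻ orders down by one, with conjugate transfer through
  k = 0. States beyond the truncation order K are dropped.

Per pulse the simulator applies the RF rotation at the effective flip
`b1 × flip`, relaxes over TE, samples F₀⁺ (the complex echo), relaxes
over TR − TE, and shifts. The acquisition this models excites protons
every TR = 7.5 ms with TE = 2 ms; sodium is excited every 15 ms with
TE = 1 ms and a constant 30° flip, which is why the sodium image is
treated as a density-weighted (not fully quantitative) signal.

**The pulse train is configuration, not physics.** The actual
vendor-side flip-angle pattern of the modeled acquisition is not public;
all package computations are train-agnostic. `make_pulse_train()`
provides a documented convention — 420 pulses in 6 segments (the
acquisition uses 6 shots per slab) of sinusoidal ramps between a 10°
floor and per-segment ceilings of 40–70°, constant RF phase (FISP:
gradient spoiling only, no RF spoiling), optional inter-segment delays —
and `pulse_train()` accepts arbitrary per-pulse patterns, including CSV
round-trips. An inversion preparation exists behind a flag but is off by
default, since the modeled sequence does not describe one.

Numerical choices: the truncation order defaults to
`min(n_pulses, 100)`, bounded-memory and validated by a
truncation-sufficiency test (doubling K changes no sample at small n);
two implementations exist — a pure-R operator composition (reference)
and an Rcpp batch kernel used for dictionaries — pinned against each
other to 1e-13; and the simulator is validated against the closed-form
spoiled-GRE (Ernst) steady state sin α (1−E1)/(1−E1 cos α) e^(−TE/T2)
for constant trains in the T2 ≪ TR limit, where gradient spoiling is
effectively complete.

## Dictionary and matching

The dictionary grid is the acquisition's published matching grid: T1
from 150 ms and T2 from 15 ms in 5 % geometric steps, capped at 4347 ms
and 435 ms (70 values each), and a B1⁺ axis of 10°–130° in 1° steps
(121 values). Whether that axis is "the achieved angle of a reference
pulse" or "a pure scale on the train" is not decidable from the modeled
description; the package implements B1⁺ as a multiplicative scale
mapped to degrees through a reference angle (default 70°, the axis
midpoint), so `b1_deg = 70` means the nominal train. Entries with
T2 ≥ T1 are excluded by default — no tissue exhibits them and they only
enlarge the search space — with a flag and an excluded-entry count for
completeness.

Fingerprints are compressed by a sliding-window average along time
(window and stride default to 8/8, giving 52 samples from 420 pulses).
The real reconstruction ties this window to its view-sharing CG-SENSE
window, which is not printed; the default is therefore a package
convention and every result is window-agnostic. The identical operator
is applied to measured signals and dictionary atoms.

Atoms are simulated at unit m0 and L2-normalized with their
pre-normalization norms retained, so matching by maximal normalized
inner-product magnitude |⟨atom, s⟩|/‖s‖ returns a PD amplitude
`pd = |⟨atom, s⟩|/norm` that is exactly linear in m0. Matching uses the
magnitude of the complex inner product, making it invariant to the
arbitrary global phase of a reconstructed voxel. Ties break toward the
lowest (T1, T2, B1⁺) in lexicographic order via the sorted atom
ordering. Noiseless on-grid recovery is exact and is asserted
exhaustively on small grids and on full-grid phantoms in the acceptance
tests.

## The digital head phantom

`make_geometry()` builds a deterministic head: a WM ellipsoidal core, a
GM shell, a CSF outer shell plus two ventricles, and two eyes (vitreous
humor) anterior to and disjoint from the head. Crisp labels are smoothed
into partial-volume probability maps by a separable truncated-Gaussian
filter (default σ = 2 mm) with row-normalized kernels, which preserves
probability sums exactly; deep compartment cores keep probability 1,
which is what makes "exact recovery in tissue cores" a well-defined
test. The sodium image lives on an in-plane grid coarser by the
acquisition's ≈ 1.9 resolution ratio, sampled by nearest-neighbour
lookup; slices are shared, as in the acquisition (3 mm for both nuclei).

The default desk-scale grid is 64×64×24 over a 240×240×168 mm³ field of
view; the acquisition's full 160×160×56 matrix is a supported
configuration (`phantom_spec(grid_shape = c(160, 160, 56))`). Tests and
the acceptance script use 16³–32×32×12 grids and a B1⁺ axis thinned to
10° steps, sizes chosen so the full pipeline runs in seconds to a couple
of minutes on a laptop core while leaving every compartment non-empty on
both grids; the geometry constructor rejects grids that empty a
compartment.

**Statistical structure.** `tissue_distribution()` carries, per tissue
and parameter, a population mean, an inter-subject SD, and an intra-scan
relative SD. Defaults encode the modeled study's published components:
means from its per-tissue averages (GM/WM/CSF T1 1450/940/2570 ms, T2
40/32/102 ms, normalized PD 0.87/0.66/1, normalized sodium
0.35/0.31/0.50), inter-subject SDs as square roots of its inter-subject
variances, intra-scan relative SDs as square roots of its intra-subject
variances over the means. The study reports variance components, not
distributional shapes, so shapes are package choices: subjects draw from
truncated normals (redrawing below 10 % of the mean, which keeps
parameters positive without materially distorting moments at these
SD/mean ratios), and scans apply unit-mean multiplicative log-normal
perturbations — multiplicative because scan-to-scan instabilities
(repositioning, B0/B1 recalibration, coil loading) act proportionally on
these measurements, and the study does not quantify its intra-subject
sources individually, so a single variance knob per tissue/parameter is
exposed. Tests consequently assert moments, never shapes. Eye values are
package conventions with the one hard constraint the normalization
premise requires: the eye sodium mean is strictly the largest
compartment value (enforced at construction).

Two measurement modes exist. `direct` writes the true partial-volume
parameter maps plus additive Gaussian noise (default 2 % of the in-head
mean) — fast, for statistical Monte-Carlo. `epg` composes per-voxel
tissue parameters (crisp labels), a smooth multiplicative B1⁺ bowl
(default spanning 0.7–1.3 of nominal, to exercise the dictionary's B1⁺
axis; a flat field is available), the EPG simulator, and additive
complex Gaussian noise, yielding a fingerprint stack for matching.
Master seeds derive per-subject and per-scan child seeds
deterministically, so studies regenerate bit-identically.

What the phantom does **not** emulate: anatomy beyond nested ellipsoids,
k-space sampling, radial/view-sharing reconstruction artifacts, coil
sensitivities, inter-scan motion or registration error, segmentation
error (probability maps are phantom truth, standing in for an external
segmentation tool), B0 off-resonance, magnetization transfer, or sodium
spin-3/2 relaxation. Passing tests therefore demonstrate correctness of
the processing and statistics pipeline under the designed variance
structure — not that a scanner would achieve these numbers.

## Masks and normalizations

Tissue probability maps are renormalized to sum to one (only where the
three-tissue sum is at least 0.5 — renormalizing near-zero sums would
promote background voxels into masks) and binarized at 0.9: a voxel
joins a mask only if one tissue holds at least 90 % probability, which
minimizes partial-volume voxels, and any threshold above 0.5 makes the
masks structurally disjoint (the constructor rejects lower thresholds).
PD maps are divided by their CSF-mask mean, defining normalized CSF
PD ≡ 1.00; sodium images are divided by the eye-ROI mean on the sodium
grid. Both normalizations are scale-invariant and idempotent, and masks
move between grids by nearest-neighbour resampling, which preserves
labels and disjointness.

## Repeatability statistics

For each measurement (mean or SD of a parameter in a tissue, per scan):

* Intra_var = (1/N) Σᵢ varᵢ — the mean within-subject variance;
* Inter_var = var(meanᵢ) — the variance of subject means;
* CV = 100 × (1/N) Σᵢ SDᵢ/meanᵢ, in percent;
* ICC = Inter_var / (Inter_var + Intra_var);
* detectable change = 2 × CV.

All variances and SDs use the sample (n−1) denominator — the modeled
description does not state its convention, n−1 is the standard choice at
these sample sizes, and brute-force oracle tests pin the implementation
to that choice at 1e-12. Band boundaries are implemented with the
quoted inclusivities (CV ≤ 10 very good, ≤ 20 good, ≤ 30 moderate,
> 30 poor — poor supersedes the overlapping moderate definition;
ICC ≥ 0.8 very good, ≥ 0.6 good, ≥ 0.4 fair/moderate, < 0.4 poor).
Undefined cells are explicit `NA` markers, never zeros: the
(PD, CSF, mean) row is the normalization's defined constant 1 with no
variability statistics, and a zero-variance ICC is flagged rather than
invented. Report printing rounds ICC to 2 decimals and CV to 1, but CSV
and JSON writers keep full precision and round-trip losslessly.

`check_table_components()` verifies the published ICC column against its
published inter/intra variances at a 0.01 tolerance; all 23 rows with
printed components agree, confirming that the published ICCs were
computed on (approximately) these components. A few rows differ in the
second decimal when recomputed from the *printed* (rounded) variances —
e.g. 0.60 recomputed vs 0.61 printed — which is why the tolerance equals
one unit in the last printed place.

## A known property of this ICC estimator

Because Inter_var is the raw variance of subject means, it contains a
within-subject contribution: E[Inter_var] = σb² + σw²/k for k scans per
subject. Together with the nonlinearity of the ratio, the ICC estimator
at N = 10, k = 3 is *not* unbiased for σb²/(σb² + σw²): Monte-Carlo over
replicate simulated studies centers near 0.62, 0.79 and 0.94 when the
generating ratio is 0.60, 0.80 and 0.95. The package deliberately
implements only this estimator — not ANOVA-corrected ICC variants —
because it is the definition whose published values the package
verifies; users comparing simulated ICCs against generating ratios at
high ICC should expect the ~0.01 downward offset. Relatedly, with
identical subjects (σb² = 0) the estimator centers near 1/(k+1), not 0,
and approaches 0 only as the number of scans grows; the test suite
checks exactly that behavior. Similarly, CV is undefined for
measurements whose subject means can be non-positive, and the code
raises an error rather than returning a sign-corrupted value.

## Problem sizes and runtimes

The shipped tests use: 48–60-pulse trains for operator-level checks; the
full 420-pulse train with the complete T1/T2 grid and a 13-value B1⁺
axis (≈ 60,000 atoms) for the noiseless-recovery pipeline on a 32×32×12
phantom; 16³ phantoms for the 200-replicate ICC-recovery Monte-Carlo;
and 1500-pulse constant trains for the Ernst-limit check. These sizes
are the package's reference configurations for development-scale
hardware; all of them scale up by configuration only (full B1⁺ axis,
160×160×56 grids), with memory being the practical limit for full-size
fingerprint stacks (a full-grid complex stack is several GB; the
matcher processes voxels in chunks for exactly that reason).
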