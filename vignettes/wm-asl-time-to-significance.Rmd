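---
title: "Methods: time-to-significance analysis of white-matter ASL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-to-significance analysis of white-matter ASL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslpower)
```

## The statistical model

A PCASL acquisition alternates label and control volumes; the per-pair
difference `d_i = control_i − label_i` carries the perfusion signal plus
noise. For a voxel with mean difference `u` and difference standard
deviation `s`, the one-tailed paired t-statistic after `N` pairs is
`T = u·sqrt(N)/s` with `N − 1` degrees of freedom, tested against the
upper tail (the alternative is a *positive* ASL effect). Everything in
this package follows from that statistic evaluated on *cumulative
prefixes* of the difference series: the significant fraction of a mask
at each NSA, the first NSA at which each voxel crosses the threshold
(time-to-significance), and the set of voxels whose `T` stays below
zero at every NSA (non-responders).

Key assumptions: differences are independent across pairs (no temporal
autocorrelation), Gaussian within a voxel, and tested one voxel at a
time — multiple comparisons are addressed only through the optional
Bonferroni correction `α/m`, with `m` the voxel count of the analyzed
mask (the test family).

### Prefix engine

`t_curves()` maintains running sums `Σd` and `Σd²` per voxel, so the
statistic at every grid NSA costs O(1) after an O(n_pairs) pass —
linear overall, verified in the tests against a naive per-prefix
recomputation to 1e-9. Zero-variance prefixes get the limiting
sentinels: `T = +Inf` (p = 0) when `u > 0`, `T = 0` (p = 0.5) when
`u = 0`, `T = −Inf` (p = 1) when `u < 0`. A tiny negative variance from
floating-point cancellation is clamped to zero before the square root.

Two grids are used by default: every pair from 2 to `n_pairs` for
time-to-significance (exactness is cheap there), and a thinned grid
(every `curve_step` = 5 pairs) for curve, histogram and fit outputs.
Time-to-significance is *first crossing*, not sustained significance: a
voxel that dips back below the threshold later keeps its first crossing
time.

## The synthetic acquisition

No raw data accompany the study design this package operationalizes,
so the generator is a first-class, tested component that reproduces the
*statistical structure* the analysis assumes rather than anatomy.

**Phantom** (`sample_tissue_map()`): a deterministic concentric-layer
geometry on a 32×32×8 grid of 3.75×3.75×5 mm³ voxels (the 8-slice
partial-brain slab of the acquisition): an elliptical brain with a GM
shell, WM core, a central ventricle-like CSF region, and
partial-volume "mixed" voxels interleaved in a checkerboard along the
GM/WM interface (so that genuine WM–GM adjacencies survive for the
peripheral mask). Per-voxel draws: CBF ~ N(60, 10) in GM and N(20, 5)
in WM (WM = GM/3, inside the physiological 2–4× gap), transit times
N(1000, 150) ms in GM and N(1600, 200) ms in WM. All draws come from
one seeded stream in documented order (GM CBF, WM CBF, mixed CBF, GM
ATT, WM ATT, mixed ATT, non-responder selection, non-responder
magnitudes), so a seed fully reproduces the map.

**Kinetic model** (`kinetic_delta_m()`): the single-compartment
continuous-labeling closed form with all decay at blood T1 (no tissue
exchange term — appropriate for WM where little label has exchanged by
readout). Defaults: T1 blood 1650 ms at 3 T, labeling efficiency 0.85,
combined background-suppression efficiency 0.75, partition coefficient
0.9 mL/g, M0 = 1. The piecewise form (pre-arrival zero, inflow,
post-bolus decay) is continuous at both breakpoints and nonnegative;
tests check continuity to 1e-9 and agreement with an independently
coded evaluation to 1e-12. Under these defaults the expected WM
difference under the `exp3` preset is ≈ 0.21 (M0 units) at a typical
WM voxel (CBF 20, ATT 1600 ms), and `exp3` dominates `exp2` whenever
ATT ≤ 1500 ms — the protocol ranking the acquisition comparison is
built around.

**Noise** (`noise_config()`): independent Gaussian per voxel per
volume, default sd 0.35 in M0 units. This value was fixed once from a
power calculation: it puts the per-pair WM difference SNR at ≈ 0.4
(a single subtraction is far below detection) while letting roughly
80% of WM responder voxels cross α = 0.05 within the first ~40 pairs —
the steep-then-asymptotic filling regime of interest. Control volumes
additionally carry a residual static signal (default 5% of M0) that
grows 10% per slice, mimicking the progressively incomplete background
suppression of a 2D readout. There is no temporal autocorrelation and
no physiological noise by design: the validity of the paired t-test
under its own assumptions is the property under test.

**Non-responders**: a configurable fraction (default 6%) of WM voxels
is flagged with *no positive* expected difference at any NSA. Their
expected difference is drawn from a half-normal reflected to ≤ 0 with
default mean 0 (i.e. exactly zero effect); a negative mean magnitude
can be configured. The default fraction makes the fractional-recovery
ceiling land near 94% of WM, matching the observed sub-100% asymptote
mechanism: `a → 100·(1−q)` as noise vanishes, which the acceptance
tests verify within 2 percentage points on a ≥10⁴-voxel WM mask.

**SIR volume**: same grid, with the inversion-recovery contrast that
motivates SIR-based WM selection: WM ≈ 1.0, mixed ≈ 0.5, GM ≈ 0.1,
ventricular CSF ≈ 0.02 of M0, plus Gaussian noise (default sd 0.01).

What the generator does *not* emulate — anatomy, motion, physiological
noise, partial-volume point-spread mixing beyond the discrete "mixed"
class, k-space/coil effects — bounds what passing tests show: they
validate the statistical pipeline, not robustness to real-data
artifacts.

## Masking

WM is segmented by intensity bands relative to the SIR volume's robust
maximum (99th percentile): WM ≥ 0.8, partial-volume 0.25–0.8
(excluded), GM 0.05–0.25, ventricle < 0.05 *within the brain*. The
brain interior is found by flooding the complement from the image
border and declaring unreached voxels interior (hole filling). Filling
is slice-wise 2D by default: in an 8-slice partial-brain slab the
ventricle runs through the whole stack, so a 3D flood from the volume
faces would leak into it through the end slices.

Sub-masks: periventricular = ventricles dilated by one voxel
(default 26-connectivity — "all directions" including diagonals; 6 and
in-plane-8 are available because 5 mm slices make through-plane
adjacency debatable) intersected with WM; peripheral = WM voxels with
a GM voxel among their neighbors (strict neighbors — a voxel does not
border itself); deep = the remainder. When a voxel qualifies as both
periventricular and peripheral, periventricular wins, making the
three-way partition exact; the invariant
`|PV| + |peripheral| + |deep| = |WM|` is asserted on every phantom in
the tests.

## Histograms and response models

t-histograms use the fixed range [−10, 50]. The bin count is 60 (width
1): the design brief's "steps of 10 (60 bins)" is internally
inconsistent over a span of 60, and the explicit bin count is the less
ambiguous statement; the count is configurable for the 6-bin reading.
Out-of-range t-values are clipped into the extreme bins rather than
dropped so each per-subject histogram keeps unit area; group curves
average the per-subject densities bin by bin. Skewness is the adjusted
Fisher–Pearson sample coefficient.

Three asymptotic models compete for the percent-significant curve
`y(x)`, x = NSA: exponential recovery `a(1−e^{−bx})`, logarithmic
`a·log x`, and fractional recovery `ax/(b+x)` (Michaelis–Menten form,
asymptote `a`, half-saturation `b`). The nonlinear fits use
Levenberg–Marquardt with fixed, documented starts (`a₀ = max(y)`;
`b₀ = median(x)` for the fractional model, `1/median(x)` for the
exponential) and box constraint ≥ 0; the logarithmic model is linear
least squares. Selection is by smallest residual sum of squares among
converged fits; non-convergence flags the model and excludes it.
Confidence intervals are asymptotic (linearized covariance at the
optimum) at 95% — standard, cheap and reproducible; a coverage test
(200 replicates at 1-percentage-point noise) verifies ≥ 90% empirical
coverage. The mean-t law `y = K·sqrt(NSA)` is fitted through the
origin, since `T = u·sqrt(N)/s` has no intercept.

On the generator's phantom the *exponential* model often wins: with
CBF and ATT normally distributed across WM, the per-voxel effect sizes
`u/s` are roughly Gaussian and the filling curve approaches its
ceiling faster than the heavy-tailed fractional form. Which model wins
on real data is an empirical question about the tail of the effect
size distribution; the package reports all three fits with residuals
and intervals precisely so that the selection is transparent.

## Scan-time conventions

Table-facing scan times are truncated (not rounded) to one decimal:
400 pairs at TR 3500 ms is 46.67 min, printed 46.6. Session totals
quoted in whole minutes floor each protocol first (2×46 + 2×53 = 198).
`nsa_to_minutes()` is exact and unrounded for analysis.

## Problem sizes and determinism

The test suite and worked examples run phantoms of 24×24×4 to 64×64×8
voxels with 40–400 pairs, and oracle checks on random 20³ masks and
400-pair voxels — sizes chosen so the full suite completes in well
under a minute per file while the Monte-Carlo checks retain 3-standard-
error resolution. Every stochastic step takes an explicit integer
seed; identical configuration and seed give byte-identical CSV/JSON
outputs, which the pipeline test asserts.

## Known limitations

* The generator's phantom is geometric, not anatomical; absolute voxel
  counts per sub-mask are not comparable to a human acquisition.
* No motion, no temporal autocorrelation, no physiological noise: the
  calibration results (false-positive rate = α) hold under the test's
  own assumptions and will degrade on autocorrelated real series.
* CBF is never quantified in physical units; the pipeline works
  entirely in difference-signal and t-statistic space.
* Bonferroni is the only family-wise correction offered; FDR and
  cluster-based corrections are out of scope.
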