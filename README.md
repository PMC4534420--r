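# aslpower

Voxel-wise time-to-significance analysis for white-matter arterial spin
labeling (ASL) perfusion MRI.

## The problem

White-matter (WM) perfusion is 2–4 times lower than gray-matter
perfusion and arrives later (longer arterial transit times), so the
label/control difference signal of a background-suppressed PCASL
acquisition sits far below the noise floor for any single pair of
volumes. Detection is a question of signal averaging: as the number of
signal averages (NSA, label/control pairs) grows, each voxel's
one-tailed paired t-statistic

    T = u * sqrt(N) / s.d.

(u = mean control−label difference, s.d. = standard deviation of the
differences, N = NSA) grows like the square root of N, and voxels
"fill in" above the significance threshold one by one. This package
answers, for a simulated acquisition with known ground truth: how many
voxels are significant after a given scan time, how long each voxel
needs (time-to-significance), which voxels never respond, and which
asymptotic law the percent-significant curve follows.

The package provides:

* a **synthetic PCASL generator** — a layered digital head phantom
  (GM shell, WM core, ventricle-like CSF, partial-volume voxels) on an
  8-slice, 3.75×3.75×5 mm³ grid, a single-compartment kinetic model
  for the expected difference signal, slice-dependent residual static
  signal, Gaussian noise, and a configurable fraction of WM
  "non-responder" voxels with no positive ASL effect;
* **timeseries prep** — interleaved label/control splitting and
  subtraction, plus scan-time bookkeeping for the four built-in
  protocol presets (`exp1`…`exp4`, LD/PLD = 1650/1500, 1650/2000,
  2150/1500, 2150/1000 ms);
* the **significance engine** — cumulative-prefix paired t-statistics
  over an NSA grid (linear cost per voxel via running sums),
  significant-fraction curves at any α with optional Bonferroni
  correction, first-crossing time-to-significance maps, and
  non-responder detection (t < 0 at every NSA);
* **WM masking** — segmentation of WM from a co-registered
  single-inversion-recovery (SIR) volume by intensity bands, and the
  three-way partition into periventricular (one-voxel expansion of the
  ventricles), peripheral (WM bordering GM), and deep WM;
* **response models** — normalized t-histogram evolution over the
  fixed range [−10, 50], sample skewness, competitive fits of
  `y = a(1−e^{−bx})`, `y = a·log x`, and the fractional
  (Michaelis–Menten) recovery `y = ax/(b+x)` with model selection by
  residual error and 95% confidence intervals, and the
  `y = K·sqrt(NSA)` law for the mean WM t-value.

## Worked example

```r
library(aslpower)

cfg <- run_config(protocol = "exp3", n_pairs = 400, curve_step = 10,
                  seed = 1, outdir = "demo_out")
rep <- run_experiment(cfg)
rep
#> aslpower run: 2816 WM voxels, 8 non-responders
#> best response model: exp_recovery
#> outputs in: demo_out

frac <- subset(rep$thresholds, alpha == 0.05 & correction == "none")
frac[c(1:4, 40), c("nsa", "minutes", "fraction")]
#>    nsa   minutes  fraction
#> 1   10  1.333333 0.3199574
#> 2   20  2.666667 0.5145597
#> 3   30  4.000000 0.6331676
#> 4   40  5.333333 0.7276278
#> 40 400 53.333333 0.9406960

rep$response_fit
#> response_fit: best model = exp_recovery
#>   exp_recovery  RSS 59.92  params: a=93.2, b=0.03717
#>   logarithmic   RSS 1744  params: a=17.29
#>   fractional    RSS 167.2  params: a=100.2, b=16.08
```

Reading the output: of the 2816 segmented WM voxels, 73% show a
significant positive ASL effect (one-tailed paired t, α = 0.05) after
40 pairs (5.3 min of scanning) and 94% after the full 400 pairs
(53.3 min) — a steep initial filling phase followed by an asymptotic
tail, with the ceiling below 100% because a small fraction of WM
voxels (the simulated non-responders) never develop a positive effect.
The fitted asymptote of the selected response model (`a ≈ 93`) and the
non-responder fraction of the generator (6%) agree. The `exp3` preset
(LD 2150 / PLD 1500 ms) gives the strongest WM signal of the four
presets whenever transit times stay below 1500 ms.

All tables are also written as CSV, the maps as NIfTI, the fits as
JSON, and a provenance record (config, seed, MD5 of every output) as
JSON under `cfg$outdir`. A thin command-line wrapper over the same
functions ships in `inst/cli/aslpower.R`
(`Rscript aslpower.R run --config run.yaml`, plus `simulate`, `prep`,
`masks`, `significance`, `respmodel`, `thist` subcommands).

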