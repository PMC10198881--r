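---
title: "Diffusion-mode analysis of membrane-receptor tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-mode analysis of membrane-receptor tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(sptmodes)
library(dplyr)
```

## The problem

Single-particle tracking (SPT) follows individual fluorophore-labeled
membrane receptors across the frames of a TIRF movie. The mobility of a
receptor carries biological signal: receptors recruited into signaling
platforms or clathrin structures immobilize, receptors transiently trapped
by the cytoskeletal meshwork show confined diffusion, and unengaged
receptors diffuse freely. A ligand that drives receptor dimerization
therefore shifts the population balance between three diffusion modes —
**immobile**, **confined** and **free** — and does so on the time scale of
minutes, faster than any single fluorophore survives photobleaching.

`sptmodes` implements the full analysis chain for this kind of experiment:

1. trajectory linking from localization tables (`link_localizations()`),
2. per-segment mean-squared-displacement (MSD) analysis and
   diffusion-coefficient estimation (`compute_msd()`,
   `fit_diffusion_coefficient()`),
3. three-state mode classification with a localization-precision-derived
   immobility threshold (`classify_segment()`, `compute_d_min()`),
4. per-cell aggregation and time-resolved ligand-response profiles
   (`analyze_cells()`, `assign_time_bins()`, `baseline_align()`,
   `relative_change()`),
5. nonparametric group statistics (`compare_groups()`, `build_report()`),

together with a synthetic-data generator (`simulate_experiment()`) that
emulates the acquisition design and provides ground truth, so every stage
is recovery-testable.

## The acquisition design the generator emulates

Each cell is imaged for 1000 frames at 20 ms integration. Because a single
movie is far shorter than a receptor-activation response, many cells are
imaged sequentially over ~25 minutes, each cell receiving its own time
stamp. The ligand is added after the fifth cell, so cells 1–5 provide a
within-well resting baseline (the `[-5, 0)` minute interval) and the
remaining cells sample the response at increasing times after stimulation.
Per-cell diffusion summaries are then pooled into 1- or 5-minute bins to
suppress cell-to-cell heterogeneity.

The generator reproduces this design: emitters appear at random frames,
survive a geometric number of frames (per-frame bleaching probability
`p_bleach`, default 0.064), perform 2D Brownian motion (per-axis step
variance $2D\,\Delta t$), static positions, or Brownian motion inside a
reflecting circular corral, and every recorded position carries isotropic
Gaussian localization noise (`sigma_loc`, default 20 nm). Localization
tables use the ThunderSTORM CSV dialect (nanometres on disk, micrometres
internally).

```{r quick-sim}
cfg <- sim_config(n_cells = 3, n_emitters_per_cell = 50, seed = 1)
experiment <- simulate_experiment(cfg)
experiment
```

### What the generator does not emulate

Motion blur within the 20 ms integration window, pixelation, camera noise
and false localizations are not simulated: the pipeline consumes
localization tables, and these effects are second-order for the diffusion
range studied here. Emitters do not switch modes mid-trajectory. Passing
recovery tests on this generator therefore demonstrates correctness of the
analysis chain, not robustness to every artifact of real microscopy data.

## The model

For 2D Brownian motion with localization noise, the time-averaged MSD is

$$\mathrm{MSD}(n\,\Delta t) \;=\; 4 D \, n \Delta t \;+\; 4\sigma_{dyn}^2,$$

so an ordinary least-squares fit of the first `n_fit = 4` MSD points gives
the diffusion coefficient as slope/4 and the *dynamic localization
precision* $\sigma_{dyn}$ from the intercept. Negative fitted $D$ (pure
noise) is retained, never clipped: it is informative for the immobile
classification, and is only excluded from per-mode mean-$D$ reporting.

### Immobility threshold

A segment is immobile when its fitted $D$ falls strictly below a threshold
$D_{min}$ derived from the third quartile (linear-interpolation
convention) of the dynamic localization precision:
$D_{min} = Q_3(\sigma_{dyn})^2 / (4\Delta t)$ — the apparent diffusion
coefficient of a noise-only emitter over one frame interval. The quartile
convention is fixed (type 7) because $Q_3$ feeds a hard threshold.
Published per-target values (HER2 0.0084, TMD 0.0037, GPI
0.0086 µm²/s) are available via `d_min_override()` and are the default in
`run_pipeline()` reproduction runs; the formula mode remains selectable.
One caveat of the formula mode, flagged here deliberately: strongly
confined segments inflate the MSD intercept with part of their confinement
plateau, which drags $Q_3$ — and hence $D_{min}$ — upward. The pooled-Q3
convention (one threshold per dataset rather than per cell) was chosen for
stability at realistic per-cell segment counts.

### Confined versus free

Mobile segments are tested for sub-linear MSD growth by fitting the
anomalous-diffusion law $\mathrm{MSD}(t) = 4\Gamma t^{\alpha} + c$ and
calling a segment confined when the upper confidence bound of the
anomalous exponent lies below one:
$\hat\alpha + z\,\mathrm{SE}(\hat\alpha) < 1$ with $z = 1.96$.

The implementation of this fit deserves its own paragraph, because naive
choices fail in both directions. A three-parameter nonlinear fit reports
standard errors that are far too small for free segments (the points of a
time-averaged MSD are strongly correlated, so independent-error SEs
understate the true sampling scatter of $\hat\alpha$) and absurdly large
for confined segments (at the plateau, $\alpha$ and the offset $c$ become
collinear). `sptmodes` instead:

* fixes the noise offset at $c = 4\sigma_{loc}^2$ from the localization
  uncertainty column — the plateau then remains *in* the curve, where it
  belongs, flattening the log-slope (subtracting the segment's own fitted
  intercept would subtract part of the plateau and erase the confinement
  signature);
* fits $\log(\mathrm{MSD} - c)$ against $\log t$ by generalized least
  squares with the analytic per-lag relative variance of a time-averaged
  MSD, $(2n^2+1)/\left(3n(N-n+1)\right)$ for lag $n$ of an $N$-point
  segment, propagated through the offset subtraction, with a second-order
  correction for the log transform's downward bias;
* restricts the fit to the short-lag region (lags ≤ 10): that is where
  the variance model is accurate and where confinement curvature carries
  information; long lags of a single trajectory are dominated by noise
  that is both large and correlated, and including them destabilizes
  $\hat\alpha$ without adding power;
* selects lags adaptively by segment length: segments shorter than 60
  localizations use every lag up to 10 (each carries unique information
  and power is the binding constraint), while longer segments use a
  log-spaced subset (1, 2, 3, 5, 7, 10). Adjacent mid-range points of a
  time-averaged MSD are nearly redundant, and thinning them brings the
  independent-error standard errors into calibration with the true
  sampling scatter of $\hat\alpha$ where data are plentiful.

Segments whose offset-subtracted MSD has fewer than three positive lags
carry no displacement signal above the noise floor and are classified
immobile.

With these choices the classifier's operating point, measured on the
package's own simulation oracle, is: ≈ 95% of long free segments labeled
free (false-confinement ≈ 5% for long segments, ≈ 9% for short ones),
≈ 95% of long strongly confined segments labeled confined, and ≈ 70%
confined detection at the short segment lengths (20–40 localizations)
that dominate a geometric length distribution. The residual free→confined leakage and the missed short
confined segments roughly balance in cohort mode fractions, which is what
makes cohort-level recovery accurate to a few percent even though
per-segment calls at n ≈ 25 are intrinsically uncertain.

```{r classify-demo}
set.seed(7)
s <- sqrt(2 * 0.15 * 0.02)
seg <- tibble::tibble(
  frame = 0:99,
  x = cumsum(c(0, rnorm(99, 0, s))) + rnorm(100, 0, 0.02),
  y = cumsum(c(0, rnorm(99, 0, s))) + rnorm(100, 0, 0.02),
  uncertainty = 0.02
)
msd <- compute_msd(seg)
fit <- fit_diffusion_coefficient(msd)
glance(fit)
classify_segment(fit, msd, d_min = d_min_override("HER2"), sigma_loc = 0.02)
plot_msd(msd, fit)
```

## Trajectory linking

Localizations are linked into trajectories by a transparent greedy
nearest-neighbour assignment: candidate links within a search radius of
`radius_factor * exp_displacement` (default 3 × 117 nm for HER2) are
accepted in order of increasing distance; unmatched track ends terminate
(or persist through up to `max_gap_frames` missed frames when gap closing
is enabled); unmatched localizations open new segments. At the emitter
densities of single-particle tracking (≲ 0.05 µm⁻² per frame) this linker
reaches > 99% track purity against the generator's ground truth. The
probabilistic motion-model linking of dedicated tracking software
(including trajectory splitting on mode switches, governed by a switching
probability of 0.01) is intentionally out of scope; `p_switch` is carried
in `tracking_params()` for configuration fidelity but unused by the greedy
linker.

Tracking-scale parameters are estimated from the data as in the original
analysis workflow: `estimate_p_bleach()` is the geometric maximum-likelihood
estimate $\hat p = n / \sum d_i$ on segment durations (the model the
per-frame bleaching parameter implies), `estimate_exp_displacement()`
averages mutual-nearest-neighbour frame-to-frame displacements
(conservative: ambiguous pairs are dropped), and `estimate_precision()`
summarizes the per-localization uncertainty column. The published global
values for the three experimental targets ship in `tracking_defaults()`;
note the source table's displacement values are ambiguous between the
second HER2 entry and TMD — the defaults assign HER2 = 117 nm,
TMD = 82 nm, GPI = 165 nm and document rather than hide the ambiguity.

## Time-course analysis

Per-cell summaries are pooled into half-open bins $[kw, (k+1)w)$ minutes
relative to ligand addition (default $w = 5$), reported as mean ± SEM over
cells. To compensate fluctuations of the resting state between
measurements, the baseline `[-5, 0)` mode fractions of each condition are
shifted (additively, by default) onto the grand-mean baseline, and the
fraction triple is renormalized to sum to one; additive alignment was
chosen because it preserves the between-bin differences that the
relative-change figures display, and a multiplicative variant is
available. Fractions only are aligned by default; diffusion coefficients
pass through untouched.

Each bin's response is expressed as the relative change versus baseline,
$rc = (\bar x_{bin} - \bar x_{base})/\bar x_{base} \times 100\%$, with the
standard error of the difference,
$\mathrm{SED} = 100\sqrt{\mathrm{SEM}_{bin}^2 + \mathrm{SEM}_{base}^2} /
|\bar x_{base}|$, as the error bar (independent-samples propagation; the
source analysis names SED without a formula). A resting immobile fraction
of 10.5% rising to 22.7% is a +116% change; rising to 14.9% is +42%.

The ligand scenarios built into the generator's `response_profile()`
follow the observed phenomenology: the immobile fraction rises linearly to
a peak at `t_peak` (default 5 min) and relaxes exponentially
(`decay_tau`, default 10 min) toward a plateau. A plateau above baseline
encodes an EGF-like sustained response; a plateau equal to baseline with a
faster decay encodes a TGFα-like transient response. The functional form
is the package's own choice — the source data show only empirical profiles
— selected for closed-form testability (`response_fractions()` at
`t = t_peak + decay_tau` is exactly
`plateau + (peak - plateau)/e`).

```{r timecourse-demo}
cfg <- default_run_config()
cfg$simulation$n_cells <- 15L
cfg$simulation$n_emitters_per_cell <- 100L
cfg$seed <- 42L
run <- run_pipeline(cfg)
run
autoplot(run)
```

## Statistics

Per-cell means are the statistical unit throughout ("one cell, one
value"). Populations are screened with a Shapiro–Wilk test at α = 0.05
(`normality_gate()`), but — matching the analysis scheme this package
reproduces — nonparametric tests are used for comparison regardless,
because some populations reject normality: Mann–Whitney U for independent
treatment groups, Wilcoxon signed-rank for paired samples, both two-sided
(the conservative default; sidedness is not stated in the source scheme).
Significance labels follow the star scheme with strict boundaries:
p ≥ 0.05 none, < 0.05 `*`, < 0.01 `**`, < 0.001 `***`. Raw p values are
reported; a Bonferroni option exists but is off by default. The exact U
distribution is used for groups of ≤ 20 without ties, the tie-corrected
normal approximation otherwise.

## Numerical and design choices

* **Units.** Localization CSVs are in nanometres (ThunderSTORM dialect);
  all internal computation is in micrometres and seconds; diffusion
  coefficients are µm²/s everywhere. Frames are 0-based internally; 1-based
  input tables are detected and shifted with a message.
* **Gaps.** MSD computation indexes positions by frame offset, so segments
  with interior gaps contribute only displacement pairs whose both
  endpoints exist; lag bookkeeping reports per-lag pair counts.
* **Degenerate inputs.** All-zero MSD curves classify as immobile; cells
  with no segment surviving the 20-localization length filter yield an
  explicit `n_segments = 0` marker excluded from cohort means; empty
  localization tables link to empty segment tables.
* **Confinement geometry.** The generator's confined state is a reflecting
  circular corral (the simplest mechanism with a defined MSD plateau),
  with defaults `D_conf = 0.10` µm²/s and radius 0.14 µm. These defaults
  are deliberate: a study that reports a sizable confined fraction
  *detected by this classification method* implies confinement inside the
  method's operational window — an MSD crossover ($r^2/4D_{conf}\Delta t$)
  of a few frame intervals, late enough that the 4-point $D$ stays above
  $D_{min}$ and early enough that curvature is detectable within typical
  segment lengths. Corral parameters outside that window would describe a
  different (undetectable) kind of confinement than the one the study
  quantified.
* **Cell-to-cell heterogeneity.** Real cells vary in their resting
  immobile fraction; the magnitude is not quantified in the source. The
  generator exposes `cell_jitter_sd` (default 0) rather than inventing a
  default, and the binning stage is what absorbs heterogeneity in real
  data.
* **Problem sizes.** The bundled tests and the acceptance script run the
  recovery studies at 40 cells × 300 emitters (resting recovery) and 80
  cells (time-course discrimination, 16 cells per 5-min bin); the original
  experiments pooled 40 cells per bin from multiple wells. These sizes
  give cohort-level standard errors small enough for the stated
  tolerances while keeping a full run in minutes on one core.

## Known limitations

* Per-segment confined/free calls at 20–40 localizations are intrinsically
  uncertain (the 95% CI on $\hat\alpha$ spans ±0.3–0.5); cohort fractions
  are reliable, individual labels are not.
* The greedy linker has no splitting/merging and will fuse trajectories
  at densities well above the SPT regime.
* `estimate_p_bleach()` ignores right-censoring by the movie end; with
  1000-frame movies and mean lifetimes of ~16 frames the induced bias is
  ≈ +1–2% of the estimate, well inside its sampling error at realistic
  segment counts.
* The formula-mode $D_{min}$ inherits the confinement-plateau inflation
  discussed above; reproduction runs should prefer the published
  overrides.
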