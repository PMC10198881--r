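# sptmodes

Diffusion-mode analysis for single-particle tracking (SPT) of membrane
receptors.

Receptor tyrosine kinases such as HER2 change their lateral mobility in the
plasma membrane when they engage signaling partners: activated receptors
immobilize. `sptmodes` implements the analysis chain that turns
single-molecule localization tables into that biological readout:

* **Trajectory linking** — greedy nearest-neighbour linking of
  ThunderSTORM-style localization tables, with data-driven estimation of
  the tracking-scale parameters (`p_bleach`, expected frame-to-frame
  displacement, per-cell precision).
* **MSD analysis** — per-segment time-averaged mean squared displacement;
  the diffusion coefficient from a 4-point linear fit,
  `MSD(t) = 4Dt + 4σ²`; dynamic localization precision from the intercept.
* **Three-state mode classification** — *immobile* below a threshold
  `D_min = Q3(σ_dyn)²/(4Δt)` derived from the third quartile of the dynamic
  localization precision (published per-target overrides included);
  *confined* vs *free* by an anomalous-exponent test on
  `MSD(t) = 4Γt^α + c`, confined when `α + 1.96·SE(α) < 1`.
* **Time-course analysis** — per-cell summaries pooled into 5-min bins
  relative to ligand addition, baseline alignment of the pre-ligand
  interval across conditions, and relative-change profiles with standard
  errors of the difference (SED).
* **Statistics** — Shapiro–Wilk normality screen, Mann–Whitney U /
  Wilcoxon signed-rank comparisons, significance stars
  (`p < 0.05/0.01/0.001`).
* **Synthetic data** — a generator that emulates the sequential
  multi-cell acquisition (1000 frames @ 20 ms per cell, 25 cells, ligand
  after cell 5) with known ground truth: three diffusion modes,
  localization noise, geometric photobleaching and configurable
  ligand-response kinetics.

Everything takes and returns tibbles, so the stages chain with the pipe.

## Worked example

Simulate a small resting-state experiment, link, analyze, and summarize:

```r
library(sptmodes)

cfg <- sim_config(
  n_cells = 12, n_emitters_per_cell = 300,
  response = flat_profile(f_imm = 0.105, f_conf = 0.281),
  seed = 11
)
experiment <- simulate_experiment(cfg)
cells <- analyze_cells(experiment, d_min = d_min_override("HER2"))
round(colMeans(cells[, c("f_imm", "f_conf", "f_free", "D_free")]), 3)
#> f_imm f_conf f_free D_free
#> 0.089  0.273  0.638  0.142
```

The ground truth behind this run is 10.5% immobile, 28.1% confined, 61.4%
free, with a free diffusion coefficient of 0.15 µm²/s: the pipeline
recovers the mode fractions to within a few percent and the free-D to
within 6% from 12 cells.

The relative-change arithmetic of the time-course stage reproduces the
canonical worked numbers — a resting immobile fraction of 10.5% rising to
22.7% under stimulation is a +116% change, rising to 14.9% is +42%:

```r
binned <- tibble::tibble(
  condition = "EGF", bin_start = c(-5, 0), bin_end = c(0, 5),
  bin_label = c("[-5,0)", "[0,5)"), n_cells = 160L,
  property = factor("f_imm", levels = "f_imm"),
  mean = c(0.105, 0.227), sem = c(0.004, 0.008)
)
relative_change(binned, property = "f_imm")
#> # A tibble: 2 × 7
#>   condition bin_start bin_label property n_cells rel_change_pct sed_pct
#>   <chr>         <dbl> <chr>     <fct>      <int>          <dbl>   <dbl>
#> 1 EGF              -5 [-5,0)    f_imm        160             0     5.39
#> 2 EGF               0 [0,5)     f_imm        160           116.    8.52
```

An end-to-end run (simulate → link → analyze → bin → align → relative
change → report) is one call:

```r
run <- run_pipeline(default_run_config())
run
#> <spt_run> 25 cells, config df0fe036
#> Time bins: 5
#> Peak immobile-fraction change: +192% in [5,10) min
autoplot(run)   # dot plot of relative change with SED bars
```

See `vignette("diffusion-modes")` for the model, the classifier's error
model, and every numerical choice.

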