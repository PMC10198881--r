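test_that("response_fractions returns baseline before ligand and peak at t_peak", {
  prof <- response_profile(
    baseline_f_imm = 0.105, peak_f_imm = 0.295, t_peak = 5,
    decay_tau = 10, plateau_f_imm = 0.17, f_conf = 0.281
  )
  pre <- response_fractions(-3, prof)
  expect_equal(pre$f_imm, 0.105)
  expect_equal(pre$f_conf, 0.281)
  expect_equal(pre$f_free, 1 - 0.105 - 0.281)

  at_peak <- response_fractions(5, prof)
  expect_equal(at_peak$f_imm, 0.295)
})

test_that("response relaxation follows the closed-form exponential law", {
  prof <- response_profile(
    baseline_f_imm = 0.105, peak_f_imm = 0.295, t_peak = 5,
    decay_tau = 10, plateau_f_imm = 0.17, f_conf = 0.281
  )
  # one time constant past the peak: plateau + (peak - plateau) * exp(-1)
  expect_equal(
    response_fractions(15, prof)$f_imm,
    0.17 + (0.295 - 0.17) * exp(-1),
    tolerance = 1e-12
  )
})

test_that("response fractions are valid proportions at all times", {
  prof <- response_profile()
  grid <- response_fractions(seq(-5, 60, by = 0.25), prof)
  expect_true(all(grid$f_imm >= 0 & grid$f_imm <= 1))
  expect_true(all(grid$f_free >= 0 & grid$f_free <= 1))
  expect_equal(grid$f_imm + grid$f_conf + grid$f_free, rep(1, nrow(grid)))
  expect_error(response_fractions(NaN, prof), "finite")
  expect_error(response_fractions(Inf, prof), "finite")
})

test_that("profile and config invariants are enforced", {
  expect_error(response_profile(baseline_f_imm = 0.3, peak_f_imm = 0.2))
  expect_error(
    response_profile(baseline_f_imm = 0.6, peak_f_imm = 0.6, f_conf = 0.5),
    "exceed"
  )
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(fov = c(0.2, 20), confinement_radius = 0.14), "field of view")
  expect_error(sim_config(ligand_time = 30, total_time = 25))
})

test_that("motionless noise-free emitters yield identical localizations", {
  cfg <- sim_config(
    n_cells = 1, n_frames = 50, n_emitters_per_cell = 20,
    D_free = 0, sigma_loc = 0, response = flat_profile(f_imm = 0, f_conf = 0),
    seed = 1
  )
  set.seed(1)
  sim <- simulate_cell(cfg, t_cell = -5)
  spread <- dplyr::summarise(
    dplyr::group_by(sim$locs, id),
    sx = diff(range(x)), sy = diff(range(y))
  )
  expect_true(all(spread$sx == 0 & spread$sy == 0))
})

test_that("noise-only displacement and Brownian step statistics match closed forms", {
  # immobile emitters with sigma = 0.02 um: E[step^2] = 4 sigma^2
  cfg_imm <- sim_config(
    n_cells = 1, n_frames = 40, n_emitters_per_cell = 400,
    sigma_loc = 0.02, p_bleach = 0.02,
    response = flat_profile(f_imm = 1, f_conf = 0), seed = 2
  )
  set.seed(2)
  sim <- simulate_cell(cfg_imm, t_cell = -5)
  steps2 <- unlist(lapply(split(sim$locs, sim$locs$id), function(tr) {
    tr <- tr[order(tr$frame), ]
    keep <- diff(tr$frame) == 1
    (diff(tr$x)^2 + diff(tr$y)^2)[keep]
  }))
  expect_gt(length(steps2), 3000)
  se <- stats::sd(steps2) / sqrt(length(steps2))
  expect_lt(abs(mean(steps2) - 4 * 0.02^2), 3 * se)

  # free emitters, D = 0.1, dt = 0.02, no noise: E[step^2] = 4 D dt
  cfg_free <- sim_config(
    n_cells = 1, n_frames = 40, n_emitters_per_cell = 400,
    D_free = 0.1, sigma_loc = 0, p_bleach = 0.02,
    response = flat_profile(f_imm = 0, f_conf = 0), seed = 3
  )
  set.seed(3)
  sim <- simulate_cell(cfg_free, t_cell = -5)
  steps2 <- unlist(lapply(split(sim$locs, sim$locs$id), function(tr) {
    tr <- tr[order(tr$frame), ]
    keep <- diff(tr$frame) == 1
    (diff(tr$x)^2 + diff(tr$y)^2)[keep]
  }))
  se <- stats::sd(steps2) / sqrt(length(steps2))
  expect_lt(abs(mean(steps2) - 4 * 0.1 * 0.02), 3 * se)
})

test_that("free-emitter MSD of true positions grows as 4 D n dt", {
  cfg <- sim_config(
    n_cells = 1, n_frames = 60, n_emitters_per_cell = 1000,
    D_free = 0.15, sigma_loc = 0.02, p_bleach = 1e-9,
    response = flat_profile(f_imm = 0, f_conf = 0), seed = 4
  )
  set.seed(4)
  sim <- simulate_cell(cfg, t_cell = -5)
  for (lag in 1:4) {
    d2 <- unlist(lapply(split(sim$locs, sim$locs$id), function(tr) {
      tr <- tr[order(tr$frame), ]
      n <- nrow(tr)
      if (n <= lag) return(NULL)
      i <- seq_len(n - lag)
      (tr$x_true[i + lag] - tr$x_true[i])^2 +
        (tr$y_true[i + lag] - tr$y_true[i])^2
    }))
    se <- stats::sd(d2) / sqrt(length(d2))
    expect_lt(abs(mean(d2) - 4 * 0.15 * lag * 0.02), 3 * se)
  }
})

test_that("confined emitters' MSD plateaus below 2 r^2", {
  r <- 0.14
  cfg <- sim_config(
    n_cells = 1, n_frames = 200, n_emitters_per_cell = 200,
    D_conf = 0.1, confinement_radius = r, sigma_loc = 0, p_bleach = 1e-9,
    response = flat_profile(f_imm = 0, f_conf = 1), seed = 5
  )
  set.seed(5)
  sim <- simulate_cell(cfg, t_cell = -5)
  lag <- 100L
  d2 <- unlist(lapply(split(sim$locs, sim$locs$id), function(tr) {
    tr <- tr[order(tr$frame), ]
    n <- nrow(tr)
    if (n <= lag) return(NULL)
    i <- seq_len(n - lag)
    (tr$x_true[i + lag] - tr$x_true[i])^2 + (tr$y_true[i + lag] - tr$y_true[i])^2
  }))
  expect_lt(mean(d2), 2 * r^2)
  expect_gt(mean(d2), 0.5 * r^2) # saturated, not static
})

test_that("drawn mode counts match requested fractions (binomial check at 1e4)", {
  cfg <- sim_config(
    n_cells = 1, n_frames = 3, n_emitters_per_cell = 10000,
    sigma_loc = 0, p_bleach = 0.9,
    response = flat_profile(f_imm = 0.105, f_conf = 0.281), seed = 6
  )
  set.seed(6)
  sim <- simulate_cell(cfg, t_cell = -5)
  expect_equal(nrow(sim$truth), 10000)
  counts <- table(sim$truth$mode)
  truth_f <- c(immobile = 0.105, confined = 0.281, free = 0.614)
  for (m in names(truth_f)) {
    p <- truth_f[[m]]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(counts[[m]] / 10000 - p), 4 * se)
  }
})

test_that("trajectory durations are geometric with mean 1/p_bleach", {
  cfg <- sim_config(
    n_cells = 1, n_frames = 1000, n_emitters_per_cell = 10000,
    sigma_loc = 0, p_bleach = 0.064,
    response = flat_profile(f_imm = 1, f_conf = 0), seed = 7
  )
  set.seed(7)
  sim <- simulate_cell(cfg, t_cell = -5)
  dur <- sim$truth$n_frames_true
  se <- stats::sd(dur) / sqrt(length(dur))
  expect_lt(abs(mean(dur) - 1 / 0.064), 3 * se)
})

test_that("recorded localizations are true positions plus isotropic noise", {
  cfg <- sim_config(
    n_cells = 1, n_frames = 30, n_emitters_per_cell = 500,
    sigma_loc = 0.02, p_bleach = 0.05,
    response = flat_profile(), seed = 8
  )
  set.seed(8)
  sim <- simulate_cell(cfg, t_cell = -5)
  resx <- sim$locs$x - sim$locs$x_true
  resy <- sim$locs$y - sim$locs$y_true
  n <- length(resx)
  expect_lt(abs(stats::sd(resx) - 0.02), 4 * 0.02 / sqrt(2 * n))
  expect_lt(abs(stats::sd(resy) - 0.02), 4 * 0.02 / sqrt(2 * n))
  expect_lt(abs(stats::cor(resx, resy)), 4 / sqrt(n))
})

test_that("sequential experiment stamps timestamps and conditions correctly", {
  cfg <- sim_config(
    n_cells = 25, n_frames = 5, n_emitters_per_cell = 5,
    total_time = 30, ligand_time = 5, seed = 9
  )
  exp <- simulate_experiment(cfg)
  expect_equal(nrow(exp), 25)
  expect_true(all(diff(exp$t_min) > 0))
  expect_equal(sum(exp$t_min >= -5 & exp$t_min < 0), 5)
  expect_equal(exp$condition, ifelse(exp$t_min < 0, "resting", "stimulated"))
  expect_equal(sum(exp$condition == "resting"), 5)
})

test_that("a flat profile gives identical ground-truth fractions for all cells", {
  cfg <- sim_config(
    n_cells = 10, n_frames = 5, n_emitters_per_cell = 5,
    response = flat_profile(f_imm = 0.2, f_conf = 0.3), seed = 10
  )
  exp <- simulate_experiment(cfg)
  expect_equal(unique(exp$f_imm_true), 0.2)
  expect_equal(unique(exp$f_conf_true), 0.3)
})

test_that("the same seed reproduces the experiment exactly", {
  cfg <- sim_config(n_cells = 2, n_frames = 50, n_emitters_per_cell = 30, seed = 11)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1, e2)
  e3 <- simulate_experiment(sim_config(
    n_cells = 2, n_frames = 50, n_emitters_per_cell = 30, seed = 12
  ))
  expect_false(identical(e1$locs[[1]], e3$locs[[1]]))
})
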