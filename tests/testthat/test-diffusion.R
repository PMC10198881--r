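test_that("MSD matches hand-enumerated values on the worked 5-point path", {
  seg <- make_segment(c(0, 1, 1, 2, 2), c(0, 0, 1, 1, 2))
  msd <- compute_msd(seg, max_lag_fraction = 1)
  expect_equal(msd$msd, c(1, 2, 5, 8))
  expect_equal(msd$n_pairs, c(4L, 3L, 2L, 1L))
  expect_equal(msd$t, (1:4) * 0.02)
})

test_that("MSD is zero for static points and ballistic for a linear walk", {
  expect_true(all(compute_msd(static_segment(10))$msd == 0))
  d <- 0.3
  seg <- make_segment((0:19) * d, rep(0, 20))
  msd <- compute_msd(seg, max_lag_fraction = 1)
  expect_equal(msd$msd, (msd$lag * d)^2)
  expect_error(compute_msd(make_segment(1, 1)), "at least 2")
})

test_that("MSD equals the brute-force double-loop oracle, with and without gaps", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    seg <- brownian_segment(n, D = stats::runif(1, 0.01, 0.3), sigma = 0.02)
    expect_equal(compute_msd(seg), msd_bruteforce(seg))
    # knock out interior frames: only pairs with both endpoints count
    holey <- seg[-sample(2:(n - 1), 3), ]
    expect_equal(compute_msd(holey), msd_bruteforce(holey))
  }
})

test_that("the 4-point fit reproduces closed-form OLS and matches lm()", {
  msd <- tibble::tibble(
    lag = 1:4, t = c(0.02, 0.04, 0.06, 0.08),
    msd = c(1, 2, 5, 8), n_pairs = 4:1
  )
  fit <- fit_diffusion_coefficient(msd)
  expect_equal(fit$slope, 120)
  expect_equal(fit$D, 30)
  expect_equal(fit$intercept, -2)
  expect_true(is.na(fit$sigma_dyn)) # negative intercept: precision undefined

  oracle <- stats::lm(msd ~ t, data = msd)
  expect_equal(fit$slope, unname(stats::coef(oracle)[2]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(stats::coef(oracle)[1]), tolerance = 1e-10)
})

test_that("a flat MSD yields zero D and recovers the localization precision", {
  msd <- tibble::tibble(lag = 1:4, t = (1:4) * 0.02,
                        msd = rep(4 * 0.02^2, 4), n_pairs = 10:7)
  fit <- fit_diffusion_coefficient(msd)
  expect_equal(fit$D, 0)
  expect_equal(fit$sigma_dyn, 0.02)
  expect_error(
    fit_diffusion_coefficient(msd[1:3, ]),
    "3 usable lags"
  )
})

test_that("tidy() and glance() expose the fit in broom shape", {
  msd <- tibble::tibble(lag = 1:4, t = (1:4) * 0.02,
                        msd = c(1, 2, 5, 8), n_pairs = 4:1)
  fit <- fit_diffusion_coefficient(msd)
  td <- tidy(fit)
  expect_equal(td$term, c("slope", "intercept"))
  expect_equal(td$estimate, c(120, -2))
  gl <- glance(fit)
  expect_equal(gl$D, 30)
  expect_equal(gl$n_fit, 4)
})

test_that("fitted D on noise-free Brownian segments is unbiased", {
  set.seed(32)
  D <- 0.1
  d_hat <- replicate(300, {
    fit_diffusion_coefficient(compute_msd(brownian_segment(40, D = D)))$D
  })
  se <- stats::sd(d_hat) / sqrt(length(d_hat))
  expect_lt(abs(mean(d_hat) - D), 3 * se)
})

test_that("D_min follows the Q3 rule with type-7 quartiles", {
  # independent quartile computation: type-7 linear interpolation by hand
  sig <- c(0.01, 0.02, 0.03, 0.04)
  q3_hand <- 0.03 + 0.25 * (0.04 - 0.03) # h = 1 + 3*0.75 = 3.25
  expect_equal(unname(stats::quantile(sig, 0.75, type = 7)), q3_hand)
  expect_equal(compute_d_min(sig, dt = 0.02), q3_hand^2 / (4 * 0.02))
  expect_equal(compute_d_min(sig, dt = 0.02), 0.0325^2 / 0.08)

  expect_equal(compute_d_min(rep(0, 5), dt = 0.02), 0)
  expect_equal(compute_d_min(c(NA, 0.02), dt = 0.02), 0.02^2 / 0.08)
  expect_error(compute_d_min(NA_real_, dt = 0.02), "sigma_dyn")

  expect_equal(d_min_override("HER2"), 0.0084)
  expect_equal(d_min_override("TMD"), 0.0037)
  expect_equal(d_min_override("GPI"), 0.0086)
})

test_that("immobile threshold is a strict inequality and degenerate MSD is immobile", {
  msd_brownian <- tibble::tibble(
    lag = 1:10, t = (1:10) * 0.02,
    msd = 4 * 0.0084 * (1:10) * 0.02 + 1e-6, n_pairs = 30:21
  )
  fit <- fit_diffusion_coefficient(msd_brownian)

  below <- classify_segment(fit, msd_brownian, d_min = fit$D + 1e-9, sigma_loc = 0)
  expect_equal(as.character(below$mode), "immobile")
  at <- classify_segment(fit, msd_brownian, d_min = fit$D, sigma_loc = 0)
  expect_false(as.character(at$mode) == "immobile")

  zero <- tibble::tibble(lag = 1:5, t = (1:5) * 0.02, msd = rep(0, 5),
                         n_pairs = 10:6)
  fit0 <- fit_diffusion_coefficient(zero)
  expect_equal(
    as.character(classify_segment(fit0, zero, d_min = 0, sigma_loc = 0)$mode),
    "immobile"
  )
})

test_that("classification recovers free and confined motion at high rates", {
  set.seed(33)
  lab_free <- replicate(200, {
    seg <- brownian_segment(100, D = 0.1, sigma = 0.02)
    msd <- compute_msd(seg)
    fit <- fit_diffusion_coefficient(msd)
    as.character(classify_segment(fit, msd, d_min = 0.0084,
                                  sigma_loc = 0.02)$mode)
  })
  expect_gte(mean(lab_free == "free"), 0.85)

  lab_conf <- replicate(200, {
    seg <- confined_segment(100, D = 0.1, radius = 0.1, sigma = 0.02)
    msd <- compute_msd(seg)
    fit <- fit_diffusion_coefficient(msd)
    as.character(classify_segment(fit, msd, d_min = 0.0084,
                                  sigma_loc = 0.02)$mode)
  })
  expect_gte(mean(lab_conf == "confined"), 0.8)
})

test_that("immobile labelling is monotone in d_min", {
  set.seed(34)
  exp <- small_experiment(n_cells = 1, n_emitters = 150, seed = 35)
  segs <- link_localizations(exp$locs[[1]], tracking_params())
  thresholds <- c(0, 0.002, 0.0084, 0.02, 0.05, 10)
  f_imm <- vapply(thresholds, function(dm) {
    st <- analyze_segments(segs, d_min = dm)
    mean(st$mode == "immobile")
  }, numeric(1))
  expect_true(all(diff(f_imm) >= 0))
  expect_equal(f_imm[length(f_imm)], 1)
})

test_that("analyze_cell filters short segments and aggregates labels", {
  set.seed(36)
  mk <- function(id, n, x) {
    tibble::tibble(segment_id = id, frame = 0:(n - 1),
                   x = x, y = rep(0, n), uncertainty = 0.02)
  }
  segs <- dplyr::bind_rows(
    lapply(1:5, function(i) mk(i, 19, stats::rnorm(19, sd = 0.1))),
    lapply(6:10, function(i) mk(i, 25, cumsum(stats::rnorm(25, sd = 0.08))))
  )
  cell <- analyze_cell(segs, cell_id = 7L, d_min = 0.0084)
  expect_equal(cell$n_segments, 5)
  expect_equal(cell$cell_id, 7L)
  expect_equal(cell$f_imm + cell$f_conf + cell$f_free, 1)

  # all-immobile cell: static points, huge threshold
  static <- dplyr::bind_rows(lapply(1:4, function(i) mk(i, 30, rep(i, 30))))
  cell_imm <- analyze_cell(static, d_min = 1)
  expect_equal(cell_imm$f_imm, 1)
  expect_equal(cell_imm$f_conf, 0)

  # nothing survives the length filter: explicit empty marker
  empty <- analyze_cell(mk(1, 10, stats::rnorm(10)), d_min = 0.0084)
  expect_equal(empty$n_segments, 0)
  expect_true(is.na(empty$D_global))
})

test_that("cell summaries are invariant to segment order", {
  exp <- small_experiment(n_cells = 1, n_emitters = 120, seed = 37)
  segs <- link_localizations(exp$locs[[1]], tracking_params())
  a <- analyze_cell(segs, d_min = 0.0084)
  segs_shuffled <- segs[sample(nrow(segs)), ]
  b <- analyze_cell(segs_shuffled, d_min = 0.0084)
  expect_equal(a, b)
})

test_that("fractions from every analyzed cell sum to one", {
  exp <- small_experiment(n_cells = 3, n_emitters = 100, seed = 38)
  cells <- analyze_cells(exp, d_min = d_min_override("HER2"))
  ok <- cells$n_segments > 0
  expect_true(all(abs(cells$f_imm[ok] + cells$f_conf[ok] + cells$f_free[ok] - 1) < 1e-9))
})
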