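# Standalone trajectory generators used across tests: single segments with
# known motion, independent of the package's cell-level simulator so they can
# serve as oracles for it.

make_segment <- function(x, y, frame = seq_along(x) - 1L, uncertainty = 0.02) {
  tibble::tibble(frame = as.integer(frame), x = x, y = y,
                 uncertainty = uncertainty)
}

brownian_segment <- function(n, D, dt = 0.02, sigma = 0, x0 = 0, y0 = 0) {
  sd_step <- sqrt(2 * D * dt)
  x <- x0 + cumsum(c(0, stats::rnorm(n - 1, 0, sd_step)))
  y <- y0 + cumsum(c(0, stats::rnorm(n - 1, 0, sd_step)))
  make_segment(x + stats::rnorm(n, 0, sigma), y + stats::rnorm(n, 0, sigma),
               uncertainty = sigma)
}

static_segment <- function(n, sigma = 0, x0 = 0, y0 = 0) {
  make_segment(x0 + stats::rnorm(n, 0, sigma), y0 + stats::rnorm(n, 0, sigma),
               uncertainty = sigma)
}

# reflecting circular corral around the start position
confined_segment <- function(n, D, radius, dt = 0.02, sigma = 0) {
  sd_step <- sqrt(2 * D * dt)
  x <- numeric(n)
  y <- numeric(n)
  for (k in seq_len(n)[-1]) {
    xp <- x[k - 1] + stats::rnorm(1, 0, sd_step)
    yp <- y[k - 1] + stats::rnorm(1, 0, sd_step)
    rho <- sqrt(xp^2 + yp^2)
    if (rho > radius) {
      rn <- max(min(2 * radius - rho, radius), 0)
      xp <- xp * rn / rho
      yp <- yp * rn / rho
    }
    x[k] <- xp
    y[k] <- yp
  }
  make_segment(x + stats::rnorm(n, 0, sigma), y + stats::rnorm(n, 0, sigma),
               uncertainty = sigma)
}

# brute-force time-averaged MSD: double loop over all index pairs, the
# independent oracle for compute_msd()
msd_bruteforce <- function(seg, max_lag_fraction = 0.6, dt = 0.02) {
  seg <- seg[order(seg$frame), ]
  span <- max(seg$frame) - min(seg$frame)
  max_lag <- max(1L, floor(max_lag_fraction * span))
  msd <- rep(NA_real_, max_lag)
  n_pairs <- integer(max_lag)
  for (lag in seq_len(max_lag)) {
    acc <- c()
    for (i in seq_len(nrow(seg))) {
      j <- which(seg$frame == seg$frame[i] + lag)
      if (length(j) == 1) {
        acc <- c(acc, (seg$x[j] - seg$x[i])^2 + (seg$y[j] - seg$y[i])^2)
      }
    }
    n_pairs[lag] <- length(acc)
    if (length(acc) > 0) msd[lag] <- mean(acc)
  }
  tibble::tibble(lag = seq_len(max_lag), t = seq_len(max_lag) * dt,
                 msd = msd, n_pairs = n_pairs)
}

# a small resting-state experiment reused by several pipeline tests
small_experiment <- function(n_cells = 3, n_emitters = 80, seed = 42,
                             response = flat_profile()) {
  simulate_experiment(sim_config(
    n_cells = n_cells, n_emitters_per_cell = n_emitters,
    response = response, seed = seed
  ))
}
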