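#' Ground-truth mode fractions at a given time
#'
#' Evaluates the ligand-response kinetics of a [response_profile()] at time
#' `t` (minutes relative to ligand addition). Before the ligand (`t < 0`) the
#' baseline fractions are returned; the immobile fraction then rises linearly
#' to its peak at `t_peak` and relaxes exponentially toward the plateau with
#' time constant `decay_tau`. The confined fraction is constant; the free
#' fraction is the complement.
#'
#' @param t Time in minutes relative to ligand addition. Vectorized.
#' @param profile A [response_profile()].
#' @return A tibble with columns `t`, `f_imm`, `f_conf`, `f_free`; one row
#'   per element of `t`. Fractions are in `[0, 1]` and sum to 1.
#' @examples
#' response_fractions(c(-3, 0, 5, 15), response_profile())
#' @export
response_fractions <- function(t, profile = response_profile()) {
  if (!all(is.finite(t))) stop("`t` must be finite")
  if (!inherits(profile, "response_profile")) {
    stop("`profile` must be a response_profile()")
  }
  f_imm <- imm_fraction_at(t, profile)
  f_conf <- rep(profile$f_conf, length(t))
  tibble::tibble(
    t = t,
    f_imm = f_imm,
    f_conf = f_conf,
    f_free = 1 - f_imm - f_conf
  )
}

# piecewise response law shared by fractions and the free-D dip
imm_fraction_at <- function(t, p) {
  ifelse(
    t < 0,
    p$baseline_f_imm,
    ifelse(
      t <= p$t_peak,
      p$baseline_f_imm + (p$peak_f_imm - p$baseline_f_imm) * t / p$t_peak,
      p$plateau_f_imm +
        (p$peak_f_imm - p$plateau_f_imm) * exp(-(t - p$t_peak) / p$decay_tau)
    )
  )
}

# free-D multiplier in (0, 1]: dips by D_free_dip_fraction with the same
# rise/relaxation shape as the immobile response, lagged by t_D_lag
free_d_factor_at <- function(t, p) {
  if (p$D_free_dip_fraction == 0 || p$peak_f_imm == p$baseline_f_imm) {
    return(rep(1, length(t)))
  }
  shape <- (imm_fraction_at(t - p$t_D_lag, p) - p$baseline_f_imm) /
    (p$peak_f_imm - p$baseline_f_imm)
  1 - p$D_free_dip_fraction * pmax(shape, 0)
}

#' Simulate one cell's localization table with ground truth
#'
#' Draws a diffusion mode for each emitter from the ground-truth fractions at
#' the cell's timestamp, simulates 2D trajectories (static, confined to a
#' reflecting circular corral, or free Brownian with per-axis step variance
#' `2 * D * dt`), terminates each trajectory after a geometric number of
#' frames (parameter `p_bleach`), and records every true position plus
#' isotropic Gaussian localization noise of s.d. `sigma_loc` per axis.
#' Emitters appear at random frames so the per-frame density stays low and
#' roughly constant over the movie.
#'
#' @param cfg A [sim_config()].
#' @param t_cell Cell timestamp, minutes relative to ligand addition.
#' @param cell_id Identifier stamped on the output rows.
#' @return A list with elements
#'   \describe{
#'     \item{locs}{tibble of localizations: `frame` (0-based), `x`, `y`
#'       (um), `uncertainty` (um), `id` (ground-truth emitter id), and the
#'       noise-free coordinates `x_true`, `y_true`.}
#'     \item{truth}{tibble of per-emitter ground truth: `id`, `mode`,
#'       `D_true` (um^2/s), `start_frame`, `n_frames_true`.}
#'     \item{fractions}{the ground-truth mode fractions used for the draw.}
#'   }
#' @export
simulate_cell <- function(cfg, t_cell = -5, cell_id = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  fr <- response_fractions(t_cell, cfg$response)
  f <- c(imm = fr$f_imm, conf = fr$f_conf, free = fr$f_free)
  if (cfg$cell_jitter_sd > 0) {
    jit <- stats::rnorm(1, 0, cfg$cell_jitter_sd)
    f["imm"] <- min(max(f["imm"] + jit, 0), 1 - f["conf"])
    f["free"] <- 1 - f["imm"] - f["conf"]
  }
  n <- cfg$n_emitters_per_cell
  modes <- sample(c("immobile", "confined", "free"),
    size = n, replace = TRUE, prob = f
  )
  d_free_cell <- cfg$D_free * free_d_factor_at(t_cell, cfg$response)
  D_true <- c(
    immobile = 0, confined = cfg$D_conf, free = d_free_cell
  )[modes]

  # geometric survival: an emitter localized in its first frame survives each
  # subsequent frame with probability (1 - p_bleach)
  start_frame <- sample.int(cfg$n_frames, n, replace = TRUE) - 1L
  n_frames_true <- stats::rgeom(n, cfg$p_bleach) + 1L
  n_obs <- pmin(n_frames_true, cfg$n_frames - start_frame)

  sd_step <- sqrt(2 * D_true * cfg$dt)
  origin_x <- stats::runif(n, 0, cfg$fov[1])
  origin_y <- stats::runif(n, 0, cfg$fov[2])

  tracks <- vector("list", n)
  for (i in seq_len(n)) {
    m <- n_obs[i]
    if (modes[i] == "immobile" || sd_step[i] == 0) {
      x <- rep(origin_x[i], m)
      y <- rep(origin_y[i], m)
    } else if (modes[i] == "free") {
      x <- origin_x[i] + cumsum(c(0, stats::rnorm(m - 1, 0, sd_step[i])))
      y <- origin_y[i] + cumsum(c(0, stats::rnorm(m - 1, 0, sd_step[i])))
    } else {
      w <- confined_walk(m, sd_step[i], cfg$confinement_radius)
      x <- origin_x[i] + w$x
      y <- origin_y[i] + w$y
    }
    tracks[[i]] <- tibble::tibble(
      frame = start_frame[i] + seq_len(m) - 1L,
      x = x, y = y, id = i
    )
  }
  locs <- dplyr::bind_rows(tracks)
  locs$x_true <- locs$x
  locs$y_true <- locs$y
  if (cfg$sigma_loc > 0) {
    locs$x <- locs$x + stats::rnorm(nrow(locs), 0, cfg$sigma_loc)
    locs$y <- locs$y + stats::rnorm(nrow(locs), 0, cfg$sigma_loc)
  }
  locs$uncertainty <- cfg$sigma_loc
  locs <- dplyr::arrange(locs, .data$frame, .data$id)
  locs <- locs[, c("frame", "x", "y", "uncertainty", "id", "x_true", "y_true")]

  list(
    locs = locs,
    truth = tibble::tibble(
      id = seq_len(n), mode = modes, D_true = unname(D_true),
      start_frame = start_frame, n_frames_true = n_frames_true
    ),
    fractions = tibble::tibble(
      cell_id = cell_id, t_min = t_cell,
      f_imm = unname(f["imm"]), f_conf = unname(f["conf"]),
      f_free = unname(f["free"])
    )
  )
}

# Brownian walk inside a reflecting disc of radius r centred on the start
confined_walk <- function(m, sd_step, r) {
  x <- numeric(m)
  y <- numeric(m)
  for (k in seq_len(m)[-1]) {
    xp <- x[k - 1] + stats::rnorm(1, 0, sd_step)
    yp <- y[k - 1] + stats::rnorm(1, 0, sd_step)
    rho <- sqrt(xp^2 + yp^2)
    if (rho > r) {
      # radial reflection at the corral boundary
      rho_new <- 2 * r - rho
      rho_new <- max(min(rho_new, r), 0)
      xp <- xp * rho_new / rho
      yp <- yp * rho_new / rho
    }
    x[k] <- xp
    y[k] <- yp
  }
  list(x = x, y = y)
}

#' Simulate the sequential multi-cell ligand experiment
#'
#' Emulates the acquisition design in which cells are imaged one after
#' another over ~30 minutes and the ligand is added after the fifth cell:
#' each cell receives its own timestamp, cells imaged before `ligand_time`
#' are labeled `"resting"`, the remainder `"stimulated"`, and each cell's
#' ground-truth mode fractions follow the configured [response_profile()]
#' evaluated at its timestamp.
#'
#' @param cfg A [sim_config()]. `cfg$seed` seeds the simulation.
#' @return A tibble with one row per cell: `cell_id`, `t_min` (minutes
#'   relative to ligand addition), `condition`, and list-columns `locs` and
#'   `truth` as returned by [simulate_cell()], plus the ground-truth
#'   fractions `f_imm_true`, `f_conf_true`, `f_free_true`.
#' @examples
#' cfg <- sim_config(n_cells = 3, n_emitters_per_cell = 20, seed = 7)
#' simulate_experiment(cfg)
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  # uniform spacing over total_time; timestamps relative to ligand addition
  t_abs <- (seq_len(cfg$n_cells) - 1) / cfg$n_cells * cfg$total_time
  t_min <- t_abs - cfg$ligand_time
  condition <- ifelse(t_min < 0, "resting", "stimulated")

  cells <- purrr::map(seq_len(cfg$n_cells), function(i) {
    sim <- simulate_cell(cfg, t_cell = t_min[i], cell_id = i)
    tibble::tibble(
      cell_id = i, t_min = t_min[i], condition = condition[i],
      f_imm_true = sim$fractions$f_imm,
      f_conf_true = sim$fractions$f_conf,
      f_free_true = sim$fractions$f_free,
      locs = list(sim$locs), truth = list(sim$truth)
    )
  })
  dplyr::bind_rows(cells)
}
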