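#' Ligand-response profile for the synthetic experiment
#'
#' Describes how the ground-truth immobile fraction of a receptor population
#' responds to ligand addition at time 0: baseline before the ligand, a linear
#' rise to a peak at `t_peak`, then exponential relaxation toward a plateau
#' with time constant `decay_tau`. The confined fraction is held fixed and the
#' free fraction absorbs the complement, mirroring the observed
#' immobilization-at-the-expense-of-free-diffusion phenomenology.
#'
#' A plateau above baseline encodes an EGF-like response (no return to the
#' resting level within the experiment); a plateau equal to baseline encodes a
#' TGF-alpha-like transient response.
#'
#' @param baseline_f_imm Immobile fraction before ligand addition.
#' @param peak_f_imm Immobile fraction at the response peak. Must be >=
#'   `baseline_f_imm`.
#' @param t_peak Time of the peak, minutes after ligand addition (> 0).
#' @param decay_tau Relaxation time constant, minutes (> 0).
#' @param plateau_f_imm Immobile fraction the response relaxes toward.
#' @param f_conf Confined fraction, held constant over time.
#' @param D_free_dip_fraction Fractional dip of the free diffusion
#'   coefficient at the peak (0 = no dip), applied with the same time course
#'   as the immobile response but lagged by `t_D_lag`.
#' @param t_D_lag Lag of the free-D response relative to the immobile-fraction
#'   response, minutes.
#' @return An object of class `response_profile`.
#' @seealso [response_fractions()]
#' @export
response_profile <- function(baseline_f_imm = 0.105,
                             peak_f_imm = 0.295,
                             t_peak = 5,
                             decay_tau = 10,
                             plateau_f_imm = 0.17,
                             f_conf = 0.281,
                             D_free_dip_fraction = 0.15,
                             t_D_lag = 0) {
  stopifnot(
    is.numeric(baseline_f_imm), baseline_f_imm >= 0, baseline_f_imm <= 1,
    peak_f_imm >= baseline_f_imm, peak_f_imm <= 1,
    t_peak > 0, decay_tau > 0,
    plateau_f_imm >= 0, plateau_f_imm <= 1,
    f_conf >= 0, f_conf <= 1,
    D_free_dip_fraction >= 0, D_free_dip_fraction <= 1
  )
  if (max(baseline_f_imm, peak_f_imm, plateau_f_imm) + f_conf > 1) {
    stop("immobile + confined fractions exceed 1 somewhere on the profile")
  }
  structure(
    list(
      baseline_f_imm = baseline_f_imm, peak_f_imm = peak_f_imm,
      t_peak = t_peak, decay_tau = decay_tau,
      plateau_f_imm = plateau_f_imm, f_conf = f_conf,
      D_free_dip_fraction = D_free_dip_fraction, t_D_lag = t_D_lag
    ),
    class = "response_profile"
  )
}

#' A flat (null) response profile
#'
#' Convenience constructor for a profile with no ligand response: the mode
#' fractions are constant in time. Useful as a negative control in pipeline
#' tests.
#'
#' @param f_imm,f_conf Constant immobile and confined fractions.
#' @return A `response_profile` whose peak and plateau equal the baseline.
#' @export
flat_profile <- function(f_imm = 0.105, f_conf = 0.281) {
  p <- response_profile(
    baseline_f_imm = f_imm, peak_f_imm = f_imm, plateau_f_imm = f_imm,
    f_conf = f_conf, D_free_dip_fraction = 0
  )
  p
}

#' Simulation configuration for the synthetic SPT experiment
#'
#' Bundles ground-truth diffusion, photophysics and acquisition parameters for
#' the sequential multi-cell experiment emulated by [simulate_experiment()].
#' Defaults reflect the acquisition design of the study the pipeline targets:
#' 1000 frames per cell at 20 ms integration, 25 cells imaged sequentially
#' over about 30 minutes, ligand added after the fifth cell.
#'
#' @param n_cells Number of cells imaged sequentially.
#' @param n_frames Frames per movie.
#' @param dt Frame time, seconds.
#' @param pixel_size Camera pixel size, micrometres (metadata only; positions
#'   are continuous).
#' @param fov Field of view, micrometres, length-2 numeric (x, y extent).
#' @param n_emitters_per_cell Emitters simulated per cell.
#' @param D_free Free-diffusion coefficient, um^2/s.
#' @param D_conf Diffusion coefficient inside confinement zones, um^2/s.
#' @param confinement_radius Radius of the reflecting circular corral, um.
#' @param sigma_loc Static localization precision (per-axis Gaussian noise
#'   s.d.), um.
#' @param p_bleach Per-frame photobleaching probability; trajectory durations
#'   are geometric with this parameter.
#' @param total_time Duration of the sequential experiment, minutes.
#' @param ligand_time Time of ligand addition, minutes after the start of the
#'   experiment.
#' @param response A [response_profile()].
#' @param cell_jitter_sd Optional s.d. of a per-cell jitter added to the
#'   ground-truth immobile fraction (cell-to-cell heterogeneity); 0 disables.
#' @param seed Integer seed for reproducible simulation.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 25,
                       n_frames = 1000,
                       dt = 0.020,
                       pixel_size = 0.105,
                       fov = c(20, 20),
                       n_emitters_per_cell = 300,
                       D_free = 0.15,
                       D_conf = 0.10,
                       confinement_radius = 0.14,
                       sigma_loc = 0.02,
                       p_bleach = 0.064,
                       total_time = 25,
                       ligand_time = 5,
                       response = response_profile(),
                       cell_jitter_sd = 0,
                       seed = 1L) {
  stopifnot(
    n_cells >= 1, n_frames >= 2, dt > 0, pixel_size > 0,
    length(fov) == 2, all(fov > 0),
    n_emitters_per_cell >= 1,
    D_free >= 0, D_conf >= 0, confinement_radius > 0,
    sigma_loc >= 0, p_bleach > 0, p_bleach <= 1,
    total_time > 0, ligand_time >= 0, ligand_time < total_time,
    cell_jitter_sd >= 0
  )
  if (!inherits(response, "response_profile")) {
    stop("`response` must be a response_profile()")
  }
  if (any(fov < 4 * confinement_radius)) {
    stop("field of view too small for the confinement radius")
  }
  structure(
    list(
      n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
      dt = dt, pixel_size = pixel_size, fov = fov,
      n_emitters_per_cell = as.integer(n_emitters_per_cell),
      D_free = D_free, D_conf = D_conf,
      confinement_radius = confinement_radius,
      sigma_loc = sigma_loc, p_bleach = p_bleach,
      total_time = total_time, ligand_time = ligand_time,
      response = response, cell_jitter_sd = cell_jitter_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d cells x %d frames @ %.0f ms, %d emitters/cell\n",
    x$n_cells, x$n_frames, x$dt * 1000, x$n_emitters_per_cell
  ))
  cat(sprintf(
    "  D_free %.3g, D_conf %.3g um^2/s, r_conf %.3g um, sigma_loc %.3g um\n",
    x$D_free, x$D_conf, x$confinement_radius, x$sigma_loc
  ))
  cat(sprintf(
    "  p_bleach %.3g/frame, ligand at %g min of %g min\n",
    x$p_bleach, x$ligand_time, x$total_time
  ))
  invisible(x)
}
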