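#' Classify a segment's diffusion mode
#'
#' Three-state classification of a trajectory segment:
#' \enumerate{
#'   \item \strong{immobile} if the fitted diffusion coefficient falls
#'     strictly below the threshold `d_min` (a segment at exactly `d_min` is
#'     mobile), or if the MSD carries no signal above the localization-noise
#'     floor (degenerate curves included);
#'   \item otherwise the anomalous-diffusion law
#'     `msd(t) = 4 * Gamma * t^alpha + c` is fitted in the log domain over
#'     the short-lag region after subtracting the noise offset
#'     `c = 4 * sigma_loc^2`, and the segment is called \strong{confined}
#'     when the upper confidence bound of the anomalous exponent lies below
#'     1 (`alpha + z * SE(alpha) < 1`), \strong{free} otherwise.
#' }
#'
#' The log-domain fit is a generalized least squares with the analytic
#' per-lag relative variance of a time-averaged MSD,
#' `(2 n^2 + 1) / (3 n (N - n + 1))` for lag `n` of an `N`-point segment,
#' propagated through the offset subtraction, and with a second-order
#' correction for the log transform's downward bias. Only the short-lag
#' region (lags up to `alpha_lag_cap`) enters the fit: that is where the
#' variance model holds and where confinement curvature is informative,
#' while long single-trajectory lags are dominated by correlated noise.
#' For segments of 60+ localizations a log-spaced subset of those lags is
#' used — adjacent mid-range points of a time-averaged MSD are nearly
#' redundant, and thinning them keeps the independent-error standard
#' errors calibrated; short segments use every lag.
#'
#' @param fit A `diffusion_fit` for the segment (from
#'   [fit_diffusion_coefficient()]).
#' @param msd The segment's MSD tibble (from [compute_msd()]).
#' @param d_min Immobility threshold, um^2/s.
#' @param sigma_loc Localization precision of the segment (um), used as the
#'   noise offset in the anomalous fit. When `NULL`, the MSD-intercept
#'   estimate `fit$sigma_dyn` is used instead (note: for strongly confined
#'   motion the intercept absorbs part of the plateau, so the reported
#'   per-localization precision is preferred whenever available).
#' @param z Normal quantile for the confinement test (default 1.96, a 95%
#'   one-sided bound).
#' @param alpha_lag_cap Maximum number of lags in the anomalous fit.
#' @return A one-row tibble: `mode` (factor immobile/confined/free),
#'   `alpha`, `alpha_se` (`NA` for immobile calls), `d_min`.
#' @export
classify_segment <- function(fit, msd, d_min, sigma_loc = NULL, z = 1.96,
                             alpha_lag_cap = 10) {
  stopifnot(inherits(fit, "diffusion_fit"), d_min >= 0)
  out <- function(mode, alpha = NA_real_, alpha_se = NA_real_) {
    tibble::tibble(
      mode = factor(mode, levels = c("immobile", "confined", "free")),
      alpha = alpha, alpha_se = alpha_se, d_min = d_min
    )
  }
  usable <- msd[!is.na(msd$msd), ]
  if (nrow(usable) == 0 || all(usable$msd == 0)) {
    return(out("immobile")) # degenerate: no measurable displacement
  }
  if (fit$D < d_min) {
    return(out("immobile"))
  }
  c0 <- if (!is.null(sigma_loc) && is.finite(sigma_loc)) {
    4 * sigma_loc^2
  } else if (!is.na(fit$sigma_dyn)) {
    min(4 * fit$sigma_dyn^2, 0.9 * max(usable$msd))
  } else {
    0
  }
  # N: segment length governing the MSD variance model; n_pairs at lag 1 is
  # the number of consecutive-frame pairs, i.e. N - 1 for gap-free segments
  n_points <- if ("n_pairs" %in% names(usable)) {
    usable$n_pairs[1] + 1L
  } else {
    max(usable$lag) + 1L
  }
  af <- fit_alpha_gls(usable, c0 = c0, n_points = n_points,
                      max_lags = alpha_lag_cap)
  if (is.na(af$alpha)) {
    # no lag rises above the noise floor: mobility indistinguishable from 0
    return(out("immobile"))
  }
  mode <- if (af$alpha + z * af$alpha_se < 1) "confined" else "free"
  out(mode, af$alpha, af$alpha_se)
}

# log-domain GLS fit of log(msd - c0) ~ log(t) with analytic per-lag
# relative variances for a time-averaged MSD of an n_points trajectory
# (Qian-type error model), delta-method propagation through the offset
# subtraction, and Jensen bias correction of the log transform.
# Lag selection is length-adaptive: short segments use every lag up to the
# cap (each carries unique information), long segments use a log-spaced
# subset (adjacent mid-range lags of a time-averaged MSD are nearly
# redundant, and thinning them keeps the independent-error SE calibrated)
fit_alpha_gls <- function(msd, c0, n_points, max_lags = 10, long_n = 60) {
  lag_set <- if (n_points >= long_n) {
    c(1L, 2L, 3L, 5L, 7L, 10L)
  } else {
    seq_len(max_lags)
  }
  pts <- msd[!is.na(msd$msd) & msd$lag %in% lag_set, ]
  y <- pts$msd - c0
  keep <- y > 0
  pts <- pts[keep, ]
  y <- y[keep]
  if (nrow(pts) < 3) {
    return(list(alpha = NA_real_, alpha_se = NA_real_))
  }
  n <- pts$lag
  relvar <- (2 * n^2 + 1) / (3 * n * (n_points - n + 1))
  v <- relvar * (pts$msd / y)^2 # var of log(y) by the delta method
  zlog <- log(y) + v / 2 # first-order Jensen correction
  X <- cbind(1, log(pts$t))
  W <- diag(1 / v, nrow = length(v))
  xtwxi <- tryCatch(solve(t(X) %*% W %*% X), error = function(e) NULL)
  if (is.null(xtwxi)) {
    return(list(alpha = NA_real_, alpha_se = NA_real_))
  }
  beta <- xtwxi %*% t(X) %*% W %*% zlog
  list(alpha = beta[2, 1], alpha_se = sqrt(xtwxi[2, 2]))
}

#' Fit and classify every segment of a cell
#'
#' Applies the per-segment analysis chain — MSD, 4-point diffusion fit,
#' mode classification — to each linked segment, after discarding segments
#' shorter than `min_segment_length` localizations.
#'
#' When `d_min = NULL` the threshold is computed from the data at hand via
#' [compute_d_min()] (pooled third quartile of the segments' dynamic
#' localization precisions); pass a number (e.g. [d_min_override()]) to use
#' a fixed threshold.
#'
#' @param segments Linked localization tibble (from [link_localizations()]),
#'   with columns `segment_id`, `frame`, `x`, `y`.
#' @param dt Frame time, seconds.
#' @param n_fit Lags in the diffusion fit (default 4).
#' @param min_segment_length Minimum localizations per analyzed segment
#'   (default 20).
#' @param max_lag_fraction Largest MSD lag as a fraction of segment span.
#' @param d_min Immobility threshold in um^2/s, or `NULL` to derive it from
#'   these segments.
#' @param z Confidence multiplier for the confinement call.
#' @return A tibble with one row per surviving segment: `segment_id`,
#'   `n_locs`, `D`, `intercept`, `sigma_dyn`, `alpha`, `alpha_se`, `mode`,
#'   `d_min`.
#' @export
analyze_segments <- function(segments, dt = 0.02, n_fit = 4,
                             min_segment_length = 20,
                             max_lag_fraction = 0.6,
                             d_min = NULL, z = 1.96) {
  keep <- segment_durations(segments)
  keep <- keep$segment_id[keep$n_locs >= min_segment_length]
  segments <- segments[segments$segment_id %in% keep, ]
  if (nrow(segments) == 0) {
    return(tibble::tibble(
      segment_id = integer(), n_locs = integer(), D = numeric(),
      intercept = numeric(), sigma_dyn = numeric(), alpha = numeric(),
      alpha_se = numeric(),
      mode = factor(character(), levels = c("immobile", "confined", "free")),
      d_min = numeric()
    ))
  }
  per_seg <- lapply(split(segments, segments$segment_id), function(seg) {
    msd <- compute_msd(seg, max_lag_fraction = max_lag_fraction, dt = dt)
    fit <- fit_diffusion_coefficient(msd, n_fit = n_fit)
    sig <- if ("uncertainty" %in% names(seg)) mean(seg$uncertainty) else NULL
    list(seg_id = seg$segment_id[1], n_locs = nrow(seg), msd = msd, fit = fit,
         sigma_loc = sig)
  })
  fits <- tibble::tibble(
    segment_id = vapply(per_seg, function(s) as.integer(s$seg_id), integer(1)),
    n_locs = vapply(per_seg, function(s) s$n_locs, integer(1)),
    D = vapply(per_seg, function(s) s$fit$D, numeric(1)),
    intercept = vapply(per_seg, function(s) s$fit$intercept, numeric(1)),
    sigma_dyn = vapply(per_seg, function(s) s$fit$sigma_dyn, numeric(1))
  )
  if (is.null(d_min)) d_min <- compute_d_min(fits$sigma_dyn, dt = dt)
  labels <- dplyr::bind_rows(lapply(per_seg, function(s) {
    classify_segment(s$fit, s$msd, d_min = d_min, sigma_loc = s$sigma_loc,
                     z = z)
  }))
  dplyr::bind_cols(fits, labels)
}

#' Summarize one cell's diffusion properties
#'
#' Aggregates a cell's analyzed segments into the per-cell summary on which
#' all cohort statistics are computed: global diffusion coefficient (mean of
#' segment `D`), mode fractions, and per-mode mean diffusion coefficients.
#' Negative fitted `D` values (pure noise) count toward classification but
#' are excluded from the reported per-mode means of the mobile modes.
#'
#' @param segments Linked localization tibble for one cell.
#' @param cell_id,t_min,condition Metadata stamped on the summary row.
#' @inheritParams analyze_segments
#' @return A one-row tibble: `cell_id`, `t_min`, `condition`, `n_segments`,
#'   `D_global`, `f_imm`, `f_conf`, `f_free`, `D_imm`, `D_conf`, `D_free`,
#'   `mean_segment_length`, `d_min`. If no segment survives the length
#'   filter, a row with `n_segments = 0` and `NA` properties is returned
#'   (excluded from cohort means downstream).
#' @export
analyze_cell <- function(segments, cell_id = 1L, t_min = NA_real_,
                         condition = NA_character_, dt = 0.02, n_fit = 4,
                         min_segment_length = 20, max_lag_fraction = 0.6,
                         d_min = NULL, z = 1.96) {
  seg_stats <- analyze_segments(
    segments,
    dt = dt, n_fit = n_fit, min_segment_length = min_segment_length,
    max_lag_fraction = max_lag_fraction, d_min = d_min, z = z
  )
  empty <- tibble::tibble(
    cell_id = cell_id, t_min = t_min, condition = condition,
    n_segments = 0L, D_global = NA_real_,
    f_imm = NA_real_, f_conf = NA_real_, f_free = NA_real_,
    D_imm = NA_real_, D_conf = NA_real_, D_free = NA_real_,
    mean_segment_length = NA_real_, d_min = NA_real_
  )
  if (nrow(seg_stats) == 0) {
    return(empty)
  }
  mode_mean_d <- function(m, positive_only) {
    d <- seg_stats$D[seg_stats$mode == m]
    if (positive_only) d <- d[d > 0]
    if (length(d) == 0) NA_real_ else mean(d)
  }
  tibble::tibble(
    cell_id = cell_id, t_min = t_min, condition = condition,
    n_segments = nrow(seg_stats),
    D_global = mean(seg_stats$D),
    f_imm = mean(seg_stats$mode == "immobile"),
    f_conf = mean(seg_stats$mode == "confined"),
    f_free = mean(seg_stats$mode == "free"),
    D_imm = mode_mean_d("immobile", positive_only = FALSE),
    D_conf = mode_mean_d("confined", positive_only = TRUE),
    D_free = mode_mean_d("free", positive_only = TRUE),
    mean_segment_length = mean(seg_stats$n_locs),
    d_min = seg_stats$d_min[1]
  )
}

#' Analyze every cell of an experiment
#'
#' Maps [link_localizations()] and [analyze_cell()] over the cells of a
#' simulated or loaded experiment, producing the per-cell summary table the
#' time-course and statistics modules consume.
#'
#' The immobility threshold is pooled across the experiment's cells
#' (computed once from all segments' dynamic localization precisions) unless
#' a fixed `d_min` is given.
#'
#' @param experiment Tibble with one row per cell: `cell_id`, `t_min`,
#'   `condition` and a `locs` list-column of localization tables (the shape
#'   returned by [simulate_experiment()]).
#' @param params [tracking_params()] for the linker.
#' @inheritParams analyze_segments
#' @return Per-cell summary tibble (rows from [analyze_cell()]).
#' @export
analyze_cells <- function(experiment, params = tracking_params(),
                          dt = 0.02, n_fit = 4, min_segment_length = 20,
                          max_lag_fraction = 0.6, d_min = NULL, z = 1.96) {
  stopifnot(all(c("cell_id", "t_min", "condition", "locs") %in% names(experiment)))
  linked <- purrr::map(experiment$locs, link_localizations, params = params)

  if (is.null(d_min)) {
    # pooled threshold: Q3 of sigma_dyn over all cells' surviving segments
    sig <- purrr::map(linked, function(segs) {
      st <- analyze_segments(
        segs,
        dt = dt, n_fit = n_fit,
        min_segment_length = min_segment_length,
        max_lag_fraction = max_lag_fraction, d_min = Inf
      )
      st$sigma_dyn
    })
    d_min <- compute_d_min(unlist(sig), dt = dt)
  }

  purrr::list_rbind(purrr::pmap(
    list(linked, experiment$cell_id, experiment$t_min, experiment$condition),
    function(segs, id, t, cond) {
      analyze_cell(
        segs,
        cell_id = id, t_min = t, condition = cond, dt = dt, n_fit = n_fit,
        min_segment_length = min_segment_length,
        max_lag_fraction = max_lag_fraction, d_min = d_min, z = z
      )
    }
  ))
}
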