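#' Time-averaged mean squared displacement of a segment
#'
#' For each lag `n`, averages the squared displacement over every pair of
#' localizations `n` frames apart:
#' `msd(n) = mean[(x_{i+n} - x_i)^2 + (y_{i+n} - y_i)^2]`.
#' Lags run from 1 up to `max_lag_fraction` of the segment's frame span.
#' Segments with internal gaps contribute only displacement pairs whose both
#' endpoints were observed; the per-lag pair counts are reported.
#'
#' @param seg Tibble with columns `frame`, `x`, `y` (um) for one segment.
#' @param max_lag_fraction Largest lag as a fraction of the frame span
#'   (default 0.6).
#' @param dt Frame time in seconds, used for the lag-time axis.
#' @return A tibble with columns `lag` (frames), `t` (seconds), `msd`
#'   (um^2), `n_pairs`.
#' @examples
#' seg <- tibble::tibble(frame = 0:4, x = c(0, 1, 1, 2, 2), y = c(0, 0, 1, 1, 2))
#' compute_msd(seg, max_lag_fraction = 1)
#' @export
compute_msd <- function(seg, max_lag_fraction = 0.6, dt = 0.02) {
  stopifnot(all(c("frame", "x", "y") %in% names(seg)))
  if (nrow(seg) < 2) stop("segment must have at least 2 localizations")
  seg <- seg[order(seg$frame), ]
  span <- max(seg$frame) - min(seg$frame)
  max_lag <- max(1L, floor(max_lag_fraction * span))

  # index positions by frame offset so gaps are skipped, not interpolated
  offset <- seg$frame - min(seg$frame)
  x <- rep(NA_real_, span + 1)
  y <- rep(NA_real_, span + 1)
  x[offset + 1] <- seg$x
  y[offset + 1] <- seg$y

  lags <- seq_len(max_lag)
  msd <- numeric(max_lag)
  n_pairs <- integer(max_lag)
  for (n in lags) {
    dx <- x[seq_len(span + 1 - n) + n] - x[seq_len(span + 1 - n)]
    dy <- y[seq_len(span + 1 - n) + n] - y[seq_len(span + 1 - n)]
    sq <- dx^2 + dy^2
    ok <- !is.na(sq)
    n_pairs[n] <- sum(ok)
    msd[n] <- if (n_pairs[n] > 0) mean(sq[ok]) else NA_real_
  }
  tibble::tibble(lag = lags, t = lags * dt, msd = msd, n_pairs = n_pairs)
}

#' Fit a diffusion coefficient to the first points of an MSD curve
#'
#' Ordinary least squares of `msd` against lag time over the first `n_fit`
#' lags. For 2D Brownian motion `MSD(t) = 4 D t + 4 sigma_dyn^2`, so the
#' diffusion coefficient is slope/4 and the dynamic localization precision
#' `sigma_dyn = sqrt(intercept / 4)` when the intercept is positive
#' (undefined otherwise). Negative fitted `D` values are retained — they
#' carry information for the immobile classification and are never silently
#' clipped.
#'
#' @param msd MSD tibble from [compute_msd()].
#' @param n_fit Number of leading lags used for the fit (default 4).
#' @return An object of class `diffusion_fit` with elements `D` (um^2/s),
#'   `intercept` (um^2), `sigma_dyn` (um or `NA`), `residual_ss`, `n_fit`.
#'   Has [generics::tidy()] and [generics::glance()] methods.
#' @export
fit_diffusion_coefficient <- function(msd, n_fit = 4) {
  stopifnot(all(c("t", "msd") %in% names(msd)))
  usable <- msd[!is.na(msd$msd), ]
  if (nrow(usable) < n_fit) {
    stop(sprintf("MSD curve has %d usable lags; %d required", nrow(usable), n_fit))
  }
  pts <- usable[seq_len(n_fit), ]
  # closed-form simple OLS; equivalent to lm(msd ~ t)
  tb <- mean(pts$t)
  yb <- mean(pts$msd)
  slope <- sum((pts$t - tb) * (pts$msd - yb)) / sum((pts$t - tb)^2)
  intercept <- yb - slope * tb
  fitted <- intercept + slope * pts$t
  structure(
    list(
      D = slope / 4,
      slope = slope,
      intercept = intercept,
      sigma_dyn = if (intercept > 0) sqrt(intercept / 4) else NA_real_,
      residual_ss = sum((pts$msd - fitted)^2),
      n_fit = n_fit
    ),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "<diffusion_fit> D = %.4g um^2/s, intercept = %.4g um^2, sigma_dyn = %s\n",
    x$D, x$intercept,
    if (is.na(x$sigma_dyn)) "undefined" else sprintf("%.4g um", x$sigma_dyn)
  ))
  invisible(x)
}

#' Immobility threshold from the dynamic localization precision
#'
#' The immobile/mobile boundary `D_min` is derived from the third quartile
#' (Q3, linear-interpolation convention) of the dynamic localization
#' precision across segments: `D_min = Q3^2 / (4 dt)`, the apparent
#' diffusion coefficient a purely noise-limited emitter would show over one
#' frame interval. Published per-target values can be used instead via
#' `d_min_override()`.
#'
#' @param sigma_dyn Vector of dynamic localization precisions (um); `NA`s
#'   (undefined precisions from negative intercepts) are dropped.
#' @param dt Frame time, seconds.
#' @return `D_min` in um^2/s.
#' @examples
#' compute_d_min(c(0.01, 0.02, 0.03, 0.04), dt = 0.02) # ~0.0132
#' @export
compute_d_min <- function(sigma_dyn, dt = 0.02) {
  sigma_dyn <- sigma_dyn[!is.na(sigma_dyn)]
  if (length(sigma_dyn) == 0) stop("no defined sigma_dyn values")
  q3 <- unname(stats::quantile(sigma_dyn, 0.75, type = 7))
  q3^2 / (4 * dt)
}

#' Published immobility thresholds
#'
#' Fixed `D_min` values reported for the three labeled species, usable as
#' overrides in reproduction runs instead of [compute_d_min()].
#'
#' @param target One of `"HER2"`, `"TMD"`, `"GPI"`.
#' @return `D_min` in um^2/s.
#' @export
d_min_override <- function(target = c("HER2", "TMD", "GPI")) {
  target <- match.arg(target)
  c(HER2 = 0.0084, TMD = 0.0037, GPI = 0.0086)[[target]]
}
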