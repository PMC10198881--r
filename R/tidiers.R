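#' Tidy a diffusion fit
#'
#' Broom-style one-row-per-term view of the 4-point MSD fit.
#'
#' @param x A `diffusion_fit`.
#' @param ... Unused.
#' @return A tibble with `term` (`"slope"`, `"intercept"`) and `estimate`.
#' @exportS3Method generics::tidy
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept)
  )
}

#' Glance at a diffusion fit
#'
#' @param x A `diffusion_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `D`, `sigma_dyn`, `intercept`, `residual_ss`,
#'   `n_fit`.
#' @exportS3Method generics::glance
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(
    D = x$D, sigma_dyn = x$sigma_dyn, intercept = x$intercept,
    residual_ss = x$residual_ss, n_fit = x$n_fit
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
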