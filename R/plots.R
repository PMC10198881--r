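#' Plot an MSD curve with its diffusion fit
#'
#' @param msd MSD tibble from [compute_msd()].
#' @param fit Optional `diffusion_fit` overlaid as a line over its fitted
#'   lags.
#' @return A ggplot object.
#' @export
plot_msd <- function(msd, fit = NULL) {
  p <- ggplot2::ggplot(msd, ggplot2::aes(x = .data$t, y = .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "lag time (s)", y = expression(MSD ~ (mu * m^2))
    ) +
    ggplot2::theme_classic()
  if (!is.null(fit)) {
    seg <- msd[seq_len(min(fit$n_fit, nrow(msd))), ]
    seg$fitted <- fit$intercept + fit$slope * seg$t
    p <- p + ggplot2::geom_line(
      data = seg, ggplot2::aes(y = .data$fitted),
      colour = "firebrick"
    )
  }
  p
}

#' Plot per-condition diffusion-mode fractions
#'
#' Stacked per-condition mean fractions of immobile, confined and free
#' segments with SEM error bars, the summary view of a mode-fraction
#' comparison between treatment groups.
#'
#' @param cells Per-cell summary tibble.
#' @return A ggplot object.
#' @export
plot_mode_fractions <- function(cells) {
  long <- tidyr::pivot_longer(
    cells[cells$n_segments > 0, c("condition", "f_imm", "f_conf", "f_free")],
    -"condition",
    names_to = "mode", values_to = "fraction"
  )
  long$mode <- factor(long$mode,
    levels = c("f_imm", "f_conf", "f_free"),
    labels = c("immobile", "confined", "free")
  )
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$condition, .data$mode),
    mean = mean(.data$fraction), sem = stats::sd(.data$fraction) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$mode, y = .data$mean, fill = .data$condition
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.8), width = 0.2
    ) +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "fraction of segments") +
    ggplot2::theme_classic()
}

#' Plot a relative-change time course with SED error bars
#'
#' Dot plot of the percent change of a diffusion property versus the
#' pre-ligand baseline, per time bin, with standard-error-of-the-difference
#' bars — the time-resolved receptor-response view.
#'
#' @param rel Relative-change tibble from [relative_change()].
#' @return A ggplot object.
#' @export
plot_timecourse <- function(rel) {
  mid <- (rel$bin_start + rel$bin_start + diff(sort(unique(rel$bin_start)))[1]) / 2
  rel$t_mid <- mid
  ggplot2::ggplot(rel, ggplot2::aes(
    x = .data$t_mid, y = .data$rel_change_pct, colour = .data$property
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$rel_change_pct - .data$sed_pct,
        ymax = .data$rel_change_pct + .data$sed_pct
      ),
      width = 0.8
    ) +
    ggplot2::labs(
      x = "time after ligand addition (min)",
      y = "relative change (%)"
    ) +
    ggplot2::theme_classic()
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.spt_run <- function(object, ...) {
  plot_timecourse(object$rel_change)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
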