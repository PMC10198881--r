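#' Pool per-cell summaries into time bins
#'
#' Groups time-stamped cell summaries into half-open intervals
#' `[k*w, (k+1)*w)` minutes relative to ligand addition (a cell at exactly
#' t = 0 falls in the first post-ligand bin), starting at the `[-5, 0)`
#' baseline interval, and reports per-bin mean and standard error of the
#' mean for each diffusion property. Binning compensates cell-to-cell
#' heterogeneity that single-cell time stamps would otherwise inject into
#' the time course.
#'
#' @param cells Per-cell summary tibble (from [analyze_cells()]); cells with
#'   `n_segments = 0` are dropped. Timestamps `t_min` are minutes relative
#'   to ligand addition.
#' @param bin_width Bin width in minutes (1 or 5 in the original design;
#'   any positive width is accepted).
#' @param condition Optional label stamped on the output (useful when
#'   binning several ligands separately before [baseline_align()]).
#' @param properties Character vector of summary columns to aggregate.
#' @return A tibble with one row per bin and property: `condition`,
#'   `bin_start`, `bin_end`, `bin_label`, `n_cells`, `property`, `mean`,
#'   `sem`.
#' @export
assign_time_bins <- function(cells, bin_width = 5, condition = NULL,
                             properties = c(
                               "f_imm", "f_conf", "f_free",
                               "D_global", "D_imm", "D_conf", "D_free"
                             )) {
  stopifnot(bin_width > 0, "t_min" %in% names(cells))
  if (any(!is.finite(cells$t_min))) stop("every cell needs a finite timestamp")
  cells <- cells[cells$n_segments > 0, ]
  if (is.null(condition)) condition <- "all"

  bin_start <- floor(cells$t_min / bin_width) * bin_width
  cells$bin_start <- bin_start
  long <- tidyr::pivot_longer(
    cells[, c("bin_start", intersect(properties, names(cells)))],
    -"bin_start",
    names_to = "property", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$bin_start, .data$property),
    n_cells = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sem = stats::sd(.data$value, na.rm = TRUE) /
      sqrt(max(sum(!is.na(.data$value)), 1)),
    .groups = "drop"
  )
  out$bin_end <- out$bin_start + bin_width
  out$bin_label <- sprintf("[%g,%g)", out$bin_start, out$bin_end)
  out$condition <- condition
  out$property <- factor(out$property, levels = properties)
  dplyr::arrange(
    out[, c(
      "condition", "bin_start", "bin_end", "bin_label",
      "n_cells", "property", "mean", "sem"
    )],
    .data$bin_start, .data$property
  )
}

#' Align baseline mode fractions across conditions
#'
#' Corrects for fluctuations of the resting state between measurements by
#' shifting each condition's mode fractions so that its baseline
#' (`[-5, 0)`) fractions equal the grand mean baseline over all conditions.
#' The additive offset is applied to every bin of that condition, and the
#' three fractions are renormalized to sum to 1 per bin. Additive alignment
#' preserves the between-bin differences that the relative-change figures
#' display; a multiplicative variant is available. Non-fraction properties
#' (diffusion coefficients) pass through unaligned by default.
#'
#' @param binned Binned tibble from [assign_time_bins()], covering one or
#'   more conditions, each with a baseline bin starting at
#'   `baseline_start`.
#' @param baseline_start Left edge of the baseline interval (minutes).
#' @param mode How to align: `"additive"` (default) or `"multiplicative"`.
#' @param fractions The property names treated as mode fractions.
#' @return The input tibble with aligned `mean` values and a logical
#'   `aligned` column; raw means are preserved in `mean_raw`.
#' @export
baseline_align <- function(binned, baseline_start = -5,
                           mode = c("additive", "multiplicative"),
                           fractions = c("f_imm", "f_conf", "f_free")) {
  mode <- match.arg(mode)
  binned$mean_raw <- binned$mean
  binned$aligned <- binned$property %in% fractions

  base <- binned[binned$bin_start == baseline_start &
    binned$property %in% fractions, ]
  if (nrow(base) == 0) stop("no baseline bin at the requested interval")
  conds <- unique(binned$condition)
  miss <- setdiff(conds, unique(base$condition))
  if (length(miss) > 0) {
    stop("missing baseline bin for condition(s): ", paste(miss, collapse = ", "))
  }

  grand <- dplyr::summarise(
    dplyr::group_by(base, .data$property),
    grand_mean = mean(.data$mean), .groups = "drop"
  )
  base <- dplyr::left_join(base, grand, by = "property")
  base$offset <- base$grand_mean - base$mean
  base$scale <- ifelse(base$mean > 0, base$grand_mean / base$mean, 1)

  adj <- base[, c("condition", "property", "offset", "scale")]
  out <- dplyr::left_join(binned, adj, by = c("condition", "property"))
  out$offset[is.na(out$offset)] <- 0
  out$scale[is.na(out$scale)] <- 1
  out$mean <- if (mode == "additive") {
    out$mean + out$offset
  } else {
    out$mean * out$scale
  }
  out$offset <- NULL
  out$scale <- NULL

  # renormalize the three fractions within each condition x bin
  frac <- out$property %in% fractions
  key <- interaction(out$condition[frac], out$bin_start[frac], drop = TRUE)
  tot <- stats::ave(out$mean[frac], key, FUN = sum)
  out$mean[frac] <- out$mean[frac] / tot
  out
}

#' Relative change of a diffusion property versus baseline
#'
#' Expresses each time bin's mean as a percent change from the baseline
#' bin, `rc = (mean_bin - mean_base) / mean_base * 100`, with the standard
#' error of the difference (SED) propagated from the two bins' SEMs:
#' `SED = 100 * sqrt(sem_bin^2 + sem_base^2) / |mean_base|`. The baseline
#' bin maps to 0% by construction.
#'
#' @param binned Binned (optionally baseline-aligned) tibble.
#' @param property Which property to convert (e.g. `"f_imm"`, `"D_free"`).
#' @param baseline_start Left edge of the baseline interval.
#' @return A tibble per condition and bin: `condition`, `bin_start`,
#'   `bin_label`, `property`, `n_cells`, `rel_change_pct`, `sed_pct`.
#' @examples
#' # 10.5% immobile at baseline rising to 22.7% is a +116% change
#' @export
relative_change <- function(binned, property = "f_imm", baseline_start = -5) {
  sub <- binned[binned$property == property, ]
  if (nrow(sub) == 0) stop("property not present in binned data")
  base <- sub[sub$bin_start == baseline_start, ]
  if (nrow(base) == 0) stop("missing baseline bin")
  if (any(base$mean == 0)) stop("baseline mean is zero; relative change undefined")
  base <- base[, c("condition", "mean", "sem")]
  names(base) <- c("condition", "mean_base", "sem_base")
  out <- dplyr::left_join(sub, base, by = "condition")
  out$rel_change_pct <- (out$mean - out$mean_base) / out$mean_base * 100
  out$sed_pct <- 100 * sqrt(out$sem^2 + out$sem_base^2) / abs(out$mean_base)
  out[, c(
    "condition", "bin_start", "bin_label", "property",
    "n_cells", "rel_change_pct", "sed_pct"
  )]
}
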