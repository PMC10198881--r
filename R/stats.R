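#' Significance star label for a p value
#'
#' The conventional scheme: `p >= 0.05` no label, `p < 0.05` `"*"`,
#' `p < 0.01` `"**"`, `p < 0.001` `"***"`. Boundaries are strict: `p = 0.05`
#' is not significant.
#'
#' @param p Vector of p values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
star_label <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Shapiro-Wilk normality gate
#'
#' Records whether each group of per-cell values passes a Shapiro-Wilk
#' normality test at `alpha`. Matching the analysis scheme this pipeline
#' reproduces, the gate is diagnostic only: nonparametric tests are used
#' for group comparison regardless, because some populations reject
#' normality. Degenerate (constant) samples are recorded as non-normal.
#'
#' @param samples A list of numeric vectors (one per group), or a single
#'   numeric vector.
#' @param alpha Significance level of the gate.
#' @return A tibble: `group`, `n`, `W`, `p`, `normal`.
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  if (is.numeric(samples)) samples <- list(samples)
  if (is.null(names(samples))) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  purrr::list_rbind(purrr::imap(samples, function(x, nm) {
    x <- x[!is.na(x)]
    if (length(x) < 3) stop("normality test needs at least 3 values per group")
    if (stats::sd(x) == 0) {
      return(tibble::tibble(
        group = nm, n = length(x), W = NA_real_, p = NA_real_, normal = FALSE
      ))
    }
    sw <- stats::shapiro.test(x)
    tibble::tibble(
      group = nm, n = length(x),
      W = unname(sw$statistic), p = sw$p.value,
      normal = sw$p.value >= alpha
    )
  }))
}

#' Nonparametric two-group comparison with star labels
#'
#' Two-sided Mann-Whitney U test for independent groups (different
#' treatment conditions) or Wilcoxon signed-rank test for paired samples
#' (same treatment group), with the significance-star scheme applied to the
#' p value. The exact null distribution is used for small groups (both
#' n <= 20, no ties); larger or tied samples use the normal approximation
#' with continuity and tie correction.
#'
#' @param a,b Numeric vectors of per-cell values.
#' @param paired Use the Wilcoxon signed-rank test on paired differences;
#'   `a` and `b` must then have equal length.
#' @param labels Length-2 character vector naming the groups.
#' @param property Optional name of the compared property.
#' @return A one-row tibble: `property`, `group_a`, `group_b`, `test`,
#'   `statistic`, `p`, `label`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, paired = FALSE,
                           labels = c("A", "B"), property = NA_character_) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (paired) {
    if (length(a) != length(b)) stop("paired comparison needs equal lengths")
    test_name <- "Wilcoxon signed-rank"
  } else {
    if (length(a) < 3 || length(b) < 3) {
      stop("unpaired comparison needs at least 3 values per group")
    }
    test_name <- "Mann-Whitney U"
  }
  if (paired && all(a == b)) {
    # degenerate: every paired difference is zero, no evidence of change
    return(tibble::tibble(
      property = property, group_a = labels[1], group_b = labels[2],
      test = test_name, statistic = 0, p = 1, label = "",
      n_a = length(a), n_b = length(b)
    ))
  }
  exact <- !paired && length(a) <= 20 && length(b) <= 20 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(
    a, b,
    paired = paired, exact = exact, correct = TRUE,
    alternative = "two.sided"
  ))
  tibble::tibble(
    property = property,
    group_a = labels[1], group_b = labels[2],
    test = test_name,
    statistic = unname(wt$statistic),
    p = wt$p.value,
    label = star_label(wt$p.value),
    n_a = length(a), n_b = length(b)
  )
}

#' Build the per-condition comparison report
#'
#' Summarizes each diffusion property per condition (mean, SEM, n) and runs
#' pairwise Mann-Whitney U comparisons between all condition pairs, with
#' star labels. Raw p values are reported (no multiple-testing correction,
#' matching the star scheme reproduced here); Bonferroni correction can be
#' switched on.
#'
#' @param cells Per-cell summary tibble with a `condition` column.
#' @param properties Summary columns to compare.
#' @param bonferroni Apply Bonferroni correction across the pairwise tests
#'   of each property.
#' @param seed,config_hash Optional run metadata echoed into the report.
#' @return A list of class `spt_report`: `summaries` (condition x property
#'   means +/- SEM), `comparisons` (pairwise tests; empty with a single
#'   condition), `meta`.
#' @export
build_report <- function(cells, properties = c(
                           "D_global", "f_imm", "f_conf", "f_free",
                           "D_imm", "D_conf", "D_free"
                         ),
                         bonferroni = FALSE,
                         seed = NA_integer_, config_hash = NA_character_) {
  stopifnot("condition" %in% names(cells))
  cells <- cells[cells$n_segments > 0, ]
  conds <- unique(cells$condition)
  properties <- intersect(properties, names(cells))

  long <- tidyr::pivot_longer(
    cells[, c("condition", properties)], -"condition",
    names_to = "property", values_to = "value"
  )
  summaries <- dplyr::summarise(
    dplyr::group_by(long, .data$condition, .data$property),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sem = stats::sd(.data$value, na.rm = TRUE) /
      sqrt(max(sum(!is.na(.data$value)), 1)),
    .groups = "drop"
  )

  comparisons <- tibble::tibble()
  if (length(conds) >= 2) {
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    comparisons <- purrr::list_rbind(purrr::map(properties, function(pr) {
      purrr::list_rbind(purrr::map(pairs, function(pp) {
        a <- stats::na.omit(cells[[pr]][cells$condition == pp[1]])
        b <- stats::na.omit(cells[[pr]][cells$condition == pp[2]])
        if (length(a) < 3 || length(b) < 3) {
          return(tibble::tibble()) # too few cells for a meaningful test
        }
        compare_groups(a, b, labels = pp, property = pr)
      }))
    }))
    if (bonferroni && nrow(comparisons) > 0) {
      comparisons <- dplyr::mutate(
        dplyr::group_by(comparisons, .data$property),
        p = pmin(.data$p * dplyr::n(), 1),
        label = star_label(.data$p)
      )
      comparisons <- dplyr::ungroup(comparisons)
    }
  }

  structure(
    list(
      summaries = summaries,
      comparisons = comparisons,
      meta = list(
        n_cells = nrow(cells), conditions = conds,
        seed = seed, config_hash = config_hash,
        package_version = as.character(utils::packageVersion("sptmodes")),
        created = "run-time"
      )
    ),
    class = "spt_report"
  )
}

#' @export
print.spt_report <- function(x, ...) {
  cat("<spt_report>", x$meta$n_cells, "cells,",
      length(x$meta$conditions), "condition(s)\n")
  print(x$summaries, n = 20)
  if (nrow(x$comparisons) > 0) {
    cat("\nPairwise comparisons:\n")
    print(x$comparisons, n = 20)
  }
  invisible(x)
}
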