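#' Write a localization table in ThunderSTORM dialect
#'
#' Positions are stored in nanometres with the header
#' `frame,"x [nm]","y [nm]","uncertainty [nm]",id`; all internal
#' computation is in micrometres, so the conversion happens here and only
#' here. The `id` column (ground-truth emitter id) is written when present.
#'
#' @param locs Localization tibble (`frame`, `x`, `y`, `uncertainty` in um,
#'   optional `id`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  out <- tibble::tibble(
    frame = locs$frame,
    `x [nm]` = locs$x * 1000,
    `y [nm]` = locs$y * 1000,
    `uncertainty [nm]` = locs$uncertainty * 1000
  )
  if ("id" %in% names(locs)) out$id <- locs$id
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a ThunderSTORM-style localization table
#'
#' Accepts the nm-unit dialect written by [write_localizations()] (and by
#' ThunderSTORM exports with `frame`, `x [nm]`, `y [nm]`,
#' `uncertainty [nm]` columns). Positions are converted to micrometres.
#' The frame base is auto-detected: tables whose minimum frame is 1 are
#' shifted to the 0-based convention used internally, and the detection is
#' reported via a message.
#'
#' @param path CSV path.
#' @return Localization tibble: `frame` (0-based), `x`, `y`, `uncertainty`
#'   (um), plus `id` when present in the file.
#' @export
read_localizations <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  pick <- function(...) {
    nm <- intersect(c(...), names(raw))
    if (length(nm) == 0) stop("missing localization column: ", ..1)
    raw[[nm[1]]]
  }
  out <- tibble::tibble(
    frame = as.integer(pick("frame")),
    x = pick("x [nm]", "x") / 1000,
    y = pick("y [nm]", "y") / 1000,
    uncertainty = pick("uncertainty [nm]", "uncertainty [nm]_1", "uncertainty") / 1000
  )
  if ("id" %in% names(raw)) out$id <- raw$id
  if (nrow(out) > 0 && min(out$frame) == 1) {
    message("frame column is 1-based; shifting to 0-based")
    out$frame <- out$frame - 1L
  }
  out
}

#' Write / read linked segments
#'
#' Segments travel as flat CSV with micrometre units:
#' `cell_id,segment_id,frame,x_um,y_um,uncertainty_um`.
#'
#' @param segments Linked localization tibble; a `cell_id` column is added
#'   if absent.
#' @param path CSV path.
#' @param cell_id Cell id stamped on rows lacking one.
#' @return `path` (write) or the segments tibble with internal column names
#'   (read).
#' @export
write_segments <- function(segments, path, cell_id = 1L) {
  if (!"cell_id" %in% names(segments)) segments$cell_id <- cell_id
  out <- tibble::tibble(
    cell_id = segments$cell_id,
    segment_id = segments$segment_id,
    frame = segments$frame,
    x_um = segments$x,
    y_um = segments$y,
    uncertainty_um = segments$uncertainty
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  tibble::tibble(
    cell_id = raw$cell_id,
    segment_id = raw$segment_id,
    frame = as.integer(raw$frame),
    x = raw$x_um, y = raw$y_um,
    uncertainty = raw$uncertainty_um
  )
}

#' Write a simulated experiment to disk
#'
#' One localization CSV and one ground-truth JSON per cell, plus a manifest
#' CSV (`cell_id,t_min,condition,path`) tying them together.
#'
#' @param experiment Tibble from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_len(nrow(experiment)), function(i) {
    p <- file.path(dir, sprintf("cell_%03d.csv", experiment$cell_id[i]))
    write_localizations(experiment$locs[[i]], p)
    jsonlite::write_json(
      experiment$truth[[i]],
      file.path(dir, sprintf("cell_%03d_truth.json", experiment$cell_id[i])),
      dataframe = "columns", digits = NA
    )
    basename(p)
  }, character(1))
  manifest <- tibble::tibble(
    cell_id = experiment$cell_id,
    t_min = experiment$t_min,
    condition = experiment$condition,
    path = paths
  )
  mp <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mp)
  invisible(mp)
}

#' Read an experiment directory written by [write_experiment()]
#'
#' @param dir Directory containing `manifest.csv` and per-cell CSVs.
#' @return Experiment tibble with a `locs` list-column, suitable for
#'   [analyze_cells()].
#' @export
read_experiment <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
    show_col_types = FALSE
  )
  manifest$locs <- purrr::map(
    file.path(dir, manifest$path),
    function(p) suppressMessages(read_localizations(p))
  )
  manifest
}
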