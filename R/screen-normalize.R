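# Screen normalization: per-plate loess spatial correction with log2
# transform (primary screen mode), or plate-wise negative-control-median
# scaling (validation mode).

#' Read a per-well screen table
#'
#' Expects a delimited text file with one row per well and columns
#' `plate_id, row, col, reagent_id, reagent_class, cell_line, arm,
#' raw_signal` (a `normalized_viability` column is optional). Row/column
#' indices are 0-based; `reagent_class` must be one of
#' mimic/inhibitor/neg_control/pos_control/empty.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return a validated screen table data.frame.
#' @export
read_screen_table <- function(path, sep = "\t") {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  required <- setdiff(SCREEN_COLUMNS, "normalized_viability")
  stopifnot_columns(df, required, "screen table")
  if (!"normalized_viability" %in% names(df))
    df$normalized_viability <- NA_real_
  validate_screen_table(df)
}

validate_screen_table <- function(df) {
  bad_class <- setdiff(unique(df$reagent_class), REAGENT_CLASSES)
  if (length(bad_class) > 0L)
    format_error(sprintf("unknown reagent_class value(s): %s",
                         paste(bad_class, collapse = ", ")))
  nonpos <- which(!is.finite(df$raw_signal) | df$raw_signal <= 0)
  if (length(nonpos) > 0L) {
    w <- df[nonpos[1L], ]
    value_error(sprintf(
      "non-positive raw_signal at plate %s row %d col %d (%d offending wells)",
      w$plate_id, w$row, w$col, length(nonpos)))
  }
  key <- paste(df$plate_id, df$row, df$col, sep = "\r")
  if (anyDuplicated(key))
    value_error(sprintf("duplicate (plate_id, row, col) well(s): %s",
                        paste(head(unique(key[duplicated(key)]), 3L),
                              collapse = "; ")))
  df
}

#' Write a screen table to tab-separated text
#' @param table screen table.
#' @param path output path.
#' @export
write_screen_table <- function(table, path) {
  write_tsv(table[, intersect(SCREEN_COLUMNS, names(table))], path)
}

#' Loess normalization settings
#'
#' The loess covariate is 2-D well position (row, column) within a plate,
#' the standard spatial correction for arrayed screens. The surface is by
#' default fitted on library wells only, because control wells are few and
#' spatially clustered.
#'
#' @param span loess span fraction in (0, 1].
#' @param degree local polynomial degree, 1 or 2.
#' @param fit_wells `"library_only"` (mimic + inhibitor wells) or
#'   `"all_non_positive_control"`.
#' @return list of class `loess_config`.
#' @export
loess_config <- function(span = 0.5, degree = 1,
                         fit_wells = c("library_only",
                                       "all_non_positive_control")) {
  if (!is.numeric(span) || span <= 0 || span > 1)
    config_error("span must be in (0, 1]")
  if (!degree %in% c(1, 2)) config_error("degree must be 1 or 2")
  structure(list(span = span, degree = degree,
                 fit_wells = match.arg(fit_wells)),
            class = "loess_config")
}

#' Loess + log2 normalization of a viability screen
#'
#' Per plate, fits a loess surface of `log2(raw_signal)` over (row, col)
#' using the configured fit wells, then sets
#' `normalized_viability = log2(raw) - fitted + median(log2(raw))` over the
#' fit wells, so each plate is flattened and recentred at its own median.
#' All wells (controls included) receive normalized values. Plates with
#' fewer than `min_fit_wells` fit wells are skipped with a warning and keep
#' `NA` normalized values; skipped plate ids are attached as the
#' `"skipped_plates"` attribute.
#'
#' @param table screen table (see [read_screen_table()]).
#' @param cfg a [loess_config()].
#' @param min_fit_wells minimum fit wells per plate (default 20).
#' @return the table with `normalized_viability` filled in (log2 units).
#' @export
loess_log2_normalize <- function(table, cfg = loess_config(),
                                 min_fit_wells = 20L) {
  stopifnot_columns(table, setdiff(SCREEN_COLUMNS, "normalized_viability"),
                    "screen table")
  table$normalized_viability <- NA_real_
  skipped <- character(0)
  for (pid in unique(table$plate_id)) {
    idx <- which(table$plate_id == pid)
    plate <- table[idx, ]
    fit_sel <- if (cfg$fit_wells == "library_only") {
      plate$reagent_class %in% c("mimic", "inhibitor")
    } else {
      plate$reagent_class != "pos_control"
    }
    if (sum(fit_sel) < min_fit_wells) {
      warning(sprintf("plate %s skipped: only %d fit wells (< %d)",
                      pid, sum(fit_sel), min_fit_wells))
      skipped <- c(skipped, pid)
      next
    }
    l2 <- log2(plate$raw_signal)
    fit_df <- data.frame(l2 = l2[fit_sel], row = plate$row[fit_sel],
                         col = plate$col[fit_sel])
    fit <- stats::loess(l2 ~ row + col, data = fit_df, span = cfg$span,
                        degree = cfg$degree, family = "gaussian",
                        surface = "direct", normalize = FALSE)
    fitted_all <- predict(fit, newdata = data.frame(row = plate$row,
                                                    col = plate$col))
    resid <- l2 - fitted_all
    # recentre so the median of normalized fit wells equals the median of
    # log2 raw over the same wells (plates stay directly comparable)
    recenter <- median(l2[fit_sel]) - median(resid[fit_sel])
    table$normalized_viability[idx] <- resid + recenter
  }
  attr(table, "skipped_plates") <- skipped
  table
}

#' Plate-wise negative-control-median normalization (validation mode)
#'
#' Divides each well's raw signal by the plate's median negative-control
#' raw signal. Values stay on the linear scale (1 = control-level
#' viability); no log transform is applied.
#'
#' @param table screen table with at least one `neg_control` well per plate.
#' @return the table with `normalized_viability` set to the control ratio.
#' @export
negcontrol_normalize <- function(table) {
  stopifnot_columns(table, setdiff(SCREEN_COLUMNS, "normalized_viability"),
                    "screen table")
  plates <- unique(table$plate_id)
  has_neg <- vapply(plates, function(p) {
    any(table$reagent_class[table$plate_id == p] == "neg_control")
  }, logical(1))
  if (any(!has_neg)) {
    data_error(sprintf("plate(s) without negative-control wells: %s",
                       paste(plates[!has_neg], collapse = ", ")))
  }
  table$normalized_viability <- NA_real_
  for (pid in plates) {
    idx <- which(table$plate_id == pid)
    neg <- table$raw_signal[idx][table$reagent_class[idx] == "neg_control"]
    table$normalized_viability[idx] <- table$raw_signal[idx] / median(neg)
  }
  table
}
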