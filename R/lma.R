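# Lysate-microarray protein analysis: total-protein (Sypro) normalization,
# log2 transform, within-stratum Z-scores and |Z| >= 2 hit calls.

#' Sypro-normalize and log2-transform LMA intensities
#'
#' Divides each antibody signal by its spot's total-protein (Sypro) signal
#' and takes log2. Rows with a non-positive raw or Sypro intensity cannot be
#' normalized and are dropped; the number dropped is reported via a message
#' and the `"rejected"` attribute.
#'
#' @param table data.frame with at least `raw` and `sypro` columns.
#' @return the table with a `normalized_log2` column added.
#' @export
sypro_log2 <- function(table) {
  stopifnot_columns(table, c("raw", "sypro"), "LMA table")
  bad <- !is.finite(table$raw) | !is.finite(table$sypro) |
    table$raw <= 0 | table$sypro <= 0
  if (any(bad)) {
    message(sprintf("sypro_log2: rejected %d row(s) with non-positive intensity",
                    sum(bad)))
    table <- table[!bad, , drop = FALSE]
  }
  table$normalized_log2 <- log2(table$raw / table$sypro)
  attr(table, "rejected") <- sum(bad)
  table
}

#' Z-score protein signals within strata and call deregulation hits
#'
#' Standardizes `normalized_log2` to mean 0, sample SD 1 within each stratum
#' (by default per protein and cell line, across all reagent x arm
#' conditions) and flags conditions with `|z| >= z_threshold` as hits; the
#' threshold is inclusive. Direction is the sign of z. Strata with SD 0
#' yield undefined z and no hits (with a warning), as do strata with fewer
#' than 3 conditions.
#'
#' @param table output of [sypro_log2()].
#' @param z_threshold hit threshold in SDs (default 2).
#' @param stratify_by additional columns defining strata alongside
#'   `protein`; default `"cell_line"`, with `c("cell_line", "arm")` as the
#'   treatment-stratified alternative.
#' @return the table with `z_score`, `hit` and `direction` columns.
#' @export
zscore_and_call <- function(table, z_threshold = 2,
                            stratify_by = "cell_line") {
  stopifnot_columns(table, c("protein", "normalized_log2", stratify_by),
                    "LMA table")
  key <- do.call(paste, c(table[c("protein", stratify_by)], sep = "\r"))
  table$z_score <- NA_real_
  for (k in unique(key)) {
    idx <- which(key == k)
    x <- table$normalized_log2[idx]
    if (length(x) < 3L) {
      warning(sprintf("stratum %s has fewer than 3 conditions; z undefined",
                      gsub("\r", "/", k)))
      next
    }
    s <- sample_sd(x)
    if (s == 0) {
      warning(sprintf("stratum %s has zero SD; z undefined",
                      gsub("\r", "/", k)))
      next
    }
    table$z_score[idx] <- (x - mean(x)) / s
  }
  table$hit <- !is.na(table$z_score) & abs(table$z_score) >= z_threshold
  table$direction <- ifelse(table$hit, sign(table$z_score), 0)
  table
}
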