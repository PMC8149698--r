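# Tab-separated I/O for expression matrices: probes x samples values and
# detection flags, plus a sidecar sample-metadata table.

#' Write an expression matrix to tab-separated files
#'
#' Writes `<prefix>_values.tsv`, `<prefix>_detected.tsv` (probes x samples,
#' first column `probe`) and `<prefix>_samples.tsv` (sample metadata).
#'
#' @param expr a [new_mirsens_expr()].
#' @param prefix output path prefix.
#' @return the three file paths, invisibly.
#' @export
write_expression <- function(expr, prefix) {
  stopifnot(inherits(expr, "mirsens_expr"))
  paths <- paste0(prefix, c("_values.tsv", "_detected.tsv", "_samples.tsv"))
  write_tsv(data.frame(probe = rownames(expr$values), expr$values,
                       check.names = FALSE), paths[1L])
  write_tsv(data.frame(probe = rownames(expr$detected), expr$detected,
                       check.names = FALSE), paths[2L])
  write_tsv(expr$samples, paths[3L])
  invisible(paths)
}

#' Read an expression matrix written by [write_expression()]
#'
#' @param prefix path prefix used when writing.
#' @return a `mirsens_expr`.
#' @export
read_expression <- function(prefix) {
  vals <- read_tsv(paste0(prefix, "_values.tsv"))
  det <- read_tsv(paste0(prefix, "_detected.tsv"))
  samples <- read_tsv(paste0(prefix, "_samples.tsv"))
  v <- as.matrix(vals[, -1L, drop = FALSE])
  rownames(v) <- vals$probe
  d <- as.matrix(det[, -1L, drop = FALSE]) == TRUE
  rownames(d) <- det$probe
  new_mirsens_expr(v, d, samples)
}
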