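# Internal helpers: classed conditions, table IO, small assertions.

mirsens_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "mirsens_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error <- function(msg) mirsens_stop(msg, "mirsens_config_error")
format_error <- function(msg) mirsens_stop(msg, "mirsens_format_error")
value_error  <- function(msg) mirsens_stop(msg, "mirsens_value_error")
data_error   <- function(msg) mirsens_stop(msg, "mirsens_data_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic tab-separated writer used for all pipeline artifacts.
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

stopifnot_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    format_error(sprintf("%s is missing required column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Sample SD (denominator n-1); returns 0 for n == 1 to keep callers simple.
sample_sd <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
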