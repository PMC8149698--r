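# miRNA microarray preprocessing and differential expression across
# treatment arms (Kruskal-Wallis, nominal p < 0.05, uncorrected).

#' Preprocess a miRNA expression matrix
#'
#' Per sample, subtracts the median of that sample's detected (expressed)
#' probes, so the per-sample median of detected probes becomes 0. Probes
#' undetected in every sample are then set to one common floor value across
#' all samples — by default the minimum centered value observed among
#' detected entries minus 1, so floored probes sit below all real signal.
#'
#' @param expr a [new_mirsens_expr()].
#' @param floor_value common value for all-undetected probes; `NULL` uses
#'   the default above.
#' @return the preprocessed `mirsens_expr`; floored probe ids are attached
#'   as the `"floored_probes"` attribute.
#' @export
preprocess_expression <- function(expr, floor_value = NULL) {
  stopifnot(inherits(expr, "mirsens_expr"))
  v <- expr$values
  d <- expr$detected
  n_det <- colSums(d)
  if (any(n_det == 0L))
    data_error(sprintf("sample(s) with zero detected probes: %s",
                       paste(colnames(v)[n_det == 0L], collapse = ", ")))
  for (j in seq_len(ncol(v))) {
    v[, j] <- v[, j] - median(v[d[, j], j])
  }
  never <- rownames(v)[rowSums(d) == 0L]
  if (length(never) > 0L) {
    if (is.null(floor_value)) floor_value <- min(v[d]) - 1
    v[never, ] <- floor_value
  }
  out <- new_mirsens_expr(v, d, expr$samples)
  attr(out, "floored_probes") <- never
  out
}

#' Kruskal-Wallis differential miRNA expression across treatment arms
#'
#' For a chosen cell-line set, tests each probe for location differences of
#' expression across treatment arms by the tie-corrected Kruskal-Wallis test
#' (chi-squared approximation, arms - 1 df), pooling samples from the
#' selected cell lines. Significance is at nominal p < 0.05, uncorrected.
#' The cell-line sets mirror the responder grouping: all four lines
#' combined, responsive lines only, or poorly responding lines only.
#'
#' An alternative `mode = "before_after"` tests, per drug arm, untreated vs
#' that arm (two groups), for when the before/after framing is wanted.
#'
#' @param expr preprocessed `mirsens_expr` with `cell_line`, `arm` and
#'   `responder_class` sample metadata.
#' @param cellline_set `"all_four"`, `"responsive"` or `"poor"`.
#' @param mode `"arms"` (one test across all arms, default) or
#'   `"before_after"`.
#' @param untreated_arm label of the untreated arm (used by
#'   `"before_after"`).
#' @param alpha nominal significance level (default 0.05).
#' @return data.frame per probe (and per comparison in `"before_after"`
#'   mode): H statistic, p, `significant`, and per-arm medians.
#' @export
kruskal_wallis_groups <- function(expr,
                                  cellline_set = c("all_four", "responsive",
                                                   "poor"),
                                  mode = c("arms", "before_after"),
                                  untreated_arm = "untreated",
                                  alpha = 0.05) {
  cellline_set <- match.arg(cellline_set)
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "mirsens_expr"))
  stopifnot_columns(expr$samples, c("cell_line", "arm", "responder_class"),
                    "sample metadata")
  sel <- switch(cellline_set,
                all_four = rep(TRUE, nrow(expr$samples)),
                responsive = expr$samples$responder_class == "responsive",
                poor = expr$samples$responder_class == "poor")
  v <- expr$values[, sel, drop = FALSE]
  arm <- expr$samples$arm[sel]
  arms <- unique(arm)
  if (length(arms) < 2L)
    data_error("need at least 2 treatment arms in the selected cell-line set")

  kw_one <- function(x, g) {
    # constant data carries no rank information: H = 0, p = 1
    if (length(unique(x)) == 1L) return(c(H = 0, p = 1))
    kt <- stats::kruskal.test(x, factor(g))
    c(H = unname(kt$statistic), p = kt$p.value)
  }

  run_set <- function(groups, label) {
    keep <- arm %in% groups
    counts <- table(arm[keep])
    if (any(counts < 2L) || length(counts) < 2L) {
      return(data.frame(probe = rownames(v), cellline_set = cellline_set,
                        comparison = label, H = NA_real_, p = NA_real_,
                        significant = NA,
                        skipped_reason = "arm with < 2 samples",
                        stringsAsFactors = FALSE))
    }
    sub <- v[, keep, drop = FALSE]
    garm <- arm[keep]
    res <- t(apply(sub, 1L, kw_one, g = garm))
    out <- data.frame(probe = rownames(v), cellline_set = cellline_set,
                      comparison = label, H = res[, "H"], p = res[, "p"],
                      significant = res[, "p"] < alpha,
                      skipped_reason = NA_character_,
                      stringsAsFactors = FALSE)
    for (a in groups) {
      out[[paste0("median_", a)]] <-
        apply(sub[, garm == a, drop = FALSE], 1L, median)
    }
    rownames(out) <- NULL
    out
  }

  if (mode == "arms") {
    run_set(arms, "all_arms")
  } else {
    drug_arms <- setdiff(arms, untreated_arm)
    do.call(rbind, lapply(drug_arms, function(a) {
      out <- run_set(c(untreated_arm, a), paste0(untreated_arm, "_vs_", a))
      med_cols <- grep("^median_", names(out))
      if (length(med_cols) == 2L)
        names(out)[med_cols] <- c("median_untreated", "median_treated")
      out
    }))
  }
}
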