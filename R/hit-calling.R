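# Sensitizer calling: per-treatment-group median - k*SD outlier rule, the
# two exclusion criteria (no effect without drug; inhibitor target must be
# endogenously expressed), multi-context candidate selection, and the
# validation-stage Student's t-test.

#' Per-(cell line, arm) location and scale of normalized viability
#'
#' Statistics are computed over library reagents only (mimic and inhibitor
#' wells); control and empty wells never enter the median or SD. SD is the
#' classical sample SD (denominator n-1), computed including any outliers.
#' A MAD-based scale is available for robustness comparisons but is not the
#' default rule.
#'
#' @param table normalized screen table.
#' @param scale_estimator `"sd"` (default) or `"mad"` (scaled to be
#'   consistent with the SD under normality).
#' @return data.frame with one row per (cell_line, arm): `n_reagents`,
#'   `center` (median), `scale`, `degenerate` (scale == 0) and `low_n`
#'   (fewer than 10 reagents) flags.
#' @export
group_stats <- function(table, scale_estimator = c("sd", "mad")) {
  scale_estimator <- match.arg(scale_estimator)
  stopifnot_columns(table, c("cell_line", "arm", "reagent_class",
                             "normalized_viability"), "screen table")
  lib <- table[table$reagent_class %in% c("mimic", "inhibitor") &
                 !is.na(table$normalized_viability), ]
  if (nrow(lib) == 0L) data_error("no library wells with normalized values")
  groups <- unique(lib[, c("cell_line", "arm")])
  res <- lapply(seq_len(nrow(groups)), function(i) {
    v <- lib$normalized_viability[lib$cell_line == groups$cell_line[i] &
                                    lib$arm == groups$arm[i]]
    sc <- if (scale_estimator == "sd") sample_sd(v) else
      stats::mad(v, constant = 1.4826)
    data.frame(cell_line = groups$cell_line[i], arm = groups$arm[i],
               n_reagents = length(v), center = median(v), scale = sc,
               degenerate = sc == 0, low_n = length(v) < 10L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (any(out$low_n))
    warning(sprintf("%d group(s) have fewer than 10 reagents", sum(out$low_n)))
  out
}

#' Call sensitizing reagents by the median - k*SD outlier rule
#'
#' A reagent is a sensitizer in a drug-containing arm if its normalized
#' viability lies strictly below the treatment group's median minus `k`
#' group SDs (only the low-viability tail is called). The boundary is
#' strict: a value exactly at median - k*SD is not flagged. Degenerate
#' groups (SD 0) produce no flags.
#'
#' @param table normalized screen table.
#' @param stats output of [group_stats()]; computed from `table` if `NULL`.
#' @param k outlier threshold in group SDs (default 3).
#' @param no_drug_arm label of the vehicle arm; sensitizer flags are never
#'   set in that arm, but its deviations are kept for the exclusion step.
#' @return hit table: one row per library (reagent, cell line, arm) with
#'   `normalized_viability`, `deviation_in_sd`, `sensitizer`, exclusion flag
#'   placeholders, `exclusion_reason` and `candidate`.
#' @export
call_sensitizers <- function(table, stats = NULL, k = 3,
                             no_drug_arm = "vehicle") {
  if (is.null(stats)) stats <- group_stats(table)
  lib <- table[table$reagent_class %in% c("mimic", "inhibitor") &
                 !is.na(table$normalized_viability), ]
  key <- paste(lib$cell_line, lib$arm, sep = "\r")
  skey <- paste(stats$cell_line, stats$arm, sep = "\r")
  m <- match(key, skey)
  if (anyNA(m)) {
    miss <- unique(key[is.na(m)])
    data_error(sprintf("missing group stats for: %s",
                       paste(gsub("\r", "/", miss), collapse = ", ")))
  }
  center <- stats$center[m]
  scale <- stats$scale[m]
  dev <- ifelse(scale > 0, (lib$normalized_viability - center) / scale,
                NA_real_)
  hits <- data.frame(
    reagent_id = lib$reagent_id,
    reagent_class = lib$reagent_class,
    cell_line = lib$cell_line,
    arm = lib$arm,
    normalized_viability = lib$normalized_viability,
    deviation_in_sd = dev,
    sensitizer = !is.na(dev) & dev < -k & lib$arm != no_drug_arm,
    excluded_no_drug_effect = FALSE,
    excluded_not_expressed = FALSE,
    exclusion_reason = NA_character_,
    candidate = FALSE,
    stringsAsFactors = FALSE)
  attr(hits, "k") <- k
  attr(hits, "no_drug_arm") <- no_drug_arm
  hits
}

#' Apply the two sensitizer exclusion criteria
#'
#' Criterion 1 (drug independence): a reagent whose no-drug-arm deviation in
#' a given cell line reaches -k SD or beyond is toxic on its own there, so
#' it loses all sensitizer flags in that cell line. Criterion 2 (endogenous
#' expression): an inhibitor whose target miRNA is not expressed in the
#' untreated cells of a cell line cannot act there, so it loses all flags in
#' that cell line. "Expressed" means the detection flag is `TRUE` in at
#' least one untreated sample of the cell line, or the value exceeds
#' `floor`. Mimics are never excluded by criterion 2. Exclusion reasons are
#' recorded in the `exclusion_reason` column
#' (`no_drug_effect` / `target_not_expressed`).
#'
#' @param hits hit table from [call_sensitizers()].
#' @param expr optional [new_mirsens_expr()] of untreated-cell expression;
#'   required for criterion 2. Its samples need `cell_line` and `arm`
#'   metadata; untreated samples are those in `untreated_arms`.
#' @param inhibitor_targets named character vector mapping inhibitor
#'   reagent ids to miRNA probe ids in `expr`. Inhibitors with no mappable
#'   target raise a warning and are retained.
#' @param k threshold used for criterion 1; defaults to the `k` the hits
#'   were called with.
#' @param floor expression floor; a value above it counts as expressed even
#'   without a detection call. Default `Inf` means the detection flag alone
#'   decides.
#' @param no_drug_arm vehicle arm label.
#' @param untreated_arms arm labels in `expr` regarded as untreated.
#' @return the hit table with exclusions applied.
#' @export
apply_exclusions <- function(hits, expr = NULL, inhibitor_targets = NULL,
                             k = attr(hits, "k") %||% 3,
                             floor = Inf,
                             no_drug_arm = attr(hits, "no_drug_arm") %||% "vehicle",
                             untreated_arms = c("untreated", "vehicle")) {
  if (!no_drug_arm %in% hits$arm)
    data_error(sprintf("no-drug arm '%s' absent from hit table", no_drug_arm))

  # criterion 1: toxic without drug, per cell line
  nd <- hits[hits$arm == no_drug_arm, ]
  toxic <- nd[!is.na(nd$deviation_in_sd) & nd$deviation_in_sd <= -k,
              c("reagent_id", "cell_line")]
  if (nrow(toxic) > 0L) {
    hk <- paste(hits$reagent_id, hits$cell_line, sep = "\r")
    tk <- paste(toxic$reagent_id, toxic$cell_line, sep = "\r")
    sel <- hk %in% tk
    hits$excluded_no_drug_effect[sel] <- TRUE
    hits$sensitizer[sel] <- FALSE
    hits$exclusion_reason[sel] <- "no_drug_effect"
  }

  # criterion 2: inhibitor target not endogenously expressed when untreated
  inhib_ids <- unique(hits$reagent_id[hits$reagent_class == "inhibitor"])
  if (!is.null(expr) && length(inhib_ids) > 0L) {
    unmapped <- inhib_ids[!inhib_ids %in% names(inhibitor_targets %||%
                                                  character(0))]
    if (length(unmapped) > 0L)
      warning(sprintf("%d inhibitor(s) with no mappable target miRNA retained",
                      length(unmapped)))
    mapped <- setdiff(inhib_ids, unmapped)
    for (cl in unique(hits$cell_line)) {
      sel_samp <- expr$samples$cell_line == cl &
        expr$samples$arm %in% untreated_arms
      if (!any(sel_samp)) next
      for (rid in mapped) {
        probe <- inhibitor_targets[[rid]]
        if (!probe %in% rownames(expr$values)) next
        detected <- any(expr$detected[probe, sel_samp])
        above_floor <- any(expr$values[probe, sel_samp] > floor)
        if (!detected && !above_floor) {
          sel <- hits$reagent_id == rid & hits$cell_line == cl
          hits$excluded_not_expressed[sel] <- TRUE
          hits$sensitizer[sel] <- FALSE
          hits$exclusion_reason[sel] <-
            ifelse(is.na(hits$exclusion_reason[sel]),
                   "target_not_expressed", hits$exclusion_reason[sel])
        }
      }
    }
  }
  hits
}

#' Flag multi-context sensitization candidates
#'
#' A reagent is a candidate if, after exclusions, it is a sensitizer in at
#' least two distinct (cell line, arm) contexts — i.e. an effect in both
#' cell lines (any arms) or in more than one treatment setting within one
#' cell line.
#'
#' @param hits hit table after [apply_exclusions()].
#' @return the hit table with the reagent-level `candidate` flag set on all
#'   rows of candidate reagents.
#' @export
select_candidates <- function(hits) {
  sens <- hits[hits$sensitizer, c("reagent_id", "cell_line", "arm")]
  if (nrow(sens) > 0L) {
    ctx <- unique(sens)
    n_ctx <- table(ctx$reagent_id)
    cands <- names(n_ctx)[n_ctx >= 2L]
  } else {
    cands <- character(0)
  }
  hits$candidate <- hits$reagent_id %in% cands
  hits
}

#' Candidate reagent ids from a hit table
#' @param hits hit table after [select_candidates()].
#' @return character vector of candidate reagent ids.
#' @export
candidate_ids <- function(hits) sort(unique(hits$reagent_id[hits$candidate]))

#' Validation-stage Student's t-test against the scrambled control
#'
#' For each candidate reagent and arm, compares its replicate normalized
#' viabilities to the scrambled-negative-control replicates in the same arm
#' with a two-sided two-sample Student's t-test (equal variances).
#' Significance tiers are annotated as stars: * p < 0.05, ** p < 0.01,
#' *** p < 0.001. With fewer than 2 replicates on either side the p-value
#' is recorded as missing.
#'
#' @param norm_table control-normalized validation table (see
#'   [negcontrol_normalize()]); replicate wells share a `reagent_id`.
#' @param candidates character vector of candidate reagent ids.
#' @param control_id reagent id of the scrambled negative control.
#' @return data.frame (reagent_id, arm, n, mean_viability, control_mean, p,
#'   stars).
#' @export
validation_ttest <- function(norm_table, candidates, control_id) {
  stopifnot_columns(norm_table, c("reagent_id", "arm",
                                  "normalized_viability"),
                    "validation table")
  arms <- unique(norm_table$arm)
  rows <- list()
  for (arm in arms) {
    at <- norm_table[norm_table$arm == arm, ]
    ctrl <- at$normalized_viability[at$reagent_id == control_id]
    for (rid in candidates) {
      v <- at$normalized_viability[at$reagent_id == rid]
      if (length(v) == 0L) next
      p <- if (length(v) >= 2L && length(ctrl) >= 2L) {
        if (sample_sd(c(v, ctrl)) == 0) 1 else
          stats::t.test(v, ctrl, var.equal = TRUE)$p.value
      } else NA_real_
      stars <- if (is.na(p)) NA_character_
        else if (p < 0.001) "***" else if (p < 0.01) "**"
        else if (p < 0.05) "*" else "ns"
      rows[[length(rows) + 1L]] <- data.frame(
        reagent_id = rid, arm = arm, n = length(v),
        mean_viability = mean(v), control_mean = mean(ctrl),
        p = p, stars = stars, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(reagent_id = character(0), arm = character(0),
                      n = integer(0), mean_viability = numeric(0),
                      control_mean = numeric(0), p = numeric(0),
                      stars = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
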