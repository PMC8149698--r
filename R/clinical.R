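# Clinical cohort associations: miRNA-mRNA Spearman correlation with BH
# control, pairwise Wilcoxon stage comparisons with small-stage exclusion,
# and median-split Kaplan-Meier survival with the log-rank test.

validate_cohort <- function(cohort) {
  stopifnot(is.list(cohort))
  stopifnot_columns(cohort$patients,
                    c("patient_id", "time", "event"), "patient table")
  if (any(cohort$patients$time <= 0))
    value_error("survival times must be > 0")
  cohort
}

#' Spearman correlation of each miRNA with all mRNAs
#'
#' Computes Spearman's rho (average ranks for ties) and a two-sided p-value
#' (t approximation on the rank correlation) for every (miRNA, mRNA) pair,
#' then applies Benjamini-Hochberg correction — by default within each
#' miRNA's family of tests across mRNAs — and flags adjusted p < `alpha`.
#' Pairs involving a constant vector have undefined rho and are recorded as
#' missing.
#'
#' @param cohort cohort list with `mirna` and `mrna` patient x feature
#'   matrices.
#' @param mirna_ids miRNAs to test (default: all columns of `cohort$mirna`).
#' @param bh_scope `"per_mirna"` (default) or `"global"` (one family over
#'   all pairs).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame (mirna, mrna, rho, p, p_adj, significant, sign).
#' @export
mirna_mrna_correlation <- function(cohort, mirna_ids = NULL,
                                   bh_scope = c("per_mirna", "global"),
                                   alpha = 0.05) {
  bh_scope <- match.arg(bh_scope)
  mirna <- cohort$mirna
  mrna <- cohort$mrna
  if (is.null(mirna_ids)) mirna_ids <- colnames(mirna)
  n <- nrow(mirna)
  if (n < 10L) data_error("need at least 10 patients with both measurements")

  rank_mat <- function(m) apply(m, 2L, rank, ties.method = "average")
  rk_mi <- rank_mat(mirna[, mirna_ids, drop = FALSE])
  rk_mr <- rank_mat(mrna)
  const_mi <- apply(mirna[, mirna_ids, drop = FALSE], 2L,
                    function(x) length(unique(x)) == 1L)
  const_mr <- apply(mrna, 2L, function(x) length(unique(x)) == 1L)

  # Pearson on average ranks = Spearman; constant columns are set to NA
  # below, so cor()'s zero-variance warning carries no information here
  rho <- suppressWarnings(stats::cor(rk_mi, rk_mr))
  rho[const_mi, ] <- NA_real_
  rho[, const_mr] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)

  out <- data.frame(
    mirna = rep(mirna_ids, times = ncol(mrna)),
    mrna = rep(colnames(mrna), each = length(mirna_ids)),
    rho = as.vector(rho), p = as.vector(p),
    stringsAsFactors = FALSE)
  if (bh_scope == "global") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
  } else {
    out$p_adj <- NA_real_
    for (id in mirna_ids) {
      sel <- out$mirna == id
      out$p_adj[sel] <- stats::p.adjust(out$p[sel], method = "BH")
    }
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$sign <- ifelse(is.na(out$rho), NA_integer_, as.integer(sign(out$rho)))
  out[order(out$mirna, out$mrna), , drop = FALSE]
}

#' Pairwise Wilcoxon comparisons of miRNA expression across tumour stages
#'
#' Stages with fewer than `min_group` patients are excluded (as real HER2+
#' cohorts exclude their sparse stage-0/4 groups); all remaining stage pairs
#' are compared per miRNA with two-sided Wilcoxon rank-sum tests, and raw
#' (unadjusted) p-values are reported.
#'
#' @param cohort cohort list whose `patients` table has a `stage` column.
#' @param mirna_ids miRNAs to test (default all).
#' @param min_group minimum patients per stage (default 5).
#' @return data.frame (mirna, stage_a, stage_b, n_a, n_b, W, p); empty with
#'   a `"reason"` attribute if fewer than 2 stages are eligible.
#' @export
stage_comparison <- function(cohort, mirna_ids = NULL, min_group = 5L) {
  if (is.null(cohort$patients$stage))
    data_error("cohort has no stage column")
  if (is.null(mirna_ids)) mirna_ids <- colnames(cohort$mirna)
  stage <- cohort$patients$stage
  counts <- table(stage)
  eligible <- as.integer(names(counts)[counts >= min_group])
  empty <- data.frame(mirna = character(0), stage_a = integer(0),
                      stage_b = integer(0), n_a = integer(0),
                      n_b = integer(0), W = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(eligible) < 2L) {
    attr(empty, "reason") <- "fewer than 2 stages with enough patients"
    return(empty)
  }
  pairs <- utils::combn(sort(eligible), 2L)
  rows <- list()
  for (id in mirna_ids) {
    x <- cohort$mirna[, id]
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      xa <- x[stage == a]; xb <- x[stage == b]
      wt <- suppressWarnings(stats::wilcox.test(xa, xb,
                                                alternative = "two.sided"))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = id, stage_a = a, stage_b = b,
        n_a = length(xa), n_b = length(xb),
        W = unname(wt$statistic), p = wt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Median-split Kaplan-Meier survival analysis with log-rank test
#'
#' Splits patients at the cohort median of the miRNA's expression — high is
#' strictly above the median, ties go to the low arm — estimates
#' Kaplan-Meier curves per arm, and tests the difference with a two-group
#' log-rank test (1 df chi-squared, standard hypergeometric variance). The
#' OS endpoint treats all deaths as events; BCSS treats non-disease deaths
#' as censored (requires a `cause` column with `"disease"` for
#' disease-specific deaths).
#'
#' @param cohort cohort list.
#' @param mirna miRNA id (column of `cohort$mirna`).
#' @param endpoint `"os"` (default) or `"bcss"`.
#' @param min_per_arm warn if an arm has fewer patients than this.
#' @return list: `km` (step-function data.frame: group, time, n_risk,
#'   n_event, surv), `chisq`, `p`, `group_sizes`.
#' @export
median_split_survival <- function(cohort, mirna, endpoint = c("os", "bcss"),
                                  min_per_arm = 10L) {
  endpoint <- match.arg(endpoint)
  validate_cohort(cohort)
  x <- cohort$mirna[, mirna]
  pt <- cohort$patients
  keep <- is.finite(x) & !is.na(pt$time) & !is.na(pt$event)
  x <- x[keep]; pt <- pt[keep, ]
  event <- pt$event
  if (endpoint == "bcss") {
    if (is.null(pt$cause))
      data_error("BCSS endpoint requires a 'cause' column")
    event <- as.integer(pt$event == 1L & !is.na(pt$cause) &
                          pt$cause == "disease")
  }
  med <- median(x)
  group <- factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
  sizes <- table(group)
  if (any(sizes == 0L)) data_error("degenerate median split: one empty arm")
  if (any(sizes < min_per_arm))
    warning(sprintf("arm with fewer than %d patients", min_per_arm))

  sf <- survival::survfit(survival::Surv(pt$time, event) ~ group)
  km <- data.frame(
    group = rep(sub("^group=", "", names(sf$strata)), sf$strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    surv = sf$surv, stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(survival::Surv(pt$time, event) ~ group)
  chisq <- unname(sd_$chisq)
  list(km = km, chisq = chisq,
       p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       group_sizes = c(low = unname(sizes["low"]),
                       high = unname(sizes["high"])))
}
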