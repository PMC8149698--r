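# Cohort associations: Spearman + BH, stage Wilcoxon, median-split KM.

toy_cohort <- function(mirna, time, event, stage = NULL, cause = NULL,
                       mrna = NULL) {
  n <- length(time)
  patients <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                         time = time, event = event,
                         stringsAsFactors = FALSE)
  if (!is.null(stage)) patients$stage <- stage
  if (!is.null(cause)) patients$cause <- cause
  mi <- matrix(mirna, ncol = 1, dimnames = list(patients$patient_id, "m1"))
  mr <- mrna %||% matrix(rnorm(n), ncol = 1,
                         dimnames = list(patients$patient_id, "G1"))
  list(patients = patients, mirna = mi, mrna = mr)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Spearman correlation: monotone pairs, ties, BH per miRNA", {
  n <- 30
  x <- seq_len(n)
  co <- toy_cohort(x, time = rep(1, n), event = rep(1L, n),
                   mrna = matrix(c(x^3, rnorm(n)), ncol = 2,
                                 dimnames = list(sprintf("P%03d", 1:n),
                                                 c("G1", "G2"))))
  res <- mirna_mrna_correlation(co)
  expect_equal(res$rho[res$mrna == "G1"], 1)
  expect_equal(res$sign[res$mrna == "G1"], 1L)

  # matches cor.test's t-approximation including average-rank ties
  set.seed(4)
  xt <- round(rnorm(n), 1)  # forces ties
  co2 <- toy_cohort(xt, rep(1, n), rep(1L, n))
  r2 <- mirna_mrna_correlation(co2)
  ct <- suppressWarnings(cor.test(xt, co2$mrna[, 1], method = "spearman",
                                  exact = FALSE))
  expect_equal(r2$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r2$p, ct$p.value, tolerance = 1e-12)

  # constant vector: missing rho
  co3 <- toy_cohort(rep(2, n), rep(1, n), rep(1L, n))
  r3 <- mirna_mrna_correlation(co3)
  expect_true(is.na(r3$rho))
  expect_false(r3$significant)
})

test_that("BH adjustment equals the step-up formula and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(p.adjust(p, "BH"), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(p.adjust(p, "BH"), bh_stepup(p))
  set.seed(11)
  for (i in 1:10) {
    pv <- runif(20)
    adj <- p.adjust(pv, "BH")
    expect_equal(adj, bh_stepup(pv), tolerance = 1e-12)
    expect_true(all(adj >= pv))
    o <- order(pv)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("stage comparison excludes sparse stages and matches exact enumeration", {
  stage <- c(rep(1L, 3), rep(3L, 3), 0L)   # stage 0 has n = 1: excluded
  x <- c(1, 2, 3, 4, 5, 6, 100)
  co <- toy_cohort(x, rep(1, 7), rep(1L, 7), stage = stage)
  res <- stage_comparison(co, min_group = 3)
  expect_equal(nrow(res), 1L)              # only the 1-vs-3 pair remains
  expect_equal(res$p, ranksum_exact_pvalue(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$p, 0.1)                 # 2/20 assignments as extreme
  wt <- wilcox.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, wt$p.value, tolerance = 1e-12)

  # identical groups: rank sums balance, p at the top of its range (the
  # tie-corrected normal approximation with continuity lands just under 1)
  co2 <- toy_cohort(rep(c(1, 2, 3), 4), rep(1, 12), rep(1L, 12),
                    stage = rep(c(1L, 2L), each = 6))
  r2 <- stage_comparison(co2, min_group = 3)
  expect_equal(r2$W, 6 * 6 / 2)
  expect_gt(r2$p, 0.9)

  # fewer than two eligible stages: empty result with reason
  co3 <- toy_cohort(1:6, rep(1, 6), rep(1L, 6), stage = rep(1L, 6))
  r3 <- stage_comparison(co3, min_group = 3)
  expect_equal(nrow(r3), 0L)
  expect_match(attr(r3, "reason"), "fewer than 2")
})

test_that("median split puts ties low and high arm has floor(n/2) for odd n", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  co <- toy_cohort(x, time = 1:7, event = rep(1L, 7))
  res <- median_split_survival(co, "m1", min_per_arm = 1)
  expect_equal(unname(res$group_sizes["high"]), 3L)   # floor(7/2)
  expect_equal(unname(res$group_sizes["low"]), 4L)    # median goes low
})

test_that("log-rank equals the hand-computed O-E/V table on the toy example", {
  x <- c(0, 0, 0, 1, 1, 1)
  co <- toy_cohort(x, time = c(1, 2, 3, 4, 5, 6), event = rep(1L, 6))
  res <- median_split_survival(co, "m1", min_per_arm = 1)
  oracle <- logrank_oracle_chisq(c(1, 2, 3, 4, 5, 6), rep(1L, 6),
                                 c("A", "A", "A", "B", "B", "B"))
  expect_equal(res$chisq, oracle, tolerance = 1e-9)
  expect_equal(oracle, (3 - 1.15)^2 / 0.6775, tolerance = 1e-9)

  # relabeling the arms does not change the statistic
  res_flip <- median_split_survival(toy_cohort(-x, c(1, 2, 3, 4, 5, 6),
                                               rep(1L, 6)), "m1",
                                    min_per_arm = 1)
  expect_equal(res_flip$chisq, res$chisq, tolerance = 1e-9)
})

test_that("identical arms give chi-squared 0 and p 1", {
  x <- rep(c(0, 1), each = 4)
  tm <- rep(c(2, 4, 6, 8), 2)
  co <- toy_cohort(x, tm, rep(1L, 8))
  res <- median_split_survival(co, "m1", min_per_arm = 1)
  expect_equal(res$chisq, 0, tolerance = 1e-9)
  expect_equal(res$p, 1, tolerance = 1e-9)
})

test_that("KM curves start at 1, are non-increasing, and match the ECDF without censoring", {
  set.seed(33)
  n <- 40
  x <- rnorm(n)
  tm <- rexp(n, 0.1)
  co <- toy_cohort(x, tm, rep(1L, n))
  res <- median_split_survival(co, "m1")
  for (g in c("low", "high")) {
    s <- res$km$surv[res$km$group == g]
    t <- res$km$time[res$km$group == g]
    expect_true(all(s <= 1 + 1e-12))
    expect_true(all(diff(s) <= 1e-12))
    # no censoring: KM equals the empirical survival function
    in_g <- (x > median(x)) == (g == "high")
    emp <- vapply(t, function(tt) mean(tm[in_g] > tt), numeric(1))
    expect_equal(s, emp, tolerance = 1e-9)
  }
})

test_that("BCSS treats non-disease deaths as censored", {
  x <- c(rep(0, 6), rep(1, 6))
  tm <- c(1:6, 1:6)
  cause <- rep(c("disease", "other"), 6)
  co <- toy_cohort(x, tm, rep(1L, 12), cause = cause)
  os <- median_split_survival(co, "m1", endpoint = "os", min_per_arm = 1)
  bcss <- median_split_survival(co, "m1", endpoint = "bcss",
                                min_per_arm = 1)
  expect_equal(sum(os$km$n_event), 12)
  expect_equal(sum(bcss$km$n_event), 6)
  co_nocause <- toy_cohort(x, tm, rep(1L, 12))
  expect_error(median_split_survival(co_nocause, "m1", endpoint = "bcss"),
               class = "mirsens_data_error")
})
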