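# Sensitizer rule, exclusions, candidates, validation t-test.

norm_table <- function(values, arm = "lapatinib", cell_line = "KPL4",
                       classes = "mimic", ids = NULL) {
  n <- length(values)
  data.frame(plate_id = paste0(cell_line, "_", arm),
             row = (seq_len(n) - 1L) %/% 24L, col = (seq_len(n) - 1L) %% 24L,
             reagent_id = ids %||% sprintf("rg_%04d", seq_len(n)),
             reagent_class = rep_len(classes, n), cell_line = cell_line,
             arm = arm, raw_signal = 2^values,
             normalized_viability = values, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("group statistics use library wells only, with degeneracy flags", {
  tab <- norm_table(c(1, 2, 3, 4, 5))
  ctrl <- norm_table(c(10, 10), classes = "neg_control",
                     ids = c("nc1", "nc2"))
  expect_warning(st <- group_stats(rbind(tab, ctrl)), "fewer than 10")
  expect_equal(st$n_reagents, 5L)          # controls excluded
  expect_equal(st$center, 3)
  expect_equal(st$scale, 1.5811, tolerance = 1e-4)

  st2 <- group_stats(norm_table(rep(2, 12)))
  expect_true(st2$degenerate)
})

test_that("the median - 3 SD boundary is strict and degenerate groups flag nothing", {
  vals <- c(7, 6.999, 10, 10.5, 9.5, 10.2, 9.8, 10.1, 9.9, 10.3, 9.7, 10)
  tab <- norm_table(vals)
  stats <- data.frame(cell_line = "KPL4", arm = "lapatinib",
                      n_reagents = 12L, center = 10, scale = 1,
                      degenerate = FALSE, low_n = FALSE,
                      stringsAsFactors = FALSE)
  hits <- call_sensitizers(tab, stats, k = 3)
  expect_false(hits$sensitizer[1L])   # exactly at median - 3 SD
  expect_true(hits$sensitizer[2L])    # just below
  expect_equal(hits$deviation_in_sd[1L], -3)

  const <- norm_table(rep(5, 20))
  hc <- call_sensitizers(const, k = 3)
  expect_false(any(hc$sensitizer))
  expect_true(all(is.na(hc$deviation_in_sd)))

  # missing group stats is an error naming the group
  other <- norm_table(vals, arm = "combination")
  expect_error(call_sensitizers(other, stats, k = 3), "combination",
               class = "mirsens_data_error")
})

test_that("a constructed 4-SD outlier is the only flagged well", {
  set.seed(31)
  base <- rnorm(199, 10, 0.4)
  # place one well 4 SDs below the median of the full group (SD recomputed
  # including the outlier itself, by fixed-point iteration)
  out_val <- min(base) - 1
  for (i in 1:50) {
    v <- c(base, out_val)
    out_val <- median(v) - 4 * sd(v)
  }
  tab <- norm_table(c(base, out_val))
  hits <- call_sensitizers(tab, k = 3)
  expect_identical(which(hits$sensitizer), 200L)
  # brute-force agreement
  bf <- bruteforce_hit_calls(tab)
  expect_identical(hits$sensitizer, bf$sensitizer)
})

test_that("null Gaussian group flags close to the -3 SD tail rate", {
  set.seed(77)
  tab <- norm_table(rnorm(10000, 10, 0.5))
  hits <- call_sensitizers(tab, k = 3)
  frac <- mean(hits$sensitizer)
  expect_gte(frac, 0.0005)
  expect_lte(frac, 0.0035)
})

test_that("exclusion criteria: drug-independent toxicity and unexpressed targets", {
  mk <- function(arm, values, cl = "KPL4") norm_table(values, arm = arm,
                                                      cell_line = cl)
  set.seed(5)
  base <- rnorm(48, 10, 0.3)
  lap <- mk("lapatinib", c(base, 7))          # rg_0049 strong hit
  veh <- mk("vehicle", c(base, 7.5))          # ... but also toxic alone
  tab <- rbind(lap, veh)
  tab$reagent_class[tab$reagent_id == "rg_0049"] <- "inhibitor"
  hits <- call_sensitizers(tab, k = 3, no_drug_arm = "vehicle")
  expect_true(hits$sensitizer[hits$reagent_id == "rg_0049" &
                                hits$arm == "lapatinib"])
  hits <- apply_exclusions(hits, k = 3, no_drug_arm = "vehicle")
  r49 <- hits[hits$reagent_id == "rg_0049", ]
  expect_false(any(r49$sensitizer))
  expect_true(all(r49$excluded_no_drug_effect))
  expect_true(all(r49$exclusion_reason == "no_drug_effect"))

  # criterion 2: inhibitor with undetected target loses flags; mimic kept
  lap2 <- mk("lapatinib", c(base, 7, 7))
  veh2 <- mk("vehicle", c(base, 10, 10))
  tab2 <- rbind(lap2, veh2)
  tab2$reagent_class[tab2$reagent_id %in% c("rg_0048", "rg_0049")] <-
    "inhibitor"   # rg_0048 unmapped (warned, retained); rg_0050 stays a mimic
  samples <- data.frame(sample_id = "KPL4_untreated", cell_line = "KPL4",
                        arm = "untreated", stringsAsFactors = FALSE)
  vals <- matrix(c(2, 9), nrow = 2,
                 dimnames = list(c("mir_a", "mir_b"), samples$sample_id))
  det <- matrix(c(FALSE, TRUE), nrow = 2, dimnames = dimnames(vals))
  expr <- new_mirsens_expr(vals, det, samples)
  h2 <- call_sensitizers(tab2, k = 3, no_drug_arm = "vehicle")
  expect_warning(
    h2 <- apply_exclusions(h2, expr,
                           inhibitor_targets = c(rg_0049 = "mir_a"),
                           k = 3, no_drug_arm = "vehicle"),
    "no mappable")   # inhibitors other than rg_0049 are unmapped but retained
  expect_false(any(h2$sensitizer[h2$reagent_id == "rg_0049"]))
  expect_true(all(h2$exclusion_reason[h2$reagent_id == "rg_0049"] ==
                    "target_not_expressed"))
  expect_true(any(h2$sensitizer[h2$reagent_id == "rg_0050"]))  # mimic kept
})

test_that("candidates need two contexts: two arms or two cell lines", {
  hit_row <- function(id, cl, arm, sens) data.frame(
    reagent_id = id, reagent_class = "mimic", cell_line = cl, arm = arm,
    normalized_viability = 5, deviation_in_sd = -4, sensitizer = sens,
    excluded_no_drug_effect = FALSE, excluded_not_expressed = FALSE,
    exclusion_reason = NA_character_, candidate = FALSE,
    stringsAsFactors = FALSE)
  hits <- rbind(
    hit_row("a", "KPL4", "lapatinib", TRUE),
    hit_row("a", "KPL4", "combination", TRUE),   # two arms, one line
    hit_row("b", "KPL4", "lapatinib", TRUE),
    hit_row("b", "SUM190PT", "lapatinib", TRUE), # two lines, one arm
    hit_row("c", "KPL4", "lapatinib", TRUE),     # single context
    hit_row("d", "KPL4", "lapatinib", FALSE))
  out <- select_candidates(hits)
  expect_setequal(candidate_ids(out), c("a", "b"))
})

test_that("positive-control wells never influence hit calls", {
  set.seed(12)
  tab <- norm_table(rnorm(200, 10, 0.4))
  withpos <- rbind(tab, norm_table(rep(4, 8), classes = "pos_control",
                                   ids = sprintf("pc%d", 1:8)))
  h1 <- call_sensitizers(tab, k = 3)
  h2 <- call_sensitizers(withpos, k = 3)
  expect_identical(h1$sensitizer,
                   h2$sensitizer[h2$reagent_class == "mimic"])
})

test_that("validation t-test matches Student's test with tiered stars", {
  vt <- function(cand_vals, ctrl_vals) {
    n1 <- length(cand_vals); n2 <- length(ctrl_vals)
    tab <- data.frame(
      reagent_id = c(rep("cand", n1), rep("ctrl", n2)),
      arm = "lapatinib",
      normalized_viability = c(cand_vals, ctrl_vals),
      stringsAsFactors = FALSE)
    validation_ttest(tab, "cand", "ctrl")
  }
  same <- vt(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(same$p, 1, tolerance = 1e-9)

  strong <- vt(c(0.2, 0.25, 0.3), c(0.9, 0.95, 1.0))
  expect_lt(strong$p, 0.001)
  expect_identical(strong$stars, "***")
  # closed-form Student's t with 4 df
  tt <- t.test(c(0.2, 0.25, 0.3), c(0.9, 0.95, 1.0), var.equal = TRUE)
  expect_equal(strong$p, tt$p.value, tolerance = 1e-12)

  # < 2 replicates: missing p
  single <- vt(0.2, c(0.9, 0.95, 1.0))
  expect_true(is.na(single$p))
})

test_that("hit + exclusion calls agree exactly with brute force on random tables", {
  for (seed in 1:25) {
    tab <- random_norm_screen(seed)
    hits <- call_sensitizers(tab, k = 3, no_drug_arm = "vehicle")
    hits <- apply_exclusions(hits, k = 3, no_drug_arm = "vehicle")
    bf <- bruteforce_hit_calls(tab, k = 3, no_drug_arm = "vehicle")
    expect_identical(hits$sensitizer, bf$sensitizer)
    expect_identical(hits$excluded_no_drug_effect, bf$excluded_no_drug_effect)
  }
})
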