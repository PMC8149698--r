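# Generators: determinism, layout, null calibration, ground-truth joins.

test_that("screen generator is seed-deterministic and lays out 384-well plates", {
  cfg <- tiny_screen_config(seed = 11)
  s1 <- generate_screen(cfg)
  s2 <- generate_screen(cfg)
  expect_identical(s1, s2)

  default_cfg <- screen_sim_config()
  expect_identical(default_cfg$plate_size, 384L)
  expect_identical(default_cfg$n_mimics + default_cfg$n_inhibitors, 1626L)

  per_plate <- table(s1$table$plate_id)
  expect_true(all(per_plate == cfg$plate_size))
  # every well identity unique
  key <- with(s1$table, paste(plate_id, row, col))
  expect_false(anyDuplicated(key) > 0)
})

test_that("screen config invariants are enforced", {
  expect_error(screen_sim_config(noise_sd_log2 = 0), class = "mirsens_config_error")
  expect_error(screen_sim_config(arms = c("vehicle", "vehicle", "lapatinib")),
               class = "mirsens_config_error")
  expect_error(screen_sim_config(n_neg_controls = 200, n_pos_controls = 200),
               class = "mirsens_config_error")
  expect_error(
    generate_screen(tiny_screen_config(spikes = list(
      spike_spec("mimic_9999", "mimic", "KPL4", "lapatinib", -1)))),
    class = "mirsens_config_error")
  expect_error(spike_spec("mimic_0001", "mimic", "KPL4", "lapatinib", 0.5),
               class = "mirsens_config_error")
})

test_that("ground truth entries join onto generated wells, and controls behave", {
  spikes <- list(
    spike_spec("mimic_0003", "mimic", c("KPL4", "SUM190PT"),
               c("lapatinib", "combination"), -0.8),
    spike_spec("inhibitor_0007", "inhibitor", "KPL4", "lapatinib", -0.8,
               also_toxic_without_drug = TRUE))
  s <- generate_screen(tiny_screen_config(seed = 3, spikes = spikes))
  gt <- s$ground_truth$spikes
  expect_true(all(gt$reagent_id %in% s$table$reagent_id))
  # also-toxic spike expands into the no-drug arm
  expect_true("vehicle" %in% gt$arm[gt$reagent_id == "inhibitor_0007"])
  # cell-death controls forced near background: well below library signal
  lib_med <- median(log2(s$table$raw_signal[
    s$table$reagent_class %in% c("mimic", "inhibitor")]))
  pos_med <- median(log2(s$table$raw_signal[
    s$table$reagent_class == "pos_control"]))
  expect_lt(pos_med, lib_med - 3)
})

test_that("null screens without spikes or gradient give normal per-arm values", {
  pass <- vapply(1:100, function(seed) {
    cfg <- screen_sim_config(n_mimics = 50, n_inhibitors = 50,
                             cell_lines = "KPL4",
                             arms = c("vehicle", "lapatinib"),
                             drug_effect_log2 = c(vehicle = 0, lapatinib = -0.3),
                             spatial_gradient_log2 = 0, seed = seed)
    tab <- generate_screen(cfg)$table
    lib <- tab[tab$reagent_class %in% c("mimic", "inhibitor"), ]
    ps <- vapply(split(log2(lib$raw_signal), lib$arm),
                 function(v) stats::shapiro.test(v)$p.value, numeric(1))
    all(ps > 0.01)
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("LMA generator: determinism, marker cardinality, null Z calibration", {
  l1 <- generate_lma(markers = paste0("M", 1:10), n_conditions = 30, seed = 5)
  l2 <- generate_lma(markers = paste0("M", 1:10), n_conditions = 30, seed = 5)
  expect_identical(l1, l2)
  expect_identical(length(unique(l1$table$protein)), 10L)

  big <- generate_lma(markers = "AKT", n_conditions = 1000, seed = 9)
  z <- zscore_and_call(sypro_log2(big$table), z_threshold = 2)
  frac <- mean(z$hit)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.10)
})

test_that("expression panel: determinism, flag propagation, null type-I", {
  p1 <- generate_expression_panel(n_probes = 50, seed = 2)
  p2 <- generate_expression_panel(n_probes = 50, seed = 2)
  expect_identical(p1, p2)

  # fully undetected probes are floored by preprocessing and recorded
  pre <- preprocess_expression(p1$expr)
  floored <- attr(pre, "floored_probes")
  expect_setequal(floored, p1$ground_truth$undetected_probes)
  expect_true(all(apply(pre$values[floored, , drop = FALSE], 1L,
                        function(v) length(unique(v)) == 1L)))

  # zero-effect panels: nominal 0.05 Kruskal-Wallis flags <= 8% of probes
  frac <- vapply(1:50, function(seed) {
    panel <- generate_expression_panel(cell_lines = c("KPL4", "SUM190PT"),
                                       n_probes = 40, n_replicates = 3,
                                       frac_undetected = 0, seed = seed)
    res <- kruskal_wallis_groups(panel$expr, "poor")
    mean(res$significant)
  }, numeric(1))
  expect_lte(mean(frac), 0.08)
})

test_that("cohort generator: copula calibration, censoring, determinism", {
  cs <- data.frame(mirna = "hsa-miR-sim-001", mrna = "GENE0001", rho = 0.8)
  cfg <- cohort_sim_config(n_patients = 1000, n_mirnas = 2, n_mrnas = 5,
                           corr_structure = cs, seed = 21)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  emp <- cor(c1$cohort$mirna[, "hsa-miR-sim-001"],
             c1$cohort$mrna[, "GENE0001"], method = "spearman")
  expect_gte(emp, 0.75)
  expect_lte(emp, 0.85)

  no_cens <- generate_cohort(cohort_sim_config(n_patients = 100,
                                               n_mirnas = 1, n_mrnas = 1,
                                               censor_rate = 0, seed = 4))
  expect_true(all(no_cens$cohort$patients$event == 1L))

  expect_error(cohort_sim_config(censor_rate = 1), class = "mirsens_config_error")
  expect_error(cohort_sim_config(stage_probs = c("1" = 0.5, "2" = 0.4)),
               class = "mirsens_config_error")
  # correlations that cannot coexist in a PSD matrix are rejected
  bad <- data.frame(mirna = c("hsa-miR-sim-001", "hsa-miR-sim-001",
                              "hsa-miR-sim-002"),
                    mrna = c("GENE0001", "GENE0002", "GENE0001"),
                    rho = c(0.99, 0.99, -0.99))
  expect_error(generate_cohort(cohort_sim_config(n_mirnas = 2, n_mrnas = 2,
                                                 corr_structure = bad,
                                                 seed = 1)),
               class = "mirsens_config_error")
})
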