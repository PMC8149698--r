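# End-to-end workflows: screen -> normalization -> hit calling ->
# candidates -> validation, and cohort -> correlation/stage/survival ->
# enrichment. Plain delimited-text artifacts plus a JSON manifest, fully
# reproducible from config + seed.

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      config_error(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a list or a YAML path")
  if (is.null(config$out_dir)) config_error("config must set out_dir")
  config
}

manifest_entry <- function(path, n_rows) {
  list(file = basename(path),
       md5 = unname(tools::md5sum(path)),
       rows = n_rows)
}

write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Untreated-cell expression and inhibitor target map implied by a
#' simulated screen
#'
#' For a simulated screen, builds the companion untreated-cell miRNA
#' expression object the exclusion step needs: every inhibitor maps to a
#' target probe that is detected/expressed, except inhibitors spiked with
#' `targets_expressed_mirna = FALSE`, whose targets are undetected.
#'
#' @param config the [screen_sim_config()] used for the screen.
#' @return list: `expr` (a `mirsens_expr` with one untreated sample per cell
#'   line) and `inhibitor_targets` (named map reagent id -> probe id).
#' @export
screen_expression_truth <- function(config) {
  reagents <- library_reagents(config)
  inhib <- reagents$reagent_id[reagents$reagent_class == "inhibitor"]
  probes <- paste0("mir_", inhib)
  targets <- setNames(probes, inhib)
  not_expr <- vapply(config$spikes, function(s) {
    if (s$class == "inhibitor" && !s$targets_expressed_mirna)
      s$reagent_id else NA_character_
  }, character(1))
  not_expr <- not_expr[!is.na(not_expr)]
  samples <- data.frame(sample_id = paste0(config$cell_lines, "_untreated"),
                        cell_line = config$cell_lines, arm = "untreated",
                        stringsAsFactors = FALSE)
  values <- matrix(8, nrow = length(probes), ncol = nrow(samples),
                   dimnames = list(probes, samples$sample_id))
  detected <- matrix(TRUE, nrow = length(probes), ncol = nrow(samples),
                     dimnames = dimnames(values))
  if (length(not_expr) > 0L) {
    detected[targets[not_expr], ] <- FALSE
    values[targets[not_expr], ] <- 2
  }
  list(expr = new_mirsens_expr(values, detected, samples),
       inhibitor_targets = targets)
}

#' Generate a synthetic validation plate set for candidate reagents
#'
#' Emulates the confirmation experiment: candidates plus a scrambled
#' negative control and a cell-death positive control, replicated on one
#' plate per treatment arm, with true effects taken from the screen's
#' ground-truth spikes.
#'
#' @param candidates character vector of candidate reagent ids.
#' @param config the screen's [screen_sim_config()] (drug effects, noise and
#'   baseline are reused).
#' @param truth_spikes expanded spike table from [generate_screen()]'s
#'   ground truth.
#' @param cell_line cell line to validate in.
#' @param n_replicates replicate wells per reagent per arm (default 9:
#'   three biological x three technical).
#' @param seed integer seed.
#' @return a screen table ready for [negcontrol_normalize()].
#' @export
generate_validation_screen <- function(candidates, config, truth_spikes,
                                       cell_line = config$cell_lines[[1L]],
                                       n_replicates = 9L, seed = 1L) {
  set.seed(as.integer(seed))
  out <- list()
  for (arm in config$arms) {
    ids <- c(candidates, "scrambled_control", "death_control")
    classes <- c(rep("mimic", length(candidates)), "neg_control",
                 "pos_control")
    reag <- rep(ids, each = n_replicates)
    cls <- rep(classes, each = n_replicates)
    eff <- numeric(length(reag))
    sp <- truth_spikes[truth_spikes$cell_line == cell_line &
                         truth_spikes$arm == arm, , drop = FALSE]
    m <- match(reag, sp$reagent_id)
    eff[!is.na(m)] <- sp$effect_log2[m[!is.na(m)]]
    l2 <- config$baseline_log2 + config$drug_effect_log2[[arm]] + eff +
      rnorm(length(reag), 0, config$noise_sd_log2)
    l2[cls == "pos_control"] <- config$baseline_log2 - 5 +
      rnorm(sum(cls == "pos_control"), 0, config$noise_sd_log2)
    n <- length(reag)
    out[[length(out) + 1L]] <- data.frame(
      plate_id = sprintf("validation_%s_%s", cell_line, arm),
      row = (seq_len(n) - 1L) %/% 12L, col = (seq_len(n) - 1L) %% 12L,
      reagent_id = reag, reagent_class = cls, cell_line = cell_line,
      arm = arm, raw_signal = 2^l2, normalized_viability = NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the screen workflow: normalize, call hits, select and validate
#' candidates
#'
#' Stages: (1) loess + log2 normalization of the screen table, (2) group
#' statistics per (cell line, arm), (3) sensitizer calling with both
#' exclusion criteria, (4) multi-context candidate selection, (5, optional)
#' validation t-tests on a control-normalized replicate experiment. Each
#' stage writes a tab-separated artifact; a JSON manifest records the
#' resolved configuration, seed, row counts and file digests, so a rerun
#' with the same config and inputs reproduces every artifact byte for byte.
#'
#' @param config list or YAML path with elements: `out_dir`; `seed`;
#'   either `simulate` (arguments for [screen_sim_config()], with optional
#'   `spikes` given as lists) or `screen_path` (a TSV for
#'   [read_screen_table()]); optional `expr_prefix` for
#'   [read_expression()] plus `inhibitor_target_path` (TSV with
#'   `reagent_id`, `mirna` columns); `k` (default 3); `loess`
#'   (span/degree/fit_wells); `run_validation` (default `TRUE`).
#' @return the manifest, invisibly; artifacts under `config$out_dir`.
#' @export
run_screen_workflow <- function(config) {
  config <- resolve_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  k <- config$k %||% 3
  run_validation <- config$run_validation %||% TRUE

  truth <- NULL
  sim_config <- NULL
  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (!is.null(args$spikes))
      args$spikes <- lapply(args$spikes, function(s) do.call(spike_spec, s))
    args$seed <- args$seed %||% seed
    sim_config <- do.call(screen_sim_config, args)
    sim <- generate_screen(sim_config)
    screen <- sim$table
    truth <- sim$ground_truth
  } else if (!is.null(config$screen_path)) {
    screen <- read_screen_table(config$screen_path)
  } else {
    config_error("config must provide either simulate or screen_path")
  }

  lo <- config$loess %||% list()
  cfg <- loess_config(span = lo$span %||% 0.5, degree = lo$degree %||% 1,
                      fit_wells = lo$fit_wells %||% "library_only")
  no_drug_arm <- config$no_drug_arm %||%
    (if (!is.null(sim_config)) sim_config$no_drug_arm else "vehicle")

  stages <- list()
  normalized <- loess_log2_normalize(screen, cfg)
  p <- file.path(out_dir, "normalized_screen.tsv")
  write_screen_table(normalized, p)
  stages$normalized_screen <- manifest_entry(p, nrow(normalized))

  stats <- group_stats(normalized)
  p <- file.path(out_dir, "group_stats.tsv")
  write_tsv(stats, p)
  stages$group_stats <- manifest_entry(p, nrow(stats))

  hits <- call_sensitizers(normalized, stats, k = k,
                           no_drug_arm = no_drug_arm)
  if (!is.null(config$expr_prefix)) {
    expr <- read_expression(config$expr_prefix)
    tmap <- if (!is.null(config$inhibitor_target_path)) {
      tm <- read_tsv(config$inhibitor_target_path)
      stopifnot_columns(tm, c("reagent_id", "mirna"), "inhibitor target map")
      setNames(tm$mirna, tm$reagent_id)
    } else NULL
    hits <- apply_exclusions(hits, expr = expr, inhibitor_targets = tmap,
                             k = k, no_drug_arm = no_drug_arm)
  } else if (!is.null(sim_config)) {
    et <- screen_expression_truth(sim_config)
    hits <- apply_exclusions(hits, expr = et$expr,
                             inhibitor_targets = et$inhibitor_targets,
                             k = k, no_drug_arm = no_drug_arm)
  } else {
    hits <- apply_exclusions(hits, expr = NULL, k = k,
                             no_drug_arm = no_drug_arm)
  }
  hits <- select_candidates(hits)
  p <- file.path(out_dir, "hit_table.tsv")
  write_tsv(hits, p)
  stages$hit_table <- manifest_entry(p, nrow(hits))

  cands <- candidate_ids(hits)
  cand_df <- data.frame(reagent_id = cands, stringsAsFactors = FALSE)
  p <- file.path(out_dir, "candidates.tsv")
  write_tsv(cand_df, p)
  stages$candidates <- manifest_entry(p, nrow(cand_df))

  skipped <- list()
  if (isTRUE(run_validation)) {
    if (!is.null(truth) && length(cands) > 0L) {
      vtab <- generate_validation_screen(cands, sim_config, truth$spikes,
                                         seed = seed + 1L)
      vnorm <- negcontrol_normalize(vtab)
      vres <- validation_ttest(vnorm, cands, "scrambled_control")
    } else if (!is.null(config$validation_path)) {
      vnorm <- negcontrol_normalize(read_screen_table(config$validation_path))
      vres <- validation_ttest(vnorm, cands,
                               config$validation_control_id %||%
                                 "scrambled_control")
    } else {
      vres <- NULL
      skipped$validation <- "no validation data and no simulated truth"
    }
    if (!is.null(vres)) {
      p <- file.path(out_dir, "validation_ttest.tsv")
      write_tsv(vres, p)
      stages$validation_ttest <- manifest_entry(p, nrow(vres))
    }
  }

  manifest <- list(workflow = "screen",
                   package_version = as.character(packageVersion("mirsens")),
                   seed = seed, k = k,
                   loess = list(span = cfg$span, degree = cfg$degree,
                                fit_wells = cfg$fit_wells),
                   n_candidates = length(cands),
                   stages = stages, skipped = skipped)
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

#' Run the clinical workflow: correlation, stage, survival, enrichment
#'
#' Stages: (1) per-miRNA Spearman correlation against all mRNAs with BH
#' control, (2) pairwise Wilcoxon stage comparisons with small-stage
#' exclusion, (3) median-split Kaplan-Meier log-rank per miRNA and
#' endpoint, (4) hypergeometric ORA of each miRNA's significantly
#' correlated mRNAs against a GMT collection, with the measured mRNAs as
#' universe. A stage whose inputs are missing (e.g. no stage column) is
#' skipped with a recorded reason; the rest complete.
#'
#' @param config list or YAML path with elements: `out_dir`; `seed`;
#'   either `simulate` (arguments for [cohort_sim_config()], with
#'   `corr_structure` as a data.frame-able list) or `cohort_prefix`
#'   (TSV prefix: `<prefix>_patients.tsv`, `<prefix>_mirna.tsv`,
#'   `<prefix>_mrna.tsv`); optional `mirna_ids`, `endpoints`
#'   (default both `os` and `bcss`), `gmt_path`, `target_map_path`,
#'   `bh_scope`, `min_stage_group`.
#' @return the manifest, invisibly; artifacts under `config$out_dir`.
#' @export
run_clinical_workflow <- function(config) {
  config <- resolve_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)

  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (!is.null(args$corr_structure))
      args$corr_structure <- as.data.frame(args$corr_structure,
                                           stringsAsFactors = FALSE)
    for (fld in c("stage_effects", "hazard_log_hr", "stage_probs"))
      if (!is.null(args[[fld]])) args[[fld]] <- unlist(args[[fld]])
    args$seed <- args$seed %||% seed
    sim <- generate_cohort(do.call(cohort_sim_config, args))
    cohort <- sim$cohort
  } else if (!is.null(config$cohort_prefix)) {
    cohort <- read_cohort(config$cohort_prefix)
  } else {
    config_error("config must provide either simulate or cohort_prefix")
  }
  validate_cohort(cohort)
  mirna_ids <- config$mirna_ids %||% colnames(cohort$mirna)
  endpoints <- config$endpoints %||% c("os", "bcss")

  stages <- list()
  skipped <- list()

  corr <- mirna_mrna_correlation(cohort, mirna_ids,
                                 bh_scope = config$bh_scope %||% "per_mirna")
  p <- file.path(out_dir, "correlations.tsv")
  write_tsv(corr, p)
  stages$correlations <- manifest_entry(p, nrow(corr))

  if (!is.null(cohort$patients$stage)) {
    st <- stage_comparison(cohort, mirna_ids,
                           min_group = config$min_stage_group %||% 5L)
    p <- file.path(out_dir, "stage_tests.tsv")
    write_tsv(st, p)
    stages$stage_tests <- manifest_entry(p, nrow(st))
  } else {
    skipped$stage_tests <- "cohort has no stage column"
  }

  surv_rows <- list()
  for (ep in endpoints) {
    if (ep == "bcss" && is.null(cohort$patients$cause)) {
      skipped$survival_bcss <- "no cause-of-death column"
      next
    }
    for (id in mirna_ids) {
      r <- median_split_survival(cohort, id, endpoint = ep)
      surv_rows[[length(surv_rows) + 1L]] <- data.frame(
        mirna = id, endpoint = ep, chisq = r$chisq, p = r$p,
        n_low = r$group_sizes[["low"]], n_high = r$group_sizes[["high"]],
        stringsAsFactors = FALSE)
    }
  }
  surv <- do.call(rbind, surv_rows)
  p <- file.path(out_dir, "survival.tsv")
  write_tsv(surv, p)
  stages$survival <- manifest_entry(p, nrow(surv))

  gmt_path <- config$gmt_path %||%
    system.file("extdata", "synthetic_pathways_demo.gmt",
                package = "mirsens")
  tmap_path <- config$target_map_path %||%
    system.file("extdata", "synthetic_target_map.tsv", package = "mirsens")
  if (nzchar(gmt_path) && file.exists(gmt_path)) {
    collection <- read_gmt(gmt_path)
    tmap <- if (nzchar(tmap_path) && file.exists(tmap_path))
      read_target_map(tmap_path) else NULL
    enr_rows <- list()
    for (id in mirna_ids) {
      sig_mrnas <- corr$mrna[corr$mirna == id & corr$significant]
      query <- if (!is.null(tmap)) {
        union(sig_mrnas, suppressWarnings(collect_targets(id, tmap)))
      } else sig_mrnas
      if (length(query) == 0L) next
      res <- overrepresentation(query, collection,
                                universe = colnames(cohort$mrna))
      if (nrow(res) > 0L) {
        res <- cbind(mirna = id, res, stringsAsFactors = FALSE)
        enr_rows[[length(enr_rows) + 1L]] <- res
      }
    }
    enr <- if (length(enr_rows) > 0L) do.call(rbind, enr_rows) else
      data.frame(mirna = character(0), set = character(0),
                 set_size = integer(0), overlap = integer(0),
                 p = numeric(0), p_adj = numeric(0),
                 significant = logical(0), stringsAsFactors = FALSE)
    p <- file.path(out_dir, "enrichment.tsv")
    write_tsv(enr, p)
    stages$enrichment <- manifest_entry(p, nrow(enr))
  } else {
    skipped$enrichment <- "no gene-set (GMT) file available"
  }

  manifest <- list(workflow = "clinical",
                   package_version = as.character(packageVersion("mirsens")),
                   seed = seed, endpoints = endpoints,
                   stages = stages, skipped = skipped)
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

#' Write a cohort to tab-separated files
#' @param cohort cohort list (`patients`, `mirna`, `mrna`).
#' @param prefix output path prefix.
#' @return file paths, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  paths <- paste0(prefix, c("_patients.tsv", "_mirna.tsv", "_mrna.tsv"))
  write_tsv(cohort$patients, paths[1L])
  write_tsv(data.frame(patient_id = rownames(cohort$mirna), cohort$mirna,
                       check.names = FALSE), paths[2L])
  write_tsv(data.frame(patient_id = rownames(cohort$mrna), cohort$mrna,
                       check.names = FALSE), paths[3L])
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#' @param prefix path prefix.
#' @return cohort list.
#' @export
read_cohort <- function(prefix) {
  patients <- read_tsv(paste0(prefix, "_patients.tsv"))
  mi <- read_tsv(paste0(prefix, "_mirna.tsv"))
  mr <- read_tsv(paste0(prefix, "_mrna.tsv"))
  mirna <- as.matrix(mi[, -1L, drop = FALSE])
  rownames(mirna) <- mi$patient_id
  mrna <- as.matrix(mr[, -1L, drop = FALSE])
  rownames(mrna) <- mr$patient_id
  list(patients = patients, mirna = mirna, mrna = mrna)
}
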