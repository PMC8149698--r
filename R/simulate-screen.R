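# Synthetic arrayed-screen generator. Emulates a 384-well mimic/inhibitor
# viability screen run per cell line and treatment arm, with plate spatial
# bias, control wells, drug main effects and spiked drug-conditional
# sensitizer effects, plus a ground-truth record for recovery testing.

SCREEN_COLUMNS <- c("plate_id", "row", "col", "reagent_id", "reagent_class",
                    "cell_line", "arm", "raw_signal", "normalized_viability")
REAGENT_CLASSES <- c("mimic", "inhibitor", "neg_control", "pos_control", "empty")

#' Configuration for the synthetic viability screen
#'
#' Defaults mirror the screen the pipeline was designed for: 810 miRNA mimics
#' and 816 inhibitors transfected into two poorly drug-responsive HER2+ cell
#' lines (KPL4, SUM190PT) on 384-well plates, under four treatment arms
#' (vehicle, 10 ug/mL trastuzumab, 100 nM lapatinib, and the combination).
#' Viability effects are additive on the log2 luminescence scale, i.e.
#' multiplicative on the raw scale.
#'
#' @param n_mimics,n_inhibitors library sizes; reduced sizes are fine for
#'   quick tests.
#' @param cell_lines character vector of cell-line labels.
#' @param arms treatment-arm labels; must contain `no_drug_arm` exactly once.
#' @param no_drug_arm label of the vehicle/no-drug arm.
#' @param plate_size wells per plate (default 384, laid out 16 x 24).
#' @param n_neg_controls,n_pos_controls control wells per plate. Negative
#'   controls carry no reagent effect; positive controls are a cell-death
#'   control forced near background signal.
#' @param baseline_log2 log2 luminescence of untreated, unperturbed wells.
#' @param drug_effect_log2 named additive log2 shift per arm. The defaults
#'   encode viability reductions of about 4%, 17% and 33% for trastuzumab,
#'   lapatinib and the combination.
#' @param spatial_gradient_log2 maximum amplitude of the per-plate linear
#'   row/column bias (log2 units); each plate draws its own gradient.
#' @param bowl_log2 amplitude of an optional smooth radial "bowl" bias.
#' @param noise_sd_log2 residual Gaussian SD on the log2 scale.
#' @param spikes list of [spike_spec()] entries defining true sensitizers.
#' @param n_replicates wells per reagent per (cell line, arm); the screen
#'   design implies a single well, so the default is 1.
#' @param seed integer seed; same config + seed gives identical output.
#' @return a list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_mimics = 810L,
                              n_inhibitors = 816L,
                              cell_lines = c("KPL4", "SUM190PT"),
                              arms = c("vehicle", "trastuzumab",
                                       "lapatinib", "combination"),
                              no_drug_arm = "vehicle",
                              plate_size = 384L,
                              n_neg_controls = 16L,
                              n_pos_controls = 8L,
                              baseline_log2 = 10,
                              drug_effect_log2 = c(vehicle = 0,
                                                   trastuzumab = -0.06,
                                                   lapatinib = -0.27,
                                                   combination = -0.58),
                              spatial_gradient_log2 = 0.5,
                              bowl_log2 = 0,
                              noise_sd_log2 = 0.15,
                              spikes = list(),
                              n_replicates = 1L,
                              seed = 1L) {
  if (!is_count(n_mimics) || !is_count(n_inhibitors))
    config_error("n_mimics and n_inhibitors must be non-negative integers")
  if (sum(no_drug_arm == arms) != 1L)
    config_error("arms must contain the no-drug arm exactly once")
  if (!is.numeric(noise_sd_log2) || noise_sd_log2 <= 0)
    config_error("noise_sd_log2 must be > 0")
  n_controls <- n_neg_controls + n_pos_controls
  if (n_controls >= plate_size)
    config_error("plate capacity exceeded: controls fill the whole plate")
  if (!all(arms %in% names(drug_effect_log2)))
    config_error("drug_effect_log2 must name every arm")
  structure(list(
    n_mimics = as.integer(n_mimics), n_inhibitors = as.integer(n_inhibitors),
    cell_lines = cell_lines, arms = arms, no_drug_arm = no_drug_arm,
    plate_size = as.integer(plate_size),
    n_neg_controls = as.integer(n_neg_controls),
    n_pos_controls = as.integer(n_pos_controls),
    baseline_log2 = baseline_log2, drug_effect_log2 = drug_effect_log2,
    spatial_gradient_log2 = spatial_gradient_log2, bowl_log2 = bowl_log2,
    noise_sd_log2 = noise_sd_log2, spikes = spikes,
    n_replicates = as.integer(n_replicates), seed = as.integer(seed)
  ), class = "screen_sim_config")
}

#' Describe one spiked (ground-truth) sensitizer
#'
#' @param reagent_id library reagent id (must exist in the generated library).
#' @param class `"mimic"` or `"inhibitor"`.
#' @param cell_lines cell lines in which the effect applies.
#' @param arms treatment arms in which the effect applies (drug arms for a
#'   pure sensitizer).
#' @param effect_log2 additive log2 viability change; negative for a
#'   sensitizer.
#' @param also_toxic_without_drug if `TRUE` the same effect is additionally
#'   applied in the no-drug arm, which the exclusion criteria must catch.
#' @param targets_expressed_mirna inhibitors only: whether the inhibitor's
#'   target miRNA is endogenously expressed in untreated cells.
#' @return a list of class `spike_spec`.
#' @export
spike_spec <- function(reagent_id, class, cell_lines, arms, effect_log2,
                       also_toxic_without_drug = FALSE,
                       targets_expressed_mirna = TRUE) {
  if (!class %in% c("mimic", "inhibitor"))
    config_error("spike class must be 'mimic' or 'inhibitor'")
  if (effect_log2 >= 0)
    config_error("sensitizer effect_log2 must be negative")
  structure(list(reagent_id = reagent_id, class = class,
                 cell_lines = cell_lines, arms = arms,
                 effect_log2 = effect_log2,
                 also_toxic_without_drug = isTRUE(also_toxic_without_drug),
                 targets_expressed_mirna = isTRUE(targets_expressed_mirna)),
            class = "spike_spec")
}

library_reagents <- function(config) {
  data.frame(
    reagent_id = c(sprintf("mimic_%04d", seq_len(config$n_mimics)),
                   sprintf("inhibitor_%04d", seq_len(config$n_inhibitors))),
    reagent_class = rep(c("mimic", "inhibitor"),
                        c(config$n_mimics, config$n_inhibitors)),
    stringsAsFactors = FALSE
  )
}

# Deterministic plate layout: control wells at evenly spaced well indices,
# library reagents filling the rest in order.
plate_layout <- function(plate_size, n_neg, n_pos) {
  idx <- seq_len(plate_size)
  n_ctrl <- n_neg + n_pos
  ctrl_pos <- if (n_ctrl > 0L)
    unique(round(seq(1L, plate_size, length.out = n_ctrl))) else integer(0)
  # rounding collisions are only possible for absurd control counts
  stopifnot(length(ctrl_pos) == n_ctrl)
  classes <- rep("library", plate_size)
  classes[ctrl_pos] <- rep(c("neg_control", "pos_control"), c(n_neg, n_pos))
  ncol_plate <- if (plate_size == 384L) 24L else ceiling(sqrt(plate_size))
  data.frame(well = idx,
             row = (idx - 1L) %/% ncol_plate,
             col = (idx - 1L) %% ncol_plate,
             slot = classes,
             stringsAsFactors = FALSE)
}

spike_effect_table <- function(spikes, no_drug_arm) {
  if (length(spikes) == 0L) {
    return(data.frame(reagent_id = character(0), cell_line = character(0),
                      arm = character(0), effect_log2 = numeric(0),
                      also_toxic_without_drug = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(spikes, function(s) {
    arms <- s$arms
    if (s$also_toxic_without_drug) arms <- unique(c(arms, no_drug_arm))
    expand <- expand.grid(cell_line = s$cell_lines, arm = arms,
                          stringsAsFactors = FALSE)
    data.frame(reagent_id = s$reagent_id, cell_line = expand$cell_line,
               arm = expand$arm, effect_log2 = s$effect_log2,
               also_toxic_without_drug = s$also_toxic_without_drug,
               stringsAsFactors = FALSE)
  }))
}

#' Generate a synthetic arrayed viability screen with ground truth
#'
#' One row per well. Raw luminescence is
#' `2^(baseline + drug effect + spatial surface + spike effect + noise)`.
#' Negative-control wells carry no reagent effect; positive (cell-death)
#' control wells are forced near background (baseline - 5 log2, about 3%
#' viability). The `normalized_viability` column is `NA` until a
#' normalization step fills it.
#'
#' @param config a [screen_sim_config()].
#' @return list with `table` (the per-well screen table) and `ground_truth`
#'   (list with `spikes`, the expanded per-(reagent, cell line, arm) effect
#'   table, and `spike_specs`, the original specs).
#' @export
generate_screen <- function(config) {
  if (!inherits(config, "screen_sim_config"))
    config_error("config must be a screen_sim_config")
  reagents <- library_reagents(config)
  lib_per_plate <- config$plate_size - config$n_neg_controls -
    config$n_pos_controls
  if (lib_per_plate < 1L)
    config_error("plate capacity exceeded: no room for library wells")
  n_lib <- nrow(reagents)
  n_plates <- ceiling(n_lib / lib_per_plate)

  spikes <- spike_effect_table(config$spikes, config$no_drug_arm)
  unknown <- setdiff(spikes$reagent_id, reagents$reagent_id)
  if (length(unknown) > 0L)
    config_error(sprintf("spiked reagent(s) not in library: %s",
                         paste(unique(unknown), collapse = ", ")))

  layout <- plate_layout(config$plate_size, config$n_neg_controls,
                         config$n_pos_controls)
  lib_slots <- which(layout$slot == "library")

  set.seed(config$seed)
  out <- vector("list", length(config$cell_lines) * length(config$arms) *
                  config$n_replicates * n_plates)
  k <- 0L
  for (cl in config$cell_lines) {
    for (arm in config$arms) {
      for (rep_i in seq_len(config$n_replicates)) {
        for (p in seq_len(n_plates)) {
          k <- k + 1L
          lo <- (p - 1L) * lib_per_plate + 1L
          hi <- min(p * lib_per_plate, n_lib)
          plate_reagents <- reagents[lo:hi, , drop = FALSE]
          n_on_plate <- nrow(plate_reagents)

          tab <- layout
          tab$reagent_id <- NA_character_
          tab$reagent_class <- "empty"
          fill <- lib_slots[seq_len(n_on_plate)]
          tab$reagent_id[fill] <- plate_reagents$reagent_id
          tab$reagent_class[fill] <- plate_reagents$reagent_class
          ctrl <- layout$slot != "library"
          tab$reagent_class[ctrl] <- layout$slot[ctrl]
          tab$reagent_id[ctrl] <- paste0(layout$slot[ctrl], "_",
                                         seq_len(sum(ctrl)))

          # per-plate spatial bias: linear row + column gradients (amplitude
          # drawn per plate) and an optional fixed radial bowl
          g_row <- runif(1, -1, 1) * config$spatial_gradient_log2
          g_col <- runif(1, -1, 1) * config$spatial_gradient_log2
          nr <- max(tab$row) + 1L; nc <- max(tab$col) + 1L
          surf <- g_row * (tab$row / max(nr - 1L, 1L) - 0.5) +
            g_col * (tab$col / max(nc - 1L, 1L) - 0.5)
          if (config$bowl_log2 != 0) {
            r2 <- ((tab$row - (nr - 1) / 2) / nr)^2 +
              ((tab$col - (nc - 1) / 2) / nc)^2
            surf <- surf + config$bowl_log2 * (r2 / max(r2) - 0.5)
          }

          eff <- numeric(nrow(tab))
          if (nrow(spikes) > 0L) {
            sp <- spikes[spikes$cell_line == cl & spikes$arm == arm, ,
                         drop = FALSE]
            if (nrow(sp) > 0L) {
              m <- match(tab$reagent_id, sp$reagent_id)
              eff[!is.na(m)] <- sp$effect_log2[m[!is.na(m)]]
            }
          }

          log2sig <- config$baseline_log2 +
            config$drug_effect_log2[[arm]] + surf + eff +
            rnorm(nrow(tab), 0, config$noise_sd_log2)
          # cell-death control: near-background signal regardless of arm
          pos <- tab$reagent_class == "pos_control"
          log2sig[pos] <- config$baseline_log2 - 5 +
            rnorm(sum(pos), 0, config$noise_sd_log2)

          rep_tag <- if (config$n_replicates > 1L)
            sprintf("_r%d", rep_i) else ""
          out[[k]] <- data.frame(
            plate_id = sprintf("%s_%s%s_p%02d", cl, arm, rep_tag, p),
            row = tab$row, col = tab$col,
            reagent_id = tab$reagent_id,
            reagent_class = tab$reagent_class,
            cell_line = cl, arm = arm,
            raw_signal = 2^log2sig,
            normalized_viability = NA_real_,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  table <- do.call(rbind, out)
  rownames(table) <- NULL
  list(table = table,
       ground_truth = list(spikes = spikes, spike_specs = config$spikes))
}

#' Generate synthetic lysate-microarray (LMA) protein data
#'
#' Per (condition, marker) raw antibody intensity paired with a total-protein
#' (Sypro) reference intensity. The reference acts multiplicatively: the
#' antibody signal is the condition's Sypro level times `2^(marker baseline +
#' effect + noise)`, so `log2(raw / sypro)` is Gaussian for null markers.
#'
#' @param markers non-empty character vector of protein markers.
#' @param n_conditions number of conditions (reagent x arm x cell line
#'   combinations) per cell line.
#' @param cell_lines cell-line labels.
#' @param effects optional data.frame (condition, cell_line, marker,
#'   shift_log2) of true deregulations, echoed back as ground truth.
#' @param marker_baseline_log2,noise_sd_log2 marker log2 baseline and
#'   residual SD.
#' @param sypro_baseline_log2,sypro_sd_log2 total-protein reference level.
#' @param seed integer seed.
#' @return list with `table` (condition, cell_line, arm, protein, raw, sypro)
#'   and `ground_truth` (the `effects` table).
#' @export
generate_lma <- function(markers,
                         n_conditions = 96L,
                         cell_lines = "KPL4",
                         effects = NULL,
                         marker_baseline_log2 = 8,
                         noise_sd_log2 = 0.4,
                         sypro_baseline_log2 = 9,
                         sypro_sd_log2 = 0.3,
                         seed = 1L) {
  if (length(markers) == 0L) config_error("markers must be non-empty")
  set.seed(as.integer(seed))
  arms <- c("vehicle", "trastuzumab", "lapatinib", "combination")
  out <- list()
  for (cl in cell_lines) {
    cond <- sprintf("%s_cond_%04d", cl, seq_len(n_conditions))
    cond_arm <- arms[((seq_len(n_conditions) - 1L) %% length(arms)) + 1L]
    sypro <- 2^(sypro_baseline_log2 + rnorm(n_conditions, 0, sypro_sd_log2))
    for (mk in markers) {
      shift <- numeric(n_conditions)
      if (!is.null(effects)) {
        e <- effects[effects$marker == mk & effects$cell_line == cl, ,
                     drop = FALSE]
        m <- match(cond, e$condition)
        shift[!is.na(m)] <- e$shift_log2[m[!is.na(m)]]
      }
      raw <- sypro * 2^(marker_baseline_log2 + shift +
                          rnorm(n_conditions, 0, noise_sd_log2))
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, cell_line = cl, arm = cond_arm, protein = mk,
        raw = raw, sypro = sypro, stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, out)
  rownames(table) <- NULL
  list(table = table, ground_truth = list(effects = effects))
}

#' Generate a synthetic miRNA expression panel
#'
#' Probe x sample log2 expression with per-(probe, sample) detection flags
#' and sample metadata (cell line, treatment arm, responder class), emulating
#' a one-color miRNA microarray experiment across treated cell lines.
#'
#' @param cell_lines cell-line labels.
#' @param arms treatment arms (first is conventionally untreated/vehicle).
#' @param n_probes number of miRNA probes.
#' @param effects optional data.frame (probe, arm, responder_class,
#'   shift_log2); `responder_class = "all"` applies in every cell line.
#' @param n_replicates samples per (cell line, arm).
#' @param responder_map named character vector mapping cell line to
#'   `"responsive"` or `"poor"`; default matches the four HER2+ lines used
#'   throughout (SKBR3/BT-474 responsive, KPL4/SUM190PT poor).
#' @param frac_undetected fraction of probes undetected in every sample
#'   (below the array's detection call).
#' @param noise_sd_log2 residual SD.
#' @param seed integer seed.
#' @return list with `expr` (a `mirsens_expr`: `values` matrix, `detected`
#'   logical matrix, `samples` metadata) and `ground_truth` (`effects`,
#'   `undetected_probes`).
#' @export
generate_expression_panel <- function(cell_lines = c("SKBR3", "BT-474",
                                                     "KPL4", "SUM190PT"),
                                      arms = c("untreated", "trastuzumab",
                                               "lapatinib", "combination"),
                                      n_probes = 200L,
                                      effects = NULL,
                                      n_replicates = 3L,
                                      responder_map = c("SKBR3" = "responsive",
                                                        "BT-474" = "responsive",
                                                        "KPL4" = "poor",
                                                        "SUM190PT" = "poor"),
                                      frac_undetected = 0.05,
                                      noise_sd_log2 = 0.5,
                                      seed = 1L) {
  set.seed(as.integer(seed))
  samples <- expand.grid(replicate = seq_len(n_replicates), arm = arms,
                         cell_line = cell_lines, stringsAsFactors = FALSE)
  samples$responder_class <- unname(responder_map[samples$cell_line])
  samples$responder_class[is.na(samples$responder_class)] <- "poor"
  samples$sample_id <- sprintf("%s_%s_r%d", samples$cell_line, samples$arm,
                               samples$replicate)
  probes <- sprintf("hsa-miR-sim-%04d", seq_len(n_probes))
  baseline <- runif(n_probes, 6, 13)
  n_undet <- round(frac_undetected * n_probes)
  undetected <- if (n_undet > 0L) probes[seq_len(n_undet)] else character(0)

  values <- matrix(baseline, nrow = n_probes, ncol = nrow(samples)) +
    matrix(rnorm(n_probes * nrow(samples), 0, noise_sd_log2),
           nrow = n_probes)
  dimnames(values) <- list(probes, samples$sample_id)
  if (!is.null(effects)) {
    for (i in seq_len(nrow(effects))) {
      e <- effects[i, ]
      sel <- samples$arm == e$arm &
        (e$responder_class == "all" |
           samples$responder_class == e$responder_class)
      values[e$probe, sel] <- values[e$probe, sel] + e$shift_log2
    }
  }
  detected <- matrix(TRUE, nrow = n_probes, ncol = nrow(samples),
                     dimnames = dimnames(values))
  detected[undetected, ] <- FALSE
  # undetected features sit at the scanner floor
  values[undetected, ] <- matrix(rnorm(length(undetected) * nrow(samples),
                                       2, 0.2), nrow = length(undetected))
  expr <- new_mirsens_expr(values, detected, samples)
  list(expr = expr,
       ground_truth = list(effects = effects, undetected_probes = undetected))
}

#' Expression container used across the pipeline
#'
#' @param values numeric probe x sample matrix (log2 scale).
#' @param detected logical matrix of the same shape (detection calls).
#' @param samples data.frame of per-sample metadata with a `sample_id`
#'   column matching `colnames(values)`.
#' @return object of class `mirsens_expr`.
#' @export
new_mirsens_expr <- function(values, detected, samples) {
  stopifnot(is.matrix(values), is.logical(detected),
            all(dim(values) == dim(detected)))
  stopifnot_columns(samples, "sample_id", "sample metadata")
  if (!identical(colnames(values), samples$sample_id))
    format_error("colnames(values) must match samples$sample_id in order")
  structure(list(values = values, detected = detected, samples = samples),
            class = "mirsens_expr")
}

#' @export
print.mirsens_expr <- function(x, ...) {
  cat(sprintf("mirsens_expr: %d probes x %d samples (%.1f%% detected)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$detected)))
  invisible(x)
}
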