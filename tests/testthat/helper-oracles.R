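# Independent oracles used by the property and acceptance tests. These are
# deliberately naive re-implementations (loops, enumeration, closed forms)
# kept separate from the package's own code paths.

# Brute-force sensitizer + criterion-1 exclusion caller: recomputes each
# group's median and sample SD with plain loops over wells.
bruteforce_hit_calls <- function(table, k = 3, no_drug_arm = "vehicle") {
  lib <- table[table$reagent_class %in% c("mimic", "inhibitor"), ]
  n <- nrow(lib)
  sens <- logical(n)
  excl <- logical(n)
  group_of <- paste(lib$cell_line, lib$arm)
  med <- list(); sdv <- list()
  for (g in unique(group_of)) {
    v <- lib$normalized_viability[group_of == g]
    med[[g]] <- median(v)
    sdv[[g]] <- if (length(v) >= 2) sd(v) else 0
  }
  for (i in seq_len(n)) {
    g <- group_of[i]
    if (sdv[[g]] > 0 && lib$arm[i] != no_drug_arm &&
        lib$normalized_viability[i] < med[[g]] - k * sdv[[g]]) {
      sens[i] <- TRUE
    }
  }
  # criterion 1: toxic without drug, per (reagent, cell line)
  for (i in seq_len(n)) {
    if (lib$arm[i] != no_drug_arm) next
    g <- group_of[i]
    if (sdv[[g]] > 0 &&
        (lib$normalized_viability[i] - med[[g]]) / sdv[[g]] <= -k) {
      hit_rows <- which(lib$reagent_id == lib$reagent_id[i] &
                          lib$cell_line == lib$cell_line[i])
      sens[hit_rows] <- FALSE
      excl[hit_rows] <- TRUE
    }
  }
  data.frame(reagent_id = lib$reagent_id, cell_line = lib$cell_line,
             arm = lib$arm, sensitizer = sens,
             excluded_no_drug_effect = excl, stringsAsFactors = FALSE)
}

# Random screen table with normalized values already present (the oracle
# targets the calling logic, not normalization).
random_norm_screen <- function(seed, max_wells = 1000L) {
  set.seed(seed)
  n_cl <- sample(1:2, 1)
  cls <- c("KPL4", "SUM190PT")[seq_len(n_cl)]
  arms <- c("vehicle", "lapatinib", "combination")
  per_group <- sample(20:floor(max_wells / (n_cl * 3)), 1)
  rows <- list()
  for (cl in cls) for (arm in arms) {
    n <- per_group
    cls_vec <- sample(c("mimic", "inhibitor", "neg_control", "pos_control"),
                      n, replace = TRUE, prob = c(.45, .45, .05, .05))
    rows[[length(rows) + 1L]] <- data.frame(
      plate_id = paste0(cl, "_", arm, "_p1"),
      row = (seq_len(n) - 1L) %/% 24L, col = (seq_len(n) - 1L) %% 24L,
      reagent_id = ifelse(cls_vec %in% c("mimic", "inhibitor"),
                          sprintf("rg_%03d", seq_len(n)),
                          sprintf("ctrl_%03d", seq_len(n))),
      reagent_class = cls_vec, cell_line = cl, arm = arm,
      raw_signal = 1000,
      normalized_viability = rnorm(n, 10, 0.5) -
        rexp(n, 4) * rbinom(n, 1, 0.05),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Exhaustive Kruskal-Wallis permutation p-value for 4 groups of 3 distinct
# values (369,600 equally likely assignments enumerated via combinations).
kw_perm_pvalue <- function(x) {
  stopifnot(length(x) == 12L, !anyDuplicated(x))
  r <- rank(x)
  H_of <- function(R1, R2, R3, R4) {
    12 / (12 * 13) * ((R1^2 + R2^2 + R3^2 + R4^2) / 3) - 3 * 13
  }
  obs <- H_of(sum(r[1:3]), sum(r[4:6]), sum(r[7:9]), sum(r[10:12]))
  idx <- seq_len(12L)
  A <- utils::combn(idx, 3L)
  count <- 0L; total <- 0L
  for (a in seq_len(ncol(A))) {
    g1 <- A[, a]; R1 <- sum(r[g1])
    rest1 <- setdiff(idx, g1)
    B <- utils::combn(rest1, 3L)
    for (b in seq_len(ncol(B))) {
      g2 <- B[, b]; R2 <- sum(r[g2])
      rest2 <- setdiff(rest1, g2)
      C <- utils::combn(rest2, 3L)
      R3s <- colSums(matrix(r[C], nrow = 3L))
      R4s <- sum(r[rest2]) - R3s
      Hs <- H_of(R1, R2, R3s, R4s)
      count <- count + sum(Hs >= obs - 1e-12)
      total <- total + length(Hs)
    }
  }
  count / total
}

# Exact two-sided rank-sum p by enumerating all choose(6, 3) assignments.
ranksum_exact_pvalue <- function(x, y) {
  stopifnot(length(x) == 3L, length(y) == 3L)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[1:3])
  combos <- utils::combn(6L, 3L)
  sums <- colSums(matrix(r[combos], nrow = 3L))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

# Hand-computed two-group log-rank chi-squared from the risk table
# (observed minus expected over hypergeometric variance).
logrank_oracle_chisq <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2L)
  g1 <- unique(group)[1L]
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1L]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Benjamini-Hochberg step-up with explicit monotonicity enforcement.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Small deterministic screen config for unit tests.
tiny_screen_config <- function(seed = 1L, spikes = list(), ...) {
  screen_sim_config(n_mimics = 60L, n_inhibitors = 60L,
                    cell_lines = c("KPL4", "SUM190PT"),
                    spikes = spikes, seed = seed, ...)
}

# Spike set used for recovery experiments: 20 pure sensitizers at
# -5 * noise SD in the drug arms of both cell lines, plus 5 strongly
# cytotoxic reagents (-8 * noise SD) that are also toxic without drug.
recovery_spike_set <- function(seed, noise_sd = 0.15) {
  lib <- c(sprintf("mimic_%04d", 1:810), sprintf("inhibitor_%04d", 1:816))
  set.seed(seed)
  ids <- sample(lib, 25)
  cls <- function(id) if (grepl("^mimic", id)) "mimic" else "inhibitor"
  drug_arms <- c("trastuzumab", "lapatinib", "combination")
  spikes <- c(
    lapply(ids[1:20], function(id)
      spike_spec(id, cls(id), c("KPL4", "SUM190PT"), drug_arms,
                 -5 * noise_sd)),
    lapply(ids[21:25], function(id)
      spike_spec(id, cls(id), c("KPL4", "SUM190PT"), drug_arms,
                 -8 * noise_sd, also_toxic_without_drug = TRUE)))
  list(spikes = spikes, sensitizers = ids[1:20], toxic = ids[21:25])
}

run_recovery <- function(seed, noise_sd = 0.15) {
  sp <- recovery_spike_set(seed, noise_sd)
  cfg <- screen_sim_config(spikes = sp$spikes, noise_sd_log2 = noise_sd,
                           seed = seed + 1000L)
  s <- generate_screen(cfg)
  norm <- loess_log2_normalize(s$table)
  hits <- call_sensitizers(norm, no_drug_arm = "vehicle")
  et <- screen_expression_truth(cfg)
  hits <- apply_exclusions(hits, et$expr, et$inhibitor_targets)
  hits <- select_candidates(hits)
  cands <- candidate_ids(hits)
  list(sensitivity = mean(sp$sensitizers %in% cands),
       fdp = if (length(cands) > 0) mean(!cands %in% sp$sensitizers) else 0,
       n_toxic_candidates = sum(sp$toxic %in% cands))
}
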