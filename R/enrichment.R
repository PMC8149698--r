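# miRNA target collection and local over-representation analysis (ORA):
# a user-supplied miRNA -> target map joined to user GMT gene sets, tested
# with the hypergeometric upper tail and BH correction.

TARGET_TIERS <- c("experimentally_observed", "high_prediction")

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name, description,
#' member1, member2, ...`. Member symbols are upper-cased and deduplicated;
#' the universe is the union of all members.
#'
#' @param path GMT file path.
#' @return list of class `gene_set_collection`: `sets` (named list of
#'   character vectors), `descriptions`, `universe`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      format_error(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    members <- unique(toupper(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      format_error(sprintf("malformed GMT line %d: empty set", i))
    sets[[fields[1L]]] <- members
    descs[fields[1L]] <- fields[2L]
  }
  structure(list(sets = sets, descriptions = descs,
                 universe = sort(unique(unlist(sets)))),
            class = "gene_set_collection")
}

#' Read a miRNA -> target-gene map
#'
#' Tab-separated columns `mirna, gene, tier` with tier one of
#' `experimentally_observed` / `high_prediction`. Duplicate (miRNA, gene)
#' pairs are collapsed keeping the strongest tier.
#'
#' @param path file path.
#' @return data.frame (mirna, gene, tier).
#' @export
read_target_map <- function(path) {
  df <- read_tsv(path)
  stopifnot_columns(df, c("mirna", "gene", "tier"), "target map")
  bad <- setdiff(unique(df$tier), TARGET_TIERS)
  if (length(bad) > 0L)
    format_error(sprintf("unknown evidence tier(s): %s",
                         paste(bad, collapse = ", ")))
  df$gene <- toupper(df$gene)
  df$tier <- factor(df$tier, levels = TARGET_TIERS)
  df <- df[order(df$mirna, df$gene, df$tier), ]
  df <- df[!duplicated(df[, c("mirna", "gene")]), ]
  df$tier <- as.character(df$tier)
  rownames(df) <- NULL
  df
}

#' Collect target genes of a set of miRNAs
#'
#' Union of the mapped targets of the given miRNAs, restricted to the
#' requested evidence tiers. miRNAs absent from the map raise a warning and
#' are skipped.
#'
#' @param mirnas character vector of miRNA ids.
#' @param target_map data.frame (mirna, gene, tier), e.g. from
#'   [read_target_map()].
#' @param tiers evidence tiers to keep.
#' @return sorted character vector of unique target gene symbols.
#' @export
collect_targets <- function(mirnas, target_map, tiers = TARGET_TIERS) {
  if (!all(tiers %in% TARGET_TIERS))
    config_error(sprintf("tiers must be a subset of {%s}",
                         paste(TARGET_TIERS, collapse = ", ")))
  if (length(mirnas) == 0L) return(character(0))
  missing <- setdiff(mirnas, unique(target_map$mirna))
  if (length(missing) > 0L)
    warning(sprintf("miRNA(s) absent from target map, skipped: %s",
                    paste(missing, collapse = ", ")))
  sel <- target_map$mirna %in% mirnas & target_map$tier %in% tiers
  sort(unique(toupper(target_map$gene[sel])))
}

#' Hypergeometric over-representation analysis against gene sets
#'
#' For each gene set, tests whether the query list overlaps it more than
#' expected when drawing `|query|` genes at random from the universe:
#' upper-tail hypergeometric p = P(X >= overlap), one-sided. P-values are
#' BH-corrected across sets and flagged at adjusted p < `alpha`. Query
#' genes outside the universe are dropped and counted.
#'
#' @param query character vector of query gene symbols.
#' @param collection a [read_gmt()] result.
#' @param universe background gene universe; default the collection's union
#'   of members. Override with, e.g., all measured mRNAs.
#' @param alpha significance level on adjusted p (default 0.05).
#' @return data.frame (set, set_size, overlap, p, p_adj, significant),
#'   sorted by p; the number of dropped query genes is in the
#'   `"dropped_query_genes"` attribute.
#' @export
overrepresentation <- function(query, collection, universe = NULL,
                               alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- sort(unique(toupper(universe %||% collection$universe)))
  query <- unique(toupper(query))
  dropped <- sum(!query %in% universe)
  query <- intersect(query, universe)
  empty <- data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  if (length(query) == 0L) {
    attr(empty, "reason") <- "empty query after universe filtering"
    attr(empty, "dropped_query_genes") <- dropped
    return(empty)
  }
  N <- length(universe); q <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    m <- length(members)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1L, m, N - m, q, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_query_genes") <- dropped
  out
}
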