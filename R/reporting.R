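#' Best-matching protein group per disease group
#'
#' For each DiG in an overlap table, selects the group with the smallest
#' FDR-adjusted p-value. Ties are broken by larger overlap size, then by
#' lexicographic group identifier. When `alpha` is given, only DiGs whose
#' best match reaches `p_fdr <= alpha` are returned.
#'
#' @param overlaps Overlap table from [dig_group_overlap()].
#' @param alpha Optional FDR cutoff for reporting a best match.
#' @return Tibble with one row per DiG: `dig_id`, `group_id`,
#'   `overlap_size`, `p_fdr`.
#' @export
best_matches <- function(overlaps, alpha = NULL) {
  if (nrow(overlaps) == 0L) {
    return(tibble(dig_id = integer(), group_id = character(),
                  overlap_size = integer(), p_fdr = double()))
  }
  out <- overlaps %>%
    dplyr::group_by(.data$dig_id) %>%
    dplyr::arrange(.data$p_fdr, dplyr::desc(.data$overlap_size),
                   .data$group_id, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup() %>%
    dplyr::select("dig_id", "group_id", "overlap_size", "p_fdr")
  if (!is.null(alpha)) out <- out[out$p_fdr <= alpha, , drop = FALSE]
  out
}

#' Per-DiG significance verdicts across data types
#'
#' Combines overlap tables for the n-ary, regenerated and pathway data
#' types with the binary enrichment table into one row of verdicts per
#' DiG: a significance flag and (where applicable) the best-matching group
#' per data type. Flags follow the configured thresholds: FDR-adjusted
#' p <= `alpha_group` for the three group-overlap types, raw
#' p < `alpha_binary` for binary enrichment.
#'
#' @param digs Disease-group tibble (supplies the DiG universe).
#' @param nary,regen,pathway Overlap tables from [dig_group_overlap()]
#'   (any may be `NULL`).
#' @param binary Enrichment table from [binary_enrichment()] (or `NULL`).
#' @param alpha_group FDR cutoff for group overlaps (default 0.05).
#' @param alpha_binary Raw cutoff for binary enrichment (default 0.0004).
#' @return Tibble with `dig_id`, `sig_nary`, `sig_regen`, `sig_binary`,
#'   `sig_pathway`, and `best_*`/`best_*_p` columns per group data type.
#' @export
dig_verdicts <- function(digs, nary = NULL, regen = NULL, binary = NULL,
                         pathway = NULL, alpha_group = 0.05,
                         alpha_binary = 4e-4) {
  out <- tibble(dig_id = digs$dig_id)
  add_type <- function(out, overlaps, label) {
    flag_col <- paste0("sig_", label)
    id_col <- paste0("best_", label)
    p_col <- paste0("best_", label, "_p")
    if (is.null(overlaps) || nrow(overlaps) == 0L) {
      out[[flag_col]] <- FALSE
      out[[id_col]] <- NA_character_
      out[[p_col]] <- NA_real_
      return(out)
    }
    bm <- best_matches(overlaps, alpha = alpha_group)
    idx <- match(out$dig_id, bm$dig_id)
    out[[flag_col]] <- !is.na(idx)
    out[[id_col]] <- bm$group_id[idx]
    out[[p_col]] <- bm$p_fdr[idx]
    out
  }
  out <- add_type(out, nary, "nary")
  out <- add_type(out, regen, "regen")
  if (is.null(binary) || nrow(binary) == 0L) {
    out$sig_binary <- FALSE
  } else {
    sig <- binary$dig_id[!is.na(binary$significant) & binary$significant &
                           binary$p_raw < alpha_binary]
    out$sig_binary <- out$dig_id %in% sig
  }
  out <- add_type(out, pathway, "pathway")
  out
}

#' Venn partition of significant disease groups
#'
#' Counts, for the chosen data types, how many DiGs are significant in
#' exactly each non-empty combination of types. The regions are disjoint
#' and sum to the number of DiGs significant in at least one chosen type.
#'
#' @param verdicts Verdict table from [dig_verdicts()].
#' @param sets Data types to partition over, a subset of
#'   `c("nary", "regen", "binary", "pathway")`.
#' @return Tibble with `region` (type names joined by `+`) and `count`,
#'   covering all `2^length(sets) - 1` non-empty regions.
#' @export
venn_partition <- function(verdicts, sets = c("nary", "regen", "binary")) {
  sets <- match.arg(sets, c("nary", "regen", "binary", "pathway"),
                    several.ok = TRUE)
  flags <- as.matrix(verdicts[paste0("sig_", sets)])
  colnames(flags) <- sets
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  region <- apply(combos, 1L, function(m) paste(sets[as.logical(m)], collapse = "+"))
  count <- apply(combos, 1L, function(m)
    sum(apply(flags, 1L, function(f) all(f == as.logical(m)))))
  tibble(region = region, count = as.integer(count))
}

#' Source-database attribution of best-matching complexes
#'
#' Tallies the distinct best-matching complexes by the set of source
#' databases describing them; complexes reported by several databases are
#' counted once, under the combined label (e.g. `"intact & mint"`).
#'
#' @param best Best-match table from [best_matches()].
#' @param groups Complex tibble with `group_id`-compatible identifiers in
#'   `complex_id` (or `key`) and a `source_dbs` list column.
#' @return Tibble with `label` and `n_complexes`, plus attribute
#'   `n_best_matches` (the number of DiG best matches tallied).
#' @export
database_attribution <- function(best, groups) {
  id_col <- if ("complex_id" %in% names(groups)) "complex_id" else "key"
  idx <- match(unique(best$group_id), groups[[id_col]])
  if (anyNA(idx)) {
    abort("best-match group(s) missing from the complex table.")
  }
  labels <- vapply(groups$source_dbs[idx], function(dbs)
    paste(sort(dbs), collapse = " & "), "")
  tab <- sort(table(labels), decreasing = TRUE)
  out <- tibble(label = names(tab), n_complexes = as.integer(tab))
  attr(out, "n_best_matches") <- nrow(best)
  out
}

#' Low-throughput fraction of best-matching complexes
#'
#' Counts how many complexes carry an lpr score below the threshold. The
#' lpr ("literature publication reuse") score of a record is the number of
#' interactions its publication contributed; a small value indicates a
#' low-throughput study, so complexes with `lpr_min < threshold` are taken
#' as supported by low-throughput evidence.
#'
#' @param lpr Integer vector of per-complex lpr scores (`lpr_min`).
#' @param threshold Cutoff (default 22).
#' @return List with `count_low`, `count_total` and `n_excluded` (missing
#'   lpr values, excluded with a message).
#' @export
low_throughput_fraction <- function(lpr, threshold = 22L) {
  n_excluded <- sum(is.na(lpr))
  if (n_excluded > 0L) {
    inform(sprintf("%d complex(es) without lpr excluded from the low-throughput tally.",
                   n_excluded))
  }
  lpr <- lpr[!is.na(lpr)]
  list(count_low = sum(lpr < threshold), count_total = length(lpr),
       n_excluded = n_excluded)
}

#' Compare two survey run summaries
#'
#' Side-by-side metric table for two runs with the same metric schema
#' (e.g. record counts, group counts and significant-match counts per data
#' type), with deltas. Metrics missing from either run raise an error that
#' names them.
#'
#' @param summary_a,summary_b Named lists (or single-level named numeric
#'   vectors) of run metrics.
#' @param labels Column labels for the two runs.
#' @return Tibble with `metric`, the two runs' values and `delta`.
#' @export
compare_runs <- function(summary_a, summary_b, labels = c("run_a", "run_b")) {
  a <- unlist(summary_a)
  b <- unlist(summary_b)
  missing_b <- setdiff(names(a), names(b))
  missing_a <- setdiff(names(b), names(a))
  if (length(missing_a) || length(missing_b)) {
    abort(paste0("run summaries disagree on metrics. ",
                 if (length(missing_b)) paste0("Missing from ", labels[[2L]], ": ",
                                               paste(missing_b, collapse = ", "), ". "),
                 if (length(missing_a)) paste0("Missing from ", labels[[1L]], ": ",
                                               paste(missing_a, collapse = ", "), ".")))
  }
  b <- b[names(a)]
  out <- tibble(metric = names(a), a = as.numeric(a), b = as.numeric(b),
                delta = as.numeric(b) - as.numeric(a))
  names(out)[2:3] <- labels
  out
}

#' Export a network for Cytoscape
#'
#' Writes a SIF edge file plus node- and edge-attribute TSVs that Cytoscape
#' can load directly. For DiG-complex overlap networks the node type
#' attribute encodes the rendering convention (circle for disease groups,
#' hexagon for complexes) and the edge weight is the Jaccard index of the
#' overlap.
#'
#' @param edges Tibble with columns `source`, `target` and optionally
#'   further edge attributes (e.g. `jaccard`).
#' @param nodes Optional tibble with column `node` and node attributes
#'   (e.g. `type`).
#' @param prefix Output path prefix; writes `<prefix>.sif`,
#'   `<prefix>_edge_attrs.tsv` and (when `nodes` given)
#'   `<prefix>_node_attrs.tsv`.
#' @param relation SIF relation label (default `"overlap"`).
#' @return Named character vector of written paths, invisibly.
#' @export
export_cytoscape <- function(edges, nodes = NULL, prefix, relation = "overlap") {
  sif_path <- paste0(prefix, ".sif")
  sif <- if (nrow(edges) > 0L) {
    paste(edges$source, relation, edges$target, sep = "\t")
  } else character()
  writeLines(sif, sif_path)
  paths <- c(sif = sif_path)
  ea_path <- paste0(prefix, "_edge_attrs.tsv")
  ea <- edges
  ea$edge <- paste(edges$source, paste0("(", relation, ")"), edges$target)
  utils::write.table(ea[c("edge", setdiff(names(edges), c("source", "target")))],
                     ea_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, edge_attrs = ea_path)
  if (!is.null(nodes)) {
    na_path <- paste0(prefix, "_node_attrs.tsv")
    utils::write.table(nodes, na_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, node_attrs = na_path)
  }
  invisible(paths)
}

#' Read a SIF edge file
#'
#' @param path SIF path as written by [export_cytoscape()].
#' @return Tibble with `source`, `relation`, `target`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(source = character(), relation = character(),
                  target = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(source = vapply(parts, `[[`, "", 1L),
         relation = vapply(parts, `[[`, "", 2L),
         target = vapply(parts, `[[`, "", 3L))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line with name, description and tab-separated
#' member identifiers.
#'
#' @param path GMT path.
#' @return Tibble with `set_name`, `description`, `members` (list column;
#'   integer-looking members are converted to integers).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(set_name = character(), description = character(),
                  members = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                  paste(which(bad), collapse = ", ")))
  }
  members <- lapply(parts, function(p) {
    m <- p[-(1:2)]
    if (all(grepl("^[0-9]+$", m))) as.integer(m) else m
  })
  tibble(set_name = vapply(parts, `[[`, "", 1L),
         description = vapply(parts, `[[`, "", 2L),
         members = members)
}
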