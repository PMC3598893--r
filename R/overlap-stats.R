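#' Upper-tail hypergeometric probability
#'
#' P(X >= k) when drawing `sample_size` items without replacement from a
#' population of `population_size` items of which `success_population` are
#' successes. Computed exactly on the log scale via [stats::phyper()]; no
#' normal approximation is used anywhere in the package, since p-values of
#' interest span many orders of magnitude (down to 1e-12 and below).
#'
#' @param k Observed number of successes (vectorized).
#' @param success_population Number of successes in the population.
#' @param population_size Total population size.
#' @param sample_size Number of draws.
#' @return Numeric vector of tail probabilities in [0, 1].
#' @export
hyper_upper_tail <- function(k, success_population, population_size, sample_size) {
  if (any(success_population > population_size) || any(sample_size > population_size)) {
    abort("success population and sample size must not exceed the population size.")
  }
  if (any(k > pmin(success_population, sample_size))) {
    abort("observed successes exceed min(success population, sample size).")
  }
  stats::phyper(k - 1, success_population,
                population_size - success_population,
                sample_size, lower.tail = FALSE)
}

#' Similarity indices between two finite sets
#'
#' Computes the four classical overlap indices used to compare a disease
#' group with a protein group: Jaccard `|A n B| / |A u B|`, Meet/Min
#' `|A n B| / min(|A|, |B|)`, Geometric `|A n B|^2 / (|A| |B|)` and the
#' Hypergeometric index, defined as `-log p` of the upper-tail
#' hypergeometric probability of the observed overlap, normalized to [0, 1]
#' by its value at the maximum possible overlap `min(|A|, |B|)`.
#'
#' @param set_a,set_b Vectors treated as sets (duplicates removed).
#' @param population_size Population size for the hypergeometric index; if
#'   `NULL` the index is returned as `NA` (the other three indices do not
#'   need it).
#' @return A one-row tibble with columns `jaccard`, `meet_min`, `geometric`,
#'   `hypergeom_index`. If both sets are empty every index is `NA`.
#' @examples
#' similarity_indices(c("a", "b", "c"), c("b", "c", "d"))
#' @export
similarity_indices <- function(set_a, set_b, population_size = NULL) {
  a <- unique(set_a)
  b <- unique(set_b)
  na <- length(a)
  nb <- length(b)
  if (na == 0L && nb == 0L) {
    return(tibble(jaccard = NA_real_, meet_min = NA_real_,
                  geometric = NA_real_, hypergeom_index = NA_real_))
  }
  ov <- length(intersect(a, b))
  jac <- ov / length(union(a, b))
  mm <- if (min(na, nb) == 0L) 0 else ov / min(na, nb)
  geo <- if (na == 0L || nb == 0L) 0 else ov^2 / (na * nb)
  hyp <- NA_real_
  if (!is.null(population_size)) {
    population_size <- check_count(population_size, "population_size", min = 0L)
    hyp <- hypergeom_index(ov, na, nb, population_size)
  }
  tibble(jaccard = jac, meet_min = mm, geometric = geo, hypergeom_index = hyp)
}

# Normalized -log tail probability; 0 for empty overlap, 1 for full overlap.
hypergeom_index <- function(overlap, n_a, n_b, population_size) {
  if (n_a == 0L || n_b == 0L) return(0)
  max_ov <- min(n_a, n_b)
  log_p <- stats::phyper(overlap - 1, n_b, population_size - n_b, n_a,
                         lower.tail = FALSE, log.p = TRUE)
  log_p_full <- stats::phyper(max_ov - 1, n_b, population_size - n_b, n_a,
                              lower.tail = FALSE, log.p = TRUE)
  if (log_p_full == 0) return(if (overlap == max_ov) 1 else 0)
  min(1, max(0, log_p / log_p_full))
}

#' Type-1 overlap test between a disease group and a protein group
#'
#' Upper-tail hypergeometric test for the overlap between a disease group
#' (DiG) and a protein group (complex, regenerated complex or pathway).
#' The population is the total number of distinct proteins in DiGs plus
#' groups (supplied by the caller), the success population is the protein
#' group, the sample is the DiG, and the success sample is the intersection
#' of the DiG's mapped proteins with the group.
#'
#' Genes without a canonical protein still count towards the DiG's sample
#' size through `n_unmapped`: they can never intersect a protein group but
#' remain members of the disease group for statistical purposes, which makes
#' the test conservative for partially mapped DiGs.
#'
#' @param dig_proteins Mapped canonical protein IDs of the DiG.
#' @param group_proteins Canonical protein IDs of the protein group.
#' @param population_size Total number of distinct proteins considered.
#' @param n_unmapped Number of DiG genes with no canonical protein.
#' @return The raw upper-tail p-value.
#' @examples
#' # 10 proteins overall, group of 4, DiG of 3 fully contained in the group:
#' overlap_test_type1(1:3, 1:4, population_size = 10)  # 4/120
#' @export
overlap_test_type1 <- function(dig_proteins, group_proteins, population_size,
                               n_unmapped = 0L) {
  dig_proteins <- unique(dig_proteins)
  group_proteins <- unique(group_proteins)
  n_unmapped <- check_count(n_unmapped, "n_unmapped", min = 0L)
  population_size <- check_count(population_size, "population_size", min = 1L)
  sample_size <- length(dig_proteins) + n_unmapped
  overlap <- length(intersect(dig_proteins, group_proteins))
  hyper_upper_tail(overlap, length(group_proteins), population_size, sample_size)
}

#' Adjust p-values for multiple testing
#'
#' Thin validated wrapper over [stats::p.adjust()] exposing the three
#' corrections used in the survey: Bonferroni, Benjamini-Hochberg false
#' discovery rate (`"fdr"`) and Benjamini-Yekutieli (`"by"`).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method One of `"bonferroni"`, `"fdr"`, `"by"`.
#' @param n Number of tests in the family (defaults to `length(p)`).
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "fdr", "by"),
                           n = length(p)) {
  method <- match.arg(method)
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("`p` must be numeric in [0, 1] with no missing values.")
  }
  method <- switch(method, bonferroni = "bonferroni", fdr = "BH", by = "BY")
  stats::p.adjust(p, method = method, n = n)
}

#' Overlap statistics between disease groups and protein groups
#'
#' Scores every (DiG, group) combination with the four similarity indices
#' and the type-1 hypergeometric test, then adjusts p-values for multiple
#' testing. By default the adjustment family is per DiG across all groups of
#' the data type under test (each group counted as one test); set
#' `family = "global"` to correct over all (DiG, group) pairs jointly.
#'
#' @param digs Disease-group tibble as returned by [build_disease_groups()]
#'   (needs `dig_id`, `mapped_protein_ids`, `unmapped_gene_ids`).
#' @param groups Tibble with columns `group_id` and `members` (list column
#'   of canonical protein IDs), e.g. from [extract_complexes()],
#'   [regenerate()] or [read_gmt()] after gene-to-protein mapping.
#' @param population_size Population for the type-1 test. `NULL` (default)
#'   uses the joint union of all proteins appearing in the supplied DiGs and
#'   groups, plus one slot per unmapped DiG gene.
#' @param family Adjustment family, `"per_dig"` or `"global"`.
#' @param keep_zero Keep rows with zero overlap (default drops them; they
#'   still count in the adjustment family either way).
#' @return Tibble with one row per (DiG, group) pair: sizes, overlap,
#'   indices and `p_raw`, `p_bonferroni`, `p_fdr`, `p_by`.
#' @export
dig_group_overlap <- function(digs, groups, population_size = NULL,
                              family = c("per_dig", "global"),
                              keep_zero = FALSE) {
  family <- match.arg(family)
  if (nrow(digs) == 0L || nrow(groups) == 0L) {
    return(tibble(dig_id = integer(), group_id = character(),
                  dig_size = integer(), group_size = integer(),
                  overlap_size = integer(), jaccard = double(),
                  meet_min = double(), geometric = double(),
                  hypergeom_index = double(), p_raw = double(),
                  p_bonferroni = double(), p_fdr = double(), p_by = double()))
  }
  dig_prot <- lapply(digs$mapped_protein_ids, unique)
  dig_unmapped <- vapply(digs$unmapped_gene_ids, function(x) length(unique(x)), 0L)
  grp_prot <- lapply(groups$members, unique)
  if (is.null(population_size)) {
    population_size <- length(unique(c(unlist(dig_prot), unlist(grp_prot)))) +
      sum(dig_unmapped)
  }
  res <- vector("list", nrow(digs))
  for (i in seq_len(nrow(digs))) {
    a <- dig_prot[[i]]
    n_a <- length(a) + dig_unmapped[[i]]
    rows <- lapply(seq_len(nrow(groups)), function(j) {
      b <- grp_prot[[j]]
      ov <- length(intersect(a, b))
      idx <- similarity_indices(a, b, population_size = population_size)
      p <- hyper_upper_tail(ov, length(b), population_size, n_a)
      tibble(dig_id = digs$dig_id[[i]],
             group_id = as.character(groups$group_id[[j]]),
             dig_size = as.integer(n_a), group_size = length(b),
             overlap_size = as.integer(ov),
             jaccard = idx$jaccard, meet_min = idx$meet_min,
             geometric = idx$geometric, hypergeom_index = idx$hypergeom_index,
             p_raw = p)
    })
    res[[i]] <- dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(res)
  adj_in <- if (family == "per_dig") out$dig_id else rep(1L, nrow(out))
  out$p_bonferroni <- stats::ave(out$p_raw, adj_in,
                                 FUN = function(p) adjust_pvalues(p, "bonferroni"))
  out$p_fdr <- stats::ave(out$p_raw, adj_in,
                          FUN = function(p) adjust_pvalues(p, "fdr"))
  out$p_by <- stats::ave(out$p_raw, adj_in,
                         FUN = function(p) adjust_pvalues(p, "by"))
  if (!keep_zero) out <- out[out$overlap_size > 0L, , drop = FALSE]
  as_tibble(out)
}

#' Complex span of disease groups
#'
#' For each DiG, the "complex span" is the number of protein groups sharing
#' at least one subunit with it; `n_sig_raw` counts spanned groups with raw
#' p < `alpha_raw` and `n_sig_adj` those with FDR-adjusted p <= `alpha_adj`.
#'
#' @param overlaps Overlap table from [dig_group_overlap()] (zero-overlap
#'   rows may be present or absent; they never count).
#' @param alpha_raw Raw significance cutoff (default 0.05).
#' @param alpha_adj FDR-adjusted cutoff (default 0.05).
#' @return Tibble with `dig_id`, `span`, `n_sig_raw`, `n_sig_adj`.
#' @export
complex_span <- function(overlaps, alpha_raw = 0.05, alpha_adj = 0.05) {
  ov <- overlaps[overlaps$overlap_size > 0L, , drop = FALSE]
  if (nrow(ov) == 0L) {
    return(tibble(dig_id = integer(), span = integer(),
                  n_sig_raw = integer(), n_sig_adj = integer()))
  }
  ov %>%
    dplyr::group_by(.data$dig_id) %>%
    dplyr::summarise(span = dplyr::n(),
                     n_sig_raw = sum(.data$p_raw < alpha_raw),
                     n_sig_adj = sum(.data$p_fdr <= alpha_adj),
                     .groups = "drop")
}

#' Binary-interaction enrichment of disease groups (type-2 test)
#'
#' Tests whether the proteins of a DiG are connected by more binary
#' interactions than expected. The population is the number of possible
#' unordered pairs among all network nodes, the success population is the
#' number of documented edges, the sample is the number of possible pairs
#' among the DiG's mapped proteins, and the observed successes are the
#' edges of the network that join two DiG proteins. The upper-tail
#' hypergeometric probability is reported; by default enrichment is called
#' at raw p < 0.0004, a cutoff chosen to reproduce the decisions of the
#' degree-matched Monte-Carlo null (see [mc_degree_matched_null()]), which
#' corrects for the fact that high-degree proteins acquire interactions more
#' easily than the hypergeometric model assumes.
#'
#' @param digs Disease-group tibble (`dig_id`, `mapped_protein_ids`).
#' @param pin A [protein_network()].
#' @param alpha Significance cutoff on the raw p-value (default 0.0004).
#' @return Tibble with one row per DiG: `n_proteins`, `n_possible_pairs`,
#'   `k_observed_edges`, `p_raw`, `significant`, `testable`. DiGs with
#'   fewer than two mapped proteins are flagged untestable (`p_raw = NA`).
#' @export
binary_enrichment <- function(digs, pin, alpha = 4e-4) {
  stopifnot(inherits(pin, "protein_network"))
  n_nodes <- length(pin$nodes)
  n_pop <- n_possible_pairs(n_nodes)
  n_edges <- nrow(pin$edges)
  edge_keys <- pair_key(pin$edges$a, pin$edges$b)
  rows <- lapply(seq_len(nrow(digs)), function(i) {
    prot <- unique(digs$mapped_protein_ids[[i]])
    m <- length(prot)
    if (m < 2L) {
      return(tibble(dig_id = digs$dig_id[[i]], n_proteins = m,
                    n_possible_pairs = 0, k_observed_edges = NA_integer_,
                    p_raw = NA_real_, significant = NA, testable = FALSE))
    }
    pairs <- utils::combn(sort(prot), 2L)
    k <- sum(pair_key(pairs[1L, ], pairs[2L, ]) %in% edge_keys)
    p <- hyper_upper_tail(k, n_edges, n_pop, ncol(pairs))
    tibble(dig_id = digs$dig_id[[i]], n_proteins = m,
           n_possible_pairs = ncol(pairs), k_observed_edges = as.integer(k),
           p_raw = p, significant = p < alpha, testable = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Degree-matched Monte-Carlo null for binary enrichment
#'
#' Empirical null for the edge count among a DiG's proteins that conditions
#' on node degree: in each simulation every DiG protein is replaced by a
#' network node drawn uniformly from the nodes whose degree lies within a
#' multiplicative band around the protein's own degree (without replacement
#' within one simulation), and the edges among the sampled nodes are
#' counted. The empirical p-value uses the standard +1 correction,
#' `(1 + #{simulated count >= observed}) / (1 + n_sims)`, so it can never be
#' exactly zero.
#'
#' If a degree band contains fewer candidates than needed it is widened
#' stepwise (multiplying the band limits by the band factor) with a message.
#'
#' @param dig_proteins Canonical protein IDs; all must be network nodes.
#' @param pin A [protein_network()].
#' @param n_sims Number of simulations (default 10000).
#' @param band Multiplicative degree band `c(lower, upper)`; a protein of
#'   degree d admits replacements of degree in `[d * band[1], d * band[2]]`
#'   (default `c(0.5, 2)`).
#' @param seed RNG seed; mandatory so the null is reproducible.
#' @return List with `p_mc`, `observed`, `n_sims`, `sim_counts`.
#' @export
mc_degree_matched_null <- function(dig_proteins, pin, n_sims = 10000,
                                   band = c(0.5, 2), seed) {
  stopifnot(inherits(pin, "protein_network"))
  if (missing(seed)) abort("`seed` is required for the Monte-Carlo null.")
  n_sims <- check_count(n_sims, "n_sims")
  dig_proteins <- unique(dig_proteins)
  if (!all(dig_proteins %in% pin$nodes)) {
    abort("every DiG protein must be a node of the network.")
  }
  m <- length(dig_proteins)
  nodes <- pin$nodes
  deg <- pin$degree[match(nodes, names(pin$degree))]
  adj <- Matrix::sparseMatrix(
    i = match(pin$edges$a, nodes), j = match(pin$edges$b, nodes),
    x = 1, dims = c(length(nodes), length(nodes)), symmetric = TRUE)
  dig_idx <- match(dig_proteins, nodes)
  observed <- sum(adj[dig_idx, dig_idx, drop = FALSE]) / 2
  # candidate pools per DiG protein, widening empty bands stepwise
  pools <- lapply(dig_idx, function(i) {
    d <- deg[[i]]
    lo <- d * band[[1]]; hi <- d * band[[2]]
    cand <- which(deg >= lo & deg <= hi)
    widenings <- 0L
    while (length(cand) < m) {
      lo <- lo * band[[1]]; hi <- hi * band[[2]]
      if (d == 0) { lo <- 0; hi <- max(hi, widenings + 1) }
      cand <- which(deg >= lo & deg <= hi)
      widenings <- widenings + 1L
      if (widenings > 64L) { cand <- seq_along(nodes); break }
    }
    if (widenings > 0L) {
      inform(sprintf("degree band for degree-%d protein widened %d time(s)",
                     d, widenings))
    }
    cand
  })
  counts <- with_seed(seed, {
    vapply(seq_len(n_sims), function(s) {
      picked <- integer(m)
      for (j in seq_len(m)) {
        cand <- setdiff(pools[[j]], picked[seq_len(j - 1L)])
        if (length(cand) == 0L) cand <- setdiff(seq_along(nodes), picked[seq_len(j - 1L)])
        picked[[j]] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      }
      sum(adj[picked, picked, drop = FALSE]) / 2
    }, 0)
  })
  p_mc <- (1 + sum(counts >= observed)) / (1 + n_sims)
  list(p_mc = p_mc, observed = observed, n_sims = n_sims, sim_counts = counts)
}
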