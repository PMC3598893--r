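# Independent combinatorial oracle for upper-tail hypergeometric
# probabilities: enumerate every size-n subset of a population of size N
# containing K successes and count those with at least k successes.
# Deliberately brute force; usable only for N <= 12 or so.
oracle_hyper_tail <- function(k, K, N, n) {
  population <- c(rep(TRUE, K), rep(FALSE, N - K))
  subsets <- utils::combn(N, n)
  hits <- apply(subsets, 2L, function(s) sum(population[s]) >= k)
  mean(hits)
}

# Small handcrafted gene-info table for resolution tests.
tiny_gene_info <- function() {
  tibble::tibble(
    gene_id = c(10L, 11L, 12L, 13L, 14L),
    symbol = c("COLQ1", "ABCZ2", "XK9", "DUPG", "DUPG"),
    synonyms = c("CQ1|COLX", NA, "XKOLD", NA, NA),
    locus_tag = c("LOC10", "LOC11", "LOC12", "LOC13", "LOC14"),
    map_location = c("2q37.1", "7p14.3", "Xq28", "1p36.1", "1p36.1"),
    tax_id = c(9606L, 9606L, 9606L, 9606L, 9606L)
  )
}

# One interaction record in the read_mitab() schema.
make_record <- function(a, b, method = "MI:0018(two hybrid)",
                        pmid = "pubmed:1", db = "MI:0469(intact)",
                        role_a = "MI:0499(unspecified role)",
                        role_b = "MI:0499(unspecified role)",
                        edge_type = "binary", complex_id = NA_character_,
                        lpr = NA_integer_, line = NA_integer_) {
  tibble::tibble(
    uid_a = if (edge_type == "binary") paste0("icrogid:", a) else paste0("complex:", complex_id),
    uid_b = paste0("icrogid:", b),
    icrogid_a = if (edge_type == "binary") as.integer(a) else NA_integer_,
    icrogid_b = as.integer(b),
    role_a = role_a, role_b = role_b, method_mi = method, pmid = pmid,
    source_db = db, edge_type = edge_type, complex_id = complex_id,
    num_participants = 2L, lpr = as.integer(lpr), line = line)
}

# Spoke fan: one bait-prey row per prey, sharing (db, pmid, method).
make_spoke <- function(bait, preys, method = "MI:0004(affinity chromatography technology)",
                       pmid = "pubmed:9", db = "MI:0463(grid)", lpr = 5L) {
  dplyr::bind_rows(lapply(preys, function(p)
    make_record(bait, p, method = method, pmid = pmid, db = db,
                role_a = "MI:0496(bait)", role_b = "MI:0498(prey)",
                lpr = lpr)))
}

# Bipartite complex: one membership row per member.
make_bipartite <- function(id, members, db = "MI:0469(intact)",
                           pmid = "pubmed:5", lpr = 10L) {
  dplyr::bind_rows(lapply(members, function(m)
    make_record(NA, m, edge_type = "complex_membership", complex_id = id,
                db = db, pmid = pmid, role_a = "MI:0000(complex)",
                role_b = "MI:0499(member)", lpr = lpr)))
}

# Minimal disease-group tibble for the statistics functions.
make_digs <- function(protein_sets, unmapped = NULL) {
  n <- length(protein_sets)
  if (is.null(unmapped)) unmapped <- replicate(n, integer(), simplify = FALSE)
  tibble::tibble(dig_id = seq_len(n),
                 name = paste0("dig", seq_len(n)),
                 mapped_protein_ids = lapply(protein_sets, as.integer),
                 unmapped_gene_ids = lapply(unmapped, as.integer),
                 gene_ids = Map(function(m, u) sort(c(m, u)),
                                lapply(protein_sets, as.integer),
                                lapply(unmapped, as.integer)),
                 n_genes = lengths(protein_sets) + lengths(unmapped),
                 multigenic = lengths(protein_sets) + lengths(unmapped) >= 2L)
}

# Group table (complexes/pathways) for dig_group_overlap().
make_groups <- function(member_sets, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("G%03d", seq_along(member_sets))
  tibble::tibble(group_id = ids, members = lapply(member_sets, as.integer))
}

pair_key_test <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
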