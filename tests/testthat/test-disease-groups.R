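test_that("Morbid Map parsing is lossless and rejects malformed lines", {
  lines <- c(
    "Alport syndrome, X-linked, 301050 (3)|COL4A5, ASLN|303630|Xq22.3",
    "Deafness, autosomal recessive 2, 600060 (3)|MYO7A|276903|11q13.5",
    "Broken line without enough columns|ABC",
    "{Malaria, susceptibility to}, 611162 (2)|FCGR2B|604590|1q23.3")
  path <- write_lines_tmp(lines)
  entries <- parse_morbid_map(path)
  expect_equal(nrow(entries), 3L)
  expect_equal(entries$evidence_code, c(3L, 3L, 2L))
  expect_equal(entries$title[[1]], "Alport syndrome, X-linked")
  expect_equal(entries$disease_mim[[1]], "301050")
  expect_equal(entries$gene_symbols[[1]], c("COL4A5", "ASLN"))
  expect_equal(entries$map_location[[2]], "11q13.5")
  rejects <- attr(entries, "rejects")
  expect_equal(rejects$line, 3L)
  expect_match(rejects$reason, "4 pipe-delimited")
  expect_error(parse_morbid_map(tempfile()), "cannot read")
})

test_that("parsing a synthetic file preserves row count and order", {
  m <- build_manifest(sim_config(), seed = 3)
  path <- write_lines_tmp(gen_morbidmap(m))
  entries <- parse_morbid_map(path)
  expect_equal(nrow(entries), nrow(m$morbid_rows))
  expect_equal(entries$title, m$morbid_rows$title)
  expect_equal(entries$evidence_code, m$morbid_rows$evidence_code)
})

test_that("evidence filtering retains only the requested code", {
  entries <- tibble::tibble(title = letters[1:4], disease_mim = NA_character_,
                            evidence_code = c(3L, 2L, 3L, 4L),
                            gene_symbols = as.list(letters[1:4]),
                            entry_mim = NA_character_,
                            map_location = NA_character_, line = 1:4)
  kept <- filter_evidence(entries)
  expect_equal(nrow(kept), 2L)
  expect_equal(attr(kept, "n_removed"), 2L)
  empty <- filter_evidence(entries[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("title normalization applies the stated rules", {
  expect_equal(normalize_title("Alport syndrome, X-linked")$key, "alport syndrome")
  expect_equal(normalize_title("Deafness, autosomal recessive 2")$key, "deafness")
  mal <- normalize_title("{Malaria, susceptibility to}")
  expect_equal(mal$key, "malaria")
  expect_true(mal$susceptibility)
  # keyword truncation and stand-alone token removal
  expect_equal(normalize_title("Anemia due to G6PD deficiency")$key, "anemia")
  expect_equal(normalize_title("Cataract with microcornea")$key, "cataract")
  expect_equal(normalize_title("Glycogen storage disease II")$key,
               "glycogen storage disease")
  # no-comma case: trailing tag and OMIM identifier are removed
  expect_equal(normalize_title("Hyperglycinuria 138500 (3)")$key,
               "hyperglycinuria")
  expect_error(normalize_title(""), "non-empty")
})

test_that("title normalization is idempotent on generated titles", {
  m <- build_manifest(sim_config(), seed = 5)
  keys <- normalize_title(m$morbid_rows$title)$key
  expect_equal(normalize_title(keys)$key, keys)
})

test_that("title grouping accepts suffix variants and respects boundaries", {
  keys <- normalize_title(c(
    "Adenomatous polyposis of the colon", "Adenomatosis, familial",
    "Digenic iminoglycinuria", "Hyperglycinuria",
    "Deafness", "Deafness"))$key
  ids <- group_titles(keys)
  expect_equal(ids[[1]], ids[[2]])      # adenomatous ~ adenomatosis stem
  expect_false(ids[[3]] == ids[[4]])    # completely different titles
  expect_equal(ids[[5]], ids[[6]])      # exact duplicates co-group
})

test_that("DiG identifiers are stable under input permutation", {
  keys <- c("alport syndrome", "deafness", "alport syndrome", "malaria",
            "deafness", "porphyria")
  ids <- group_titles(keys)
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  ids_perm <- group_titles(keys[perm])
  expect_identical(ids_perm, ids[perm])
})

test_that("gene resolution follows the two-pass rules", {
  gi <- tiny_gene_info()
  # official symbol with matching locus
  expect_equal(resolve_gene("COLQ1", "2q37.1", gi)$gene_id, 10L)
  # symbol with non-matching locus does not hit pass 1
  r <- resolve_gene("COLQ1", "9q99", gi)
  expect_true(is.na(r$gene_id) || r$status != "symbol")
  # synonym-only resolution via the broadened second pass
  syn <- resolve_gene("XKOLD", "Xq28", gi)
  expect_equal(syn$gene_id, 12L)
  expect_equal(syn$status, "synonym")
  # locus tag fallback
  expect_equal(resolve_gene("LOC11", "7p14.3", gi)$gene_id, 11L)
  # two genes share DUPG at the same locus: ambiguous, not a guess
  amb <- resolve_gene("DUPG", "1p36.1", gi)
  expect_true(is.na(amb$gene_id))
  expect_equal(amb$status, "ambiguous")
  # unknown symbol
  expect_equal(resolve_gene("NOPE", "1p36.1", gi)$status, "no_match")
})

test_that("disease groups partition mapped and unmapped genes", {
  gi <- tibble::tibble(gene_id = 1:3, symbol = c("AA1", "BB2", "CC3"),
                       synonyms = NA_character_,
                       locus_tag = paste0("LOC", 1:3),
                       map_location = c("1p1.1", "2q2.2", "3p3.3"),
                       tax_id = 9606L)
  g2p <- tibble::tibble(gene_id = c(1L, 2L), icrogid = c(901L, 902L))
  entries <- tibble::tibble(
    title = c("Testopathy, type A", "Testopathy, type B", "Testopathy 3"),
    disease_mim = c("100001", "100002", "100003"),
    evidence_code = 3L,
    gene_symbols = list("AA1", "BB2", "CC3"),
    entry_mim = c("200001", "200002", "200003"),
    map_location = c("1p1.1", "2q2.2", "3p3.3"),
    line = 1:3)
  digs <- build_disease_groups(entries, gi, g2p)
  expect_equal(nrow(digs), 1L)
  expect_equal(digs$n_genes, 3L)
  expect_equal(digs$mapped_protein_ids[[1]], c(901L, 902L))
  expect_equal(digs$unmapped_gene_ids[[1]], 3L)
  expect_length(intersect(unlist(digs$unmapped_gene_ids),
                          g2p$gene_id[match(digs$mapped_protein_ids[[1]],
                                            g2p$icrogid)]), 0L)
  expect_true(digs$multigenic)
  expect_equal(digs$omim_ids[[1]], c("100001", "100002", "100003"))
})

test_that("planted disease groups are recovered exactly from the files", {
  m <- build_manifest(sim_config(), seed = 11)
  path <- write_lines_tmp(gen_morbidmap(m))
  entries <- filter_evidence(parse_morbid_map(path))
  digs <- build_disease_groups(entries, m$gene_info, m$gene2protein)
  expect_equal(nrow(digs), nrow(m$digs))
  for (i in seq_len(nrow(m$digs))) {
    j <- which(digs$name == tolower(m$digs$name[[i]]))
    expect_length(j, 1L)
    expect_identical(digs$gene_ids[[j]], m$digs$gene_ids[[i]])
  }
  # single-gene groups excluded from the multigenic subset
  expect_equal(sum(digs$multigenic), sum(m$digs$multigenic))
})

test_that("DiG overlap network computes Jaccard and hypergeometric edges", {
  # population of 10 genes, |A| = 4, |B| = 3, 3 shared: p = 4/120
  digs <- make_digs(list(1:4, c(1L, 2L, 3L), c(7L, 8L, 9L, 10L)))
  net <- dig_overlap_network(digs, population_size = 10)
  expect_equal(nrow(net), 1L)
  expect_equal(net$n_shared, 3L)
  expect_equal(net$jaccard, 3 / 4)
  expect_equal(net$p_raw, 4 / 120)
  # identical gene sets give Jaccard 1; disjoint DiGs give no edge
  ident <- dig_overlap_network(make_digs(list(1:3, 1:3)), population_size = 10)
  expect_equal(ident$jaccard, 1)
  none <- dig_overlap_network(make_digs(list(1:3, 4:6)))
  expect_equal(nrow(none), 0L)
})

test_that("Jaccard is symmetric and bounded on random gene sets", {
  set.seed(8)
  for (rep in 1:20) {
    a <- sample(1:30, sample(2:8, 1))
    b <- sample(1:30, sample(2:8, 1))
    j_ab <- similarity_indices(a, b)$jaccard
    j_ba <- similarity_indices(b, a)$jaccard
    expect_equal(j_ab, j_ba)
    expect_gte(j_ab, 0)
    expect_lte(j_ab, 1)
  }
})
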