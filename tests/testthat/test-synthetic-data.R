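test_that("the gene universe is deterministic and sized as requested", {
  u1 <- gen_gene_universe(5, seed = 1)
  u2 <- gen_gene_universe(5, seed = 1)
  expect_identical(u1, u2)
  u3 <- gen_gene_universe(5, seed = 2)
  expect_false(identical(u1$gene_info$symbol, u3$gene_info$symbol))
  one <- gen_gene_universe(1, seed = 7)
  expect_equal(nrow(one$gene_info), 1L)
  expect_equal(one$gene_info$tax_id, 9606L)
  expect_error(gen_gene_universe(0, seed = 1), "integer")
})

test_that("the unmappable fraction controls the gene-to-protein mapping", {
  u <- gen_gene_universe(100, seed = 3, unmappable_fraction = 0.1)
  expect_equal(nrow(u$gene2protein), 90L)
  expect_length(setdiff(u$gene_info$gene_id, u$gene2protein$gene_id), 10L)
  expect_false(any(duplicated(u$gene_info$symbol)))
})

test_that("generated files are byte-stable under a fixed seed", {
  m1 <- build_manifest(sim_config(duplicate_rate = 0), seed = 17)
  m2 <- build_manifest(sim_config(duplicate_rate = 0), seed = 17)
  expect_identical(gen_morbidmap(m1), gen_morbidmap(m2))
  expect_identical(gen_mitab(m1), gen_mitab(m2))
  expect_identical(gen_genesets(m1), gen_genesets(m2))
})

test_that("planted DiGs emit multiple title variants of one base name", {
  m <- build_manifest(sim_config(), seed = 23)
  rows <- m$morbid_rows[m$morbid_rows$included, ]
  for (nm in m$digs$name[m$digs$multigenic]) {
    expect_gte(sum(rows$dig_name == nm), 2L)
    keys <- normalize_title(rows$title[rows$dig_name == nm])$key
    expect_length(unique(keys), 1L)     # variants share one search key
  }
  # weaker-evidence rows are present in the file but flagged excluded
  noise <- m$morbid_rows[!m$morbid_rows$included, ]
  expect_gt(nrow(noise), 0L)
  expect_true(all(noise$evidence_code %in% c(2L, 4L)))
})

test_that("titles with disjoint names stay distinct even with shared genes", {
  lines <- c("Digenic iminoglycinuria, 242600 (3)|AAA1|601001|1p1.1",
             "Hyperglycinuria, 138500 (3)|AAA1|601001|1p1.1")
  entries <- parse_morbid_map(write_lines_tmp(lines))
  ids <- group_titles(normalize_title(entries$title)$key)
  expect_length(unique(ids), 2L)
})

test_that("spoke rows share the key fields and name the bait", {
  m <- build_manifest(sim_config(), seed = 29)
  rec <- m$interactions
  spokes <- m$complexes[m$complexes$encoding == "spoke", ]
  for (i in seq_len(nrow(spokes))) {
    rows <- rec[rec$edge_type == "binary" & !is.na(rec$pmid) &
                  rec$pmid == spokes$pmid[[i]], ]
    expect_equal(nrow(rows), length(spokes$members[[i]]) - 1L)
    expect_true(all(rows$icrogid_a == spokes$bait[[i]]))
    expect_length(unique(rows$method_mi), 1L)
    expect_length(unique(rows$source_db), 1L)
  }
})

test_that("bipartite complexes emit one membership row per member and database", {
  m <- build_manifest(sim_config(), seed = 37)
  rec <- m$interactions
  bip <- m$complexes[m$complexes$encoding == "bipartite", ]
  for (i in seq_len(nrow(bip))) {
    rows <- rec[!is.na(rec$complex_id) & rec$complex_id == bip$complex_id[[i]], ]
    expect_equal(nrow(rows),
                 length(bip$members[[i]]) * length(bip$source_dbs[[i]]))
    expect_setequal(unique(rows$icrogid_b), bip$members[[i]])
    expect_length(unique(rows$complex_id), 1L)
  }
})

test_that("the realized binary graph equals the manifest after deduplication", {
  m <- build_manifest(sim_config(duplicate_rate = 0.2), seed = 43)
  pin <- build_pin(canonicalize(read_mitab(write_lines_tmp(gen_mitab(m)))))
  expect_equal(nrow(pin$edges), nrow(m$binary_graph_edges))
  expect_setequal(pair_key_test(pin$edges$a, pin$edges$b),
                  pair_key_test(m$binary_graph_edges$a, m$binary_graph_edges$b))
})

test_that("planted gene sets contain their DiG and decoys touch none", {
  m <- build_manifest(sim_config(), seed = 47)
  gs <- m$genesets
  dig_genes <- unlist(m$digs$gene_ids)
  for (i in seq_len(nrow(gs))) {
    if (is.na(gs$planted_dig[[i]])) {
      expect_length(intersect(gs$gene_ids[[i]], dig_genes), 0L)
    } else {
      planted <- m$digs$gene_ids[[match(gs$planted_dig[[i]], m$digs$name)]]
      expect_true(all(planted %in% gs$gene_ids[[i]]))
    }
  }
  # GMT render and reader round-trip
  sets <- read_gmt(write_lines_tmp(gen_genesets(m), ext = ".gmt"))
  expect_equal(sets$set_name, gs$set_name)
  expect_identical(sets$members, gs$gene_ids)
})

test_that("planted overlap sizes respect the set-size bound", {
  m <- build_manifest(sim_config(), seed = 53)
  ov <- m$dig_complex_overlaps
  for (i in seq_len(nrow(ov))) {
    d <- match(ov$dig_name[[i]], m$digs$name)
    cx <- match(ov$complex_id[[i]], m$complexes$complex_id)
    expect_lte(ov$overlap_size[[i]],
               min(m$digs$n_genes[[d]], length(m$complexes$members[[cx]])))
  }
  # spoke complexes carry a bait drawn from their own member set
  sp <- m$complexes[m$complexes$encoding == "spoke", ]
  expect_true(all(mapply(function(b, mem) b %in% mem, sp$bait, sp$members)))
})

test_that("simulate_survey writes the full fixture set deterministically", {
  d1 <- tempfile(); d2 <- tempfile()
  simulate_survey(sim_config(), d1, seed = 61)
  simulate_survey(sim_config(), d2, seed = 61)
  for (f in c("morbidmap.txt", "gene_info.tsv", "gene2protein.tsv",
              "interactions.mitab.tsv", "pathways.gmt", "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
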