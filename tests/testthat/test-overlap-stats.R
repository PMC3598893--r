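test_that("similarity indices match their closed forms", {
  idx <- similarity_indices(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(idx$jaccard, 0.5)
  expect_equal(idx$meet_min, 2 / 3)
  expect_equal(idx$geometric, 4 / 9)

  same <- similarity_indices(1:4, 1:4, population_size = 20)
  expect_equal(same$jaccard, 1)
  expect_equal(same$meet_min, 1)
  expect_equal(same$geometric, 1)
  expect_equal(same$hypergeom_index, 1)

  disj <- similarity_indices(1:3, 4:6, population_size = 20)
  expect_equal(disj$jaccard, 0)
  expect_equal(disj$meet_min, 0)
  expect_equal(disj$geometric, 0)
  expect_equal(disj$hypergeom_index, 0)

  empty <- similarity_indices(integer(), integer())
  expect_true(all(is.na(unlist(empty))))
})

test_that("type-1 overlap test matches direct enumeration cases", {
  # population 10, group 4, DiG of 3 fully contained: 4 of the 120 subsets
  expect_equal(overlap_test_type1(1:3, 1:4, population_size = 10), 4 / 120)
  # zero overlap has tail probability 1
  expect_equal(overlap_test_type1(5:6, 1:4, population_size = 10), 1)
  # an unmapped gene enlarges the sample without adding successes,
  # so the same overlap becomes less surprising than full containment
  p_full <- overlap_test_type1(1:3, 1:4, population_size = 10)
  p_unm <- overlap_test_type1(1:2, 1:4, population_size = 10, n_unmapped = 1L)
  expect_gt(p_unm, p_full)
})

test_that("hypergeometric tails equal the exhaustive enumeration oracle", {
  grid <- expand.grid(N = c(8L, 10L, 12L), K = c(2L, 5L), n = c(3L, 6L))
  for (g in seq_len(nrow(grid))) {
    N <- grid$N[[g]]; K <- grid$K[[g]]; n <- grid$n[[g]]
    for (k in 0:min(K, n)) {
      expect_equal(hyper_upper_tail(k, K, N, n), oracle_hyper_tail(k, K, N, n),
                   tolerance = 1e-12,
                   label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
    }
  }
})

test_that("tail probability decreases as the overlap grows", {
  p <- hyper_upper_tail(0:5, 40, 400, 30)
  expect_true(all(diff(p) < 0))
})

test_that("p-value adjustment reproduces hand-applied corrections", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "fdr"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  for (m in c("bonferroni", "fdr", "by")) {
    expect_equal(adjust_pvalues(0.2, m), 0.2)
  }
  expect_error(adjust_pvalues(c(0.5, 1.2), "fdr"), "0, 1")
})

test_that("adjusted p-values keep their ordering guarantees", {
  p <- local({
    set.seed(42)
    runif(50)^2
  })
  bh <- adjust_pvalues(p, "fdr")
  bonf <- adjust_pvalues(p, "bonferroni")
  by <- adjust_pvalues(p, "by")
  expect_true(all(bh[order(p)] == cummax(bh[order(p)])))  # order preserved
  expect_true(all(bonf >= bh))
  expect_true(all(by >= bh))
  expect_true(all(p <= bh))
})

test_that("type-2 tail approaches the binomial limit for small samples", {
  N <- n_possible_pairs(5000)
  E <- round(N * 0.01)
  p_hyper <- hyper_upper_tail(2, E, N, 10)
  p_binom <- stats::pbinom(1, 10, E / N, lower.tail = FALSE)
  expect_lt(abs(p_hyper - p_binom) / p_binom, 0.01)
})

test_that("overlap table obeys the adjustment ordering invariant", {
  digs <- make_digs(list(1:3, c(2L, 5L, 9L)))
  groups <- make_groups(list(1:4, c(5L, 9L, 11L), 20:24))
  ov <- dig_group_overlap(digs, groups, keep_zero = TRUE)
  expect_true(all(ov$p_raw <= ov$p_fdr + 1e-12))
  expect_true(all(ov$p_fdr <= ov$p_by + 1e-12))
  expect_true(all(ov$p_raw <= ov$p_bonferroni + 1e-12))
  expect_true(all(ov$overlap_size <= pmin(ov$dig_size, ov$group_size)))
})

test_that("a contained DiG outranks decoy complexes and passes FDR", {
  set.seed(303)
  universe <- 1:200
  dig <- 1:4
  decoys <- lapply(1:50, function(i) sample(universe, 5L))
  groups <- make_groups(c(list(c(dig, 101:102)), decoys),
                        ids = c("planted", sprintf("decoy%02d", 1:50)))
  ov <- dig_group_overlap(make_digs(list(dig)), groups)
  best <- ov[order(ov$p_fdr, -ov$overlap_size), ][1L, ]
  expect_equal(best$group_id, "planted")
  expect_lte(best$p_fdr, 0.05)
})

test_that("complex span counts spanned and significant groups", {
  digs <- make_digs(list(1:4))
  groups <- make_groups(list(1:4, c(1L, 50L, 51L), 60:63, 70:73, 80:83,
                             90:93, c(2L, 95L, 96L)))
  ov <- dig_group_overlap(digs, groups, keep_zero = TRUE)
  span <- complex_span(ov)
  expect_equal(span$span, 3L)
  expect_true(span$n_sig_adj <= span$n_sig_raw)
  expect_true(span$n_sig_raw <= span$span)
  # no sharing at all
  empty <- complex_span(dig_group_overlap(make_digs(list(1:3)),
                                          make_groups(list(10:12))))
  expect_equal(nrow(empty), 0L)
})

test_that("binary enrichment counts edges among DiG proteins", {
  pin <- protein_network(tibble::tibble(a = c(1L, 1L, 2L, 4L, 6L),
                                        b = c(2L, 3L, 3L, 5L, 7L)),
                         nodes = 1:10)
  digs <- make_digs(list(1:3, c(4L, 6L), c(8L, 9L, 10L), 5L))
  enr <- binary_enrichment(digs, pin)
  expect_equal(enr$k_observed_edges[1:3], c(3L, 0L, 0L))
  expect_equal(enr$n_possible_pairs[1:3], c(3L, 1L, 3L))
  expect_equal(enr$p_raw[[3]], 1)          # zero observed edges
  expect_false(enr$testable[[4]])          # fewer than two proteins
  # triangle among 3 of 10 nodes, 5 of 45 edges: oracle check
  expect_equal(enr$p_raw[[1]], oracle_hyper_tail(3, 5, 45, 3), tolerance = 1e-12)
})

test_that("Monte-Carlo null is deterministic and degenerate at zero edges", {
  pin <- protein_network(tibble::tibble(a = c(1L, 2L, 3L), b = c(2L, 3L, 4L)),
                         nodes = 1:12)
  mc1 <- mc_degree_matched_null(c(5L, 8L, 11L), pin, n_sims = 200, seed = 4)
  mc2 <- mc_degree_matched_null(c(5L, 8L, 11L), pin, n_sims = 200, seed = 4)
  expect_identical(mc1$p_mc, mc2$p_mc)
  expect_identical(mc1$sim_counts, mc2$sim_counts)
  expect_equal(mc1$p_mc, 1)   # observed count 0: every simulation ties
  expect_error(mc_degree_matched_null(c(5L, 99L), pin, seed = 1), "node")
})
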