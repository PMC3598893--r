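#' Survey pipeline configuration
#'
#' Input paths and thresholds for a full overlap survey run. The default
#' thresholds mirror the survey's decision rules: FDR-adjusted p <= 0.05
#' for complex and pathway overlaps, raw p < 0.0004 for binary enrichment
#' (the hypergeometric cutoff whose decisions reproduce the degree-matched
#' Monte-Carlo null) and FDR-adjusted p < 0.01 for DiG-DiG overlaps.
#'
#' @param morbidmap,gene_info,gene2protein,mitab,gmt Input file paths
#'   (`gmt` may be `NULL` to skip pathway analysis).
#' @param alpha_complex,alpha_binary,alpha_dig Significance thresholds.
#' @param family Multiple-testing family for group overlaps
#'   (`"per_dig"` or `"global"`).
#' @param method_whitelist MI codes for complex regeneration.
#' @param min_preys Minimum preys per regenerated complex.
#' @param population_size Optional fixed population for type-1 tests
#'   (default: joint union of proteins in DiGs plus groups).
#' @param evidence_code Morbid evidence code to retain.
#' @param lpr_threshold Low-throughput cutoff on lpr.
#' @return Named list of class `survey_config`.
#' @export
survey_config <- function(morbidmap, gene_info, gene2protein, mitab,
                          gmt = NULL, alpha_complex = 0.05,
                          alpha_binary = 4e-4, alpha_dig = 0.01,
                          family = c("per_dig", "global"),
                          method_whitelist = default_method_whitelist(),
                          min_preys = 2L, population_size = NULL,
                          evidence_code = 3L, lpr_threshold = 22L) {
  for (a in c(alpha_complex, alpha_binary, alpha_dig)) {
    if (!is.numeric(a) || a <= 0 || a >= 1) {
      abort("all thresholds must lie in (0, 1).")
    }
  }
  structure(list(morbidmap = morbidmap, gene_info = gene_info,
                 gene2protein = gene2protein, mitab = mitab, gmt = gmt,
                 alpha_complex = alpha_complex, alpha_binary = alpha_binary,
                 alpha_dig = alpha_dig, family = match.arg(family),
                 method_whitelist = method_whitelist, min_preys = min_preys,
                 population_size = population_size,
                 evidence_code = evidence_code,
                 lpr_threshold = lpr_threshold),
            class = "survey_config")
}

#' Run the full overlap survey
#'
#' Orchestrates every stage on the configured inputs: Morbid-Map parsing
#' and evidence filtering, disease-group construction, the DiG-DiG gene
#' sharing network, MITAB parsing and canonicalization, the binary PIN,
#' bipartite complex extraction, spoke-complex regeneration, overlap
#' statistics for the n-ary, regenerated and pathway data types, binary
#' enrichment, and the survey reports (verdicts, Venn partition,
#' source-database attribution, low-throughput tally). Any stage failure
#' aborts with the stage name and cause.
#'
#' @param config A [survey_config()].
#' @return List with the stage outputs (`digs`, `dig_network`, `records`,
#'   `pin`, `complexes`, `regenerated`, `overlaps_nary`, `overlaps_regen`,
#'   `overlaps_pathway`, `enrichment`, `verdicts`, `venn`, `attribution`)
#'   and a flat `summary` of run metrics suitable for [compare_runs()].
#' @export
run_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  for (f in c("morbidmap", "gene_info", "gene2protein", "mitab")) {
    if (!file.exists(config[[f]])) {
      abort(sprintf("input `%s` not found: %s", f, config[[f]]))
    }
  }
  if (!is.null(config$gmt) && !file.exists(config$gmt)) {
    abort(sprintf("input `gmt` not found: %s", config$gmt))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("survey stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  gi <- stage("gene_info", read_gene_info(config$gene_info))
  g2p <- stage("gene2protein", read_gene2protein(config$gene2protein))
  entries <- stage("morbidmap", parse_morbid_map(config$morbidmap))
  filtered <- stage("evidence_filter",
                    filter_evidence(entries, config$evidence_code))
  digs <- stage("disease_groups", build_disease_groups(filtered, gi, g2p))
  dig_net <- stage("dig_network",
                   dig_overlap_network(digs, alpha = config$alpha_dig))
  records <- stage("mitab", canonicalize(read_mitab(config$mitab)))
  pin <- stage("pin", build_pin(records))
  complexes <- stage("complexes", extract_complexes(records))
  regen <- stage("regenerate",
                 regenerate(records, config$method_whitelist,
                            config$min_preys))
  mdigs <- digs[digs$multigenic, , drop = FALSE]
  as_groups <- function(tbl, id_col) {
    tibble(group_id = as.character(tbl[[id_col]]), members = tbl$members)
  }
  ov_nary <- stage("overlap_nary", dig_group_overlap(
    mdigs, as_groups(complexes, "complex_id"),
    population_size = config$population_size, family = config$family))
  ov_regen <- stage("overlap_regen", dig_group_overlap(
    mdigs, as_groups(regen, "key"),
    population_size = config$population_size, family = config$family))
  ov_path <- NULL
  if (!is.null(config$gmt)) {
    sets <- stage("gmt", read_gmt(config$gmt))
    prot_sets <- tibble(
      group_id = sets$set_name,
      members = lapply(sets$members, function(g) {
        icro <- g2p$icrogid[match(g, g2p$gene_id)]
        sort(unique(icro[!is.na(icro)]))
      }))
    prot_sets <- prot_sets[lengths(prot_sets$members) > 0L, , drop = FALSE]
    ov_path <- stage("overlap_pathway", dig_group_overlap(
      mdigs, prot_sets, population_size = config$population_size,
      family = config$family))
  }
  enr <- stage("binary_enrichment",
               binary_enrichment(mdigs, pin, alpha = config$alpha_binary))
  verdicts <- stage("verdicts", dig_verdicts(
    mdigs, nary = ov_nary, regen = ov_regen, binary = enr,
    pathway = ov_path, alpha_group = config$alpha_complex,
    alpha_binary = config$alpha_binary))
  venn <- stage("venn", venn_partition(verdicts))
  bm_nary <- best_matches(ov_nary, alpha = config$alpha_complex)
  attribution <- if (nrow(bm_nary) > 0L) {
    stage("attribution", database_attribution(bm_nary, complexes))
  } else {
    tibble(label = character(), n_complexes = integer())
  }
  lt <- stage("low_throughput", low_throughput_fraction(
    complexes$lpr_min[match(unique(bm_nary$group_id), complexes$complex_id)],
    config$lpr_threshold))
  sig_any <- verdicts$sig_nary | verdicts$sig_regen | verdicts$sig_binary
  summary <- list(
    n_morbid_entries = nrow(entries),
    n_code3_entries = nrow(filtered),
    n_digs = nrow(digs),
    n_multigenic_digs = nrow(mdigs),
    n_dig_edges = nrow(dig_net),
    n_sig_dig_edges = sum(dig_net$significant),
    n_interaction_records = nrow(records),
    n_pin_nodes = length(pin$nodes),
    n_pin_edges = nrow(pin$edges),
    n_nary_groups = nrow(complexes),
    n_regenerated_groups = nrow(regen),
    n_sig_nary = sum(verdicts$sig_nary),
    n_sig_regen = sum(verdicts$sig_regen),
    n_sig_binary = sum(verdicts$sig_binary),
    n_sig_pathway = if (is.null(ov_path)) NA_integer_ else sum(verdicts$sig_pathway),
    n_sig_any_interaction = sum(sig_any),
    n_low_throughput_best = lt$count_low
  )
  list(digs = digs, dig_network = dig_net, records = records, pin = pin,
       complexes = complexes, regenerated = regen, overlaps_nary = ov_nary,
       overlaps_regen = ov_regen, overlaps_pathway = ov_path,
       enrichment = enr, verdicts = verdicts, venn = venn,
       attribution = attribution, low_throughput = lt, summary = summary)
}
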