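# Synthetic fixtures with known ground truth for every pipeline stage:
# a gene universe (gene-info table + gene-to-protein mapping), a
# Morbid-Map-style disease-gene file with planted disease groups whose
# titles vary the way real OMIM titles do, a MITAB interaction file with
# planted binary edges, bipartite complexes and spoke-encoded complexes,
# and a GMT pathway file with planted and decoy sets. All random choices
# happen while building the manifest; the gen_* renderers are pure
# functions of it, so a seed determines every file byte for byte.

#' Simulation configuration
#'
#' Default study conditions for the synthetic survey: a small human-scale
#' gene universe, a dozen multigenic disease groups with two to six genes,
#' a mixed population of bipartite and spoke-encoded complexes with a few
#' planted DiG-complex containments, a heterogeneous-degree background
#' interaction network and a pathway collection with planted and decoy
#' sets. See the methods vignette for the rationale behind each default.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of simulation parameters.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 300L,
    unmappable_fraction = 0.05,
    synonym_rate = 0.6,
    n_digs = 12L,                 # multigenic planted disease groups
    n_singleton_digs = 3L,        # single-gene groups (excluded from multigenic set)
    dig_size_range = c(2L, 6L),
    n_shared_gene_pairs = 2L,     # DiG pairs forced to share one gene
    synonym_only_rate = 0.2,      # Morbid rows listing only a synonym
    susceptibility_rate = 0.15,   # rows wrapped in OMIM's "{...}" marker
    n_noise_entries = 8L,         # rows with evidence code 2 or 4
    n_bipartite_complexes = 12L,
    n_spoke_complexes = 8L,
    complex_size_range = c(3L, 6L),
    n_dig_complex_overlaps = 4L,  # DiG subset-of-bipartite-complex plants
    n_dig_regen_overlaps = 2L,    # DiG subset-of-spoke-complex plants
    n_enriched_digs = 2L,         # DiGs with a planted clique of binary edges
    n_background_edges = 150L,
    degree_gamma = 1.2,           # attachment-weight exponent (heterogeneous degrees)
    duplicate_rate = 0.05,
    n_pathways_planted = 4L,
    n_pathway_decoys = 5L,
    lpr_range = c(1L, 60L),
    source_dbs = c("MI:0469(intact)", "MI:0463(grid)", "MI:0471(mint)"),
    spoke_methods = c("MI:0004(affinity chromatography technology)",
                      "MI:0096(pull down)",
                      "MI:0006(anti bait coimmunoprecipitation)"),
    binary_method = "MI:0018(two hybrid)",  # not in the regeneration whitelist
    taxon = 9606L,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown sim_config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Generate a synthetic gene universe
#'
#' Emits a gene-info table (integer gene IDs, unique official symbols, zero
#' to two synonyms, locus tag, map location, taxon fixed to 9606) and the
#' gene-to-protein mapping in which a configurable fraction of genes has no
#' canonical protein, to exercise the handling of non-mappable disease
#' genes.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed RNG seed; the same seed reproduces the tables exactly.
#' @param unmappable_fraction Fraction of genes absent from the mapping.
#' @param synonym_rate Fraction of genes carrying synonyms.
#' @param taxon Taxon identifier (default 9606).
#' @return List with `gene_info` and `gene2protein` tibbles.
#' @export
gen_gene_universe <- function(n_genes, seed, unmappable_fraction = 0.1,
                              synonym_rate = 0.6, taxon = 9606L) {
  n_genes <- check_count(n_genes, "n_genes")
  unmappable_fraction <- check_fraction(unmappable_fraction, "unmappable_fraction")
  synonym_rate <- check_fraction(synonym_rate, "synonym_rate")
  with_seed(seed, {
    gene_id <- 1000L + seq_len(n_genes)
    symbol <- vapply(seq_len(n_genes), function(i)
      paste0(paste(sample(LETTERS, 3L, replace = TRUE), collapse = ""),
             sample(1:9, 1L)), "")
    while (any(dup <- duplicated(symbol))) {
      symbol[dup] <- paste0(symbol[dup], sample(LETTERS, sum(dup), replace = TRUE))
    }
    n_syn <- ifelse(stats::runif(n_genes) < synonym_rate,
                    sample(1:2, n_genes, replace = TRUE), 0L)
    synonyms <- vapply(seq_len(n_genes), function(i) {
      if (n_syn[[i]] == 0L) NA_character_
      else paste(paste0("SYN", gene_id[[i]], LETTERS[seq_len(n_syn[[i]])]),
                 collapse = "|")
    }, "")
    map_location <- paste0(sample(c(1:22, "X"), n_genes, replace = TRUE),
                           sample(c("p", "q"), n_genes, replace = TRUE),
                           sample(1:3, n_genes, replace = TRUE), ".",
                           sample(1:9, n_genes, replace = TRUE))
    gene_info <- tibble(gene_id = gene_id, symbol = symbol, synonyms = synonyms,
                        locus_tag = paste0("LOC", gene_id),
                        map_location = map_location, tax_id = taxon)
    n_unmappable <- round(unmappable_fraction * n_genes)
    unmappable <- if (n_unmappable > 0L) sort(sample(gene_id, n_unmappable)) else integer()
    mappable <- setdiff(gene_id, unmappable)
    gene2protein <- tibble(gene_id = mappable, icrogid = 90000L + mappable)
    list(gene_info = gene_info, gene2protein = gene2protein)
  })
}

# Disease base names built from fake morphological stems; candidates that
# would collide under the grouping matcher are resampled.
dig_base_names <- function(n) {
  stems <- c("card", "myo", "neuro", "osteo", "derm", "hepat", "nephr",
             "retin", "chondr", "fibr", "glyc", "lip", "hemo", "leuk",
             "kerat", "acro", "brachy", "tel", "pachy", "scler", "angi",
             "cranio", "entero", "gastro", "thromb")
  tails <- c("oma", "itis", "osis", "opathy", "algia", "emia", "asthenia")
  nouns <- c("syndrome", "deficiency", "dystrophy", "myopathy", "anemia",
             "carcinoma", "neuropathy", "encephalopathy", "dysplasia",
             "aciduria")
  cap <- function(s) paste0(toupper(substr(s, 1L, 1L)), substr(s, 2L, nchar(s)))
  draw <- function() paste(cap(paste0(sample(stems, 1L), sample(tails, 1L))),
                           sample(nouns, 1L))
  names_out <- character(0L)
  guard <- 0L
  while (length(names_out) < n) {
    cand <- draw()
    stems_all <- stem_key(tolower(c(names_out, cand)))
    k <- length(stems_all)
    clash <- k > 1L && any(vapply(seq_len(k - 1L), function(j)
      keys_match(stems_all[[j]], stems_all[[k]]), NA))
    if (!clash) names_out <- c(names_out, cand)
    guard <- guard + 1L
    if (guard > 50L * n) abort("could not draw non-colliding disease names.")
  }
  names_out
}

title_variant <- function(base, v, symbol, susceptible) {
  if (susceptible) return(paste0("{", base, ", susceptibility to}"))
  switch((v - 1L) %% 7L + 1L,
         paste0(base, ", autosomal recessive"),
         paste0(base, ", autosomal dominant"),
         paste0(base, ", X-linked"),
         paste0(base, " ", c("II", "III", "IV", "V")[(v - 1L) %% 4L + 1L]),
         paste0(base, " ", v),
         paste0(base, " due to ", symbol, " deficiency"),
         paste0(base, " with anemia"))
}

#' Build the ground-truth manifest for a synthetic survey
#'
#' Draws every random choice of the simulation (gene universe, planted
#' disease groups and their Morbid rows, complexes, binary edges, pathway
#' sets) under one seed and stores them, together with the fully
#' materialized interaction-record table, in a manifest. Every planted
#' object is recoverable from the manifest without re-parsing any generated
#' file, and the file renderers ([gen_morbidmap()], [gen_mitab()],
#' [gen_genesets()]) are deterministic functions of the manifest.
#'
#' @param config Simulation parameters from [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return Manifest list; see the package vignette for the field inventory.
#' @export
build_manifest <- function(config = sim_config(), seed = config$seed) {
  cfg <- config
  universe <- gen_gene_universe(cfg$n_genes, seed = seed,
                                unmappable_fraction = cfg$unmappable_fraction,
                                synonym_rate = cfg$synonym_rate,
                                taxon = cfg$taxon)
  gi <- universe$gene_info
  g2p <- universe$gene2protein
  mappable <- g2p$gene_id
  with_seed(seed + 1L, {
    n_all_digs <- cfg$n_digs + cfg$n_singleton_digs
    bases <- dig_base_names(n_all_digs)
    sizes <- c(sample(seq(cfg$dig_size_range[[1L]], cfg$dig_size_range[[2L]]),
                      cfg$n_digs, replace = TRUE),
               rep(1L, cfg$n_singleton_digs))
    # overlap-planted DiGs need >= 2 mapped genes; draw those from the
    # mappable pool, the rest from the whole universe
    overlap_digs <- seq_len(min(cfg$n_dig_complex_overlaps + cfg$n_dig_regen_overlaps +
                                  cfg$n_enriched_digs, cfg$n_digs))
    pool <- gi$gene_id
    dig_genes <- vector("list", n_all_digs)
    used <- integer(0L)
    for (i in seq_len(n_all_digs)) {
      from <- if (i %in% overlap_digs) setdiff(mappable, used) else setdiff(pool, used)
      dig_genes[[i]] <- sort(sample(from, sizes[[i]]))
      used <- c(used, dig_genes[[i]])
    }
    # force a few DiG pairs to share one gene (DiG-DiG network edges)
    share_pairs <- min(cfg$n_shared_gene_pairs, cfg$n_digs %/% 2L)
    for (k in seq_len(share_pairs)) {
      i <- cfg$n_digs - 2L * k + 1L
      j <- cfg$n_digs - 2L * k + 2L
      if (i < 1L || j > cfg$n_digs || i %in% overlap_digs) next
      dig_genes[[j]] <- sort(unique(c(dig_genes[[j]][-1L], dig_genes[[i]][[1L]])))
    }
    digs <- tibble(name = bases, n_genes = lengths(dig_genes),
                   gene_ids = dig_genes,
                   multigenic = lengths(dig_genes) >= 2L)
    # Morbid rows: one evidence-3 row per (DiG, gene) with a title variant
    mim_counter <- 0L
    next_mim <- function() {
      mim_counter <<- mim_counter + 1L
      sprintf("%06d", 100000L + mim_counter * 7L)
    }
    rows <- list()
    for (i in seq_len(n_all_digs)) {
      genes <- dig_genes[[i]]
      for (v in seq_along(genes)) {
        g <- genes[[v]]
        grow <- gi[gi$gene_id == g, ]
        susceptible <- stats::runif(1L) < cfg$susceptibility_rate
        ttl <- title_variant(bases[[i]], v, grow$symbol, susceptible)
        syns <- if (is.na(grow$synonyms)) character() else
          strsplit(grow$synonyms, "|", fixed = TRUE)[[1L]]
        use_syn_only <- length(syns) > 0L && stats::runif(1L) < cfg$synonym_only_rate
        sym_field <- if (use_syn_only) syns[[1L]] else
          paste(c(grow$symbol, syns), collapse = ", ")
        dm <- next_mim()
        rows[[length(rows) + 1L]] <- tibble(
          col1 = paste0(ttl, ", ", dm, " (3)"),
          title = ttl, disease_mim = dm, evidence_code = 3L,
          symbol_field = sym_field, entry_mim = next_mim(),
          map_location = grow$map_location, gene_id = g,
          dig_name = bases[[i]], included = TRUE)
      }
    }
    # noise rows: same titles, weaker evidence codes, excluded by filtering
    for (k in seq_len(cfg$n_noise_entries)) {
      i <- sample(cfg$n_digs, 1L)
      g <- sample(gi$gene_id, 1L)
      grow <- gi[gi$gene_id == g, ]
      code <- sample(c(2L, 4L), 1L)
      ttl <- title_variant(bases[[i]], k + 20L, grow$symbol, FALSE)
      dm <- next_mim()
      rows[[length(rows) + 1L]] <- tibble(
        col1 = paste0(ttl, ", ", dm, " (", code, ")"),
        title = ttl, disease_mim = dm, evidence_code = code,
        symbol_field = grow$symbol, entry_mim = next_mim(),
        map_location = grow$map_location, gene_id = g,
        dig_name = bases[[i]], included = FALSE)
    }
    morbid_rows <- dplyr::bind_rows(rows)

    dig_prot <- lapply(dig_genes, function(g)
      sort(g2p$icrogid[match(intersect(g, mappable), g2p$gene_id)]))
    all_prot <- sort(g2p$icrogid)
    dig_prot_all <- unique(unlist(dig_prot))
    free_prot <- setdiff(all_prot, dig_prot_all)

    # complexes ---------------------------------------------------------
    size_range <- seq(cfg$complex_size_range[[1L]], cfg$complex_size_range[[2L]])
    n_pool <- 100L + cfg$n_background_edges + cfg$n_bipartite_complexes +
      cfg$n_spoke_complexes + nrow(morbid_rows)
    pmid_pool <- sprintf("pubmed:%08d", 10000000L + sample.int(9999999L, n_pool))
    pm <- 0L
    next_pmid <- function() { pm <<- pm + 1L; pmid_pool[[pm]] }
    lpr_draw <- function() sample(seq(cfg$lpr_range[[1L]], cfg$lpr_range[[2L]]), 1L)
    complexes <- list()
    overlaps <- list()
    bip_ids <- sprintf("%d", 700000L + seq_len(cfg$n_bipartite_complexes))
    for (c_i in seq_len(cfg$n_bipartite_complexes)) {
      if (c_i <= cfg$n_dig_complex_overlaps) {
        d <- c_i  # full containment of the DiG's mapped proteins
        core <- dig_prot[[d]]
        pad <- sample(free_prot, max(1L, min(sample(size_range, 1L), length(core) + 2L) - length(core)))
        members <- sort(unique(c(core, pad)))
        overlaps[[length(overlaps) + 1L]] <- tibble(
          dig_name = bases[[d]], complex_id = bip_ids[[c_i]],
          overlap_size = length(core), encoding = "bipartite")
      } else {
        members <- sort(sample(all_prot, sample(size_range, 1L)))
      }
      n_db <- sample(c(1L, 1L, 1L, 2L), 1L)
      complexes[[length(complexes) + 1L]] <- tibble(
        complex_id = bip_ids[[c_i]], encoding = "bipartite",
        source_dbs = list(sort(sample(cfg$source_dbs, n_db))),
        pmid = next_pmid(),
        method_mi = sample(cfg$spoke_methods, 1L),
        bait = NA_integer_, members = list(members), lpr = lpr_draw())
    }
    for (s_i in seq_len(cfg$n_spoke_complexes)) {
      if (s_i <= cfg$n_dig_regen_overlaps) {
        d <- cfg$n_dig_complex_overlaps + s_i
        core <- dig_prot[[d]]
        need <- max(3L - length(core), 1L)
        members <- sort(unique(c(core, sample(free_prot, need))))
        overlaps[[length(overlaps) + 1L]] <- tibble(
          dig_name = bases[[d]], complex_id = NA_character_,
          overlap_size = length(core), encoding = "spoke")
      } else {
        members <- sort(sample(all_prot, sample(size_range, 1L)))
      }
      bait <- sample(members, 1L)
      db <- sample(cfg$source_dbs, 1L)
      method <- sample(cfg$spoke_methods, 1L)
      pmid <- next_pmid()
      key <- paste(db, pmid, method, bait, sep = ".")
      complexes[[length(complexes) + 1L]] <- tibble(
        complex_id = key, encoding = "spoke", source_dbs = list(db),
        pmid = pmid, method_mi = method, bait = bait,
        members = list(members), lpr = lpr_draw())
      if (s_i <= cfg$n_dig_regen_overlaps) {
        overlaps[[length(overlaps)]]$complex_id <- key
      }
    }
    complexes <- dplyr::bind_rows(complexes)
    stopifnot(all(vapply(seq_len(nrow(complexes)), function(i)
      is.na(complexes$bait[[i]]) ||
        complexes$bait[[i]] %in% complexes$members[[i]], NA)))
    overlaps <- if (length(overlaps)) dplyr::bind_rows(overlaps) else
      tibble(dig_name = character(), complex_id = character(),
             overlap_size = integer(), encoding = character())

    # binary edges ------------------------------------------------------
    enriched <- integer(0L)
    planted_edges <- tibble(a = integer(), b = integer())
    if (cfg$n_enriched_digs > 0L) {
      enriched <- cfg$n_dig_complex_overlaps + cfg$n_dig_regen_overlaps +
        seq_len(cfg$n_enriched_digs)
      enriched <- enriched[enriched <= cfg$n_digs &
                             lengths(dig_prot[enriched]) >= 2L]
      for (d in enriched) {
        pr <- utils::combn(dig_prot[[d]], 2L)
        planted_edges <- dplyr::bind_rows(planted_edges,
                                          tibble(a = pr[1L, ], b = pr[2L, ]))
      }
    }
    # heterogeneous-degree background via weighted attachment
    w <- seq_along(all_prot)^(-cfg$degree_gamma)
    bg <- tibble(a = integer(), b = integer())
    seen <- pair_key(planted_edges$a, planted_edges$b)
    guard <- 0L
    while (nrow(bg) < cfg$n_background_edges && guard < 200L) {
      need <- cfg$n_background_edges - nrow(bg)
      i <- sample(all_prot, 2L * need, replace = TRUE, prob = w)
      j <- sample(all_prot, 2L * need, replace = TRUE, prob = w)
      cand <- tibble(a = pmin(i, j), b = pmax(i, j))
      cand <- cand[cand$a != cand$b, , drop = FALSE]
      k <- pair_key(cand$a, cand$b)
      keep <- !duplicated(k) & !(k %in% seen)
      cand <- cand[keep, , drop = FALSE]
      cand <- utils::head(cand, need)
      bg <- dplyr::bind_rows(bg, cand)
      seen <- c(seen, pair_key(cand$a, cand$b))
      guard <- guard + 1L
    }
    binary_edges <- dplyr::bind_rows(planted_edges, bg)

    # interaction records ------------------------------------------------
    rec <- list()
    for (e in seq_len(nrow(binary_edges))) {
      rec[[length(rec) + 1L]] <- tibble(
        uid_a = paste0("icrogid:", binary_edges$a[[e]]),
        uid_b = paste0("icrogid:", binary_edges$b[[e]]),
        icrogid_a = binary_edges$a[[e]], icrogid_b = binary_edges$b[[e]],
        role_a = "MI:0499(unspecified role)", role_b = "MI:0499(unspecified role)",
        method_mi = cfg$binary_method, pmid = next_pmid(),
        source_db = sample(cfg$source_dbs, 1L),
        edge_type = "binary", complex_id = NA_character_,
        num_participants = 2L, lpr = lpr_draw())
    }
    for (i in seq_len(nrow(complexes))) {
      cx <- complexes[i, ]
      members <- cx$members[[1L]]
      if (cx$encoding == "bipartite") {
        for (db in cx$source_dbs[[1L]]) {
          rec[[length(rec) + 1L]] <- tibble(
            uid_a = paste0("complex:", cx$complex_id),
            uid_b = paste0("icrogid:", members),
            icrogid_a = NA_integer_, icrogid_b = members,
            role_a = "MI:0000(complex)", role_b = "MI:0499(member)",
            method_mi = cx$method_mi, pmid = cx$pmid, source_db = db,
            edge_type = "complex_membership", complex_id = cx$complex_id,
            num_participants = length(members), lpr = cx$lpr)
        }
      } else {
        preys <- setdiff(members, cx$bait)
        rec[[length(rec) + 1L]] <- tibble(
          uid_a = paste0("icrogid:", cx$bait),
          uid_b = paste0("icrogid:", preys),
          icrogid_a = cx$bait, icrogid_b = preys,
          role_a = "MI:0496(bait)", role_b = "MI:0498(prey)",
          method_mi = cx$method_mi, pmid = cx$pmid,
          source_db = cx$source_dbs[[1L]][[1L]],
          edge_type = "binary", complex_id = NA_character_,
          num_participants = 2L, lpr = cx$lpr)
      }
    }
    interactions <- dplyr::bind_rows(rec)
    is_bin <- which(interactions$edge_type == "binary")
    n_dup <- round(cfg$duplicate_rate * length(is_bin))
    if (n_dup > 0L) {
      interactions <- dplyr::bind_rows(interactions,
                                       interactions[sample(is_bin, n_dup), ])
    }
    interactions$line <- seq_len(nrow(interactions)) + 1L
    # realized binary graph: planted + background + spoke bait-prey fans
    spoke_rows <- interactions[interactions$edge_type == "binary" &
                                 role_is_bait(interactions$role_a), ]
    all_bin <- tibble(a = pmin(c(binary_edges$a, spoke_rows$icrogid_a),
                               c(binary_edges$b, spoke_rows$icrogid_b)),
                      b = pmax(c(binary_edges$a, spoke_rows$icrogid_a),
                               c(binary_edges$b, spoke_rows$icrogid_b)))
    binary_graph_edges <- all_bin[!duplicated(pair_key(all_bin$a, all_bin$b)), ]

    # pathway sets -------------------------------------------------------
    gs <- list()
    for (p_i in seq_len(cfg$n_pathways_planted)) {
      d <- p_i
      pad <- sample(setdiff(pool, unlist(dig_genes)), 4L)
      gs[[length(gs) + 1L]] <- tibble(
        set_name = sprintf("PW%03d", p_i),
        description = paste("planted pathway containing", bases[[d]]),
        gene_ids = list(sort(unique(c(dig_genes[[d]], pad)))),
        planted_dig = bases[[d]])
    }
    decoy_pool <- setdiff(pool, unlist(dig_genes))
    for (p_i in seq_len(cfg$n_pathway_decoys)) {
      gs[[length(gs) + 1L]] <- tibble(
        set_name = sprintf("PW%03d", cfg$n_pathways_planted + p_i),
        description = "decoy pathway",
        gene_ids = list(sort(sample(decoy_pool, 6L))),
        planted_dig = NA_character_)
    }
    genesets <- dplyr::bind_rows(gs)

    # invariants
    for (k in seq_len(nrow(overlaps))) {
      cx <- complexes[complexes$complex_id == overlaps$complex_id[[k]], ]
      d <- which(bases == overlaps$dig_name[[k]])
      stopifnot(overlaps$overlap_size[[k]] <=
                  min(length(dig_genes[[d]]), length(cx$members[[1L]])))
    }

    list(config = cfg, seed = seed, gene_info = gi, gene2protein = g2p,
         digs = digs, morbid_rows = morbid_rows, complexes = complexes,
         dig_complex_overlaps = overlaps,
         enriched_digs = bases[enriched],
         binary_edges = binary_edges,
         binary_graph_edges = binary_graph_edges,
         interactions = interactions, genesets = genesets)
  })
}

#' Render the Morbid-Map file from a manifest
#'
#' @param manifest Manifest from [build_manifest()].
#' @param path Optional output path; when given the lines are written there.
#' @return Character vector of pipe-delimited lines, invisibly when `path`
#'   is given.
#' @export
gen_morbidmap <- function(manifest, path = NULL) {
  rows <- manifest$morbid_rows
  if (is.null(rows) || nrow(rows) == 0L) abort("manifest contains no Morbid rows.")
  lines <- paste(rows$col1, rows$symbol_field, rows$entry_mim,
                 rows$map_location, sep = "|")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Render the MITAB interaction file from a manifest
#'
#' @inheritParams gen_morbidmap
#' @return The MITAB lines (header plus one line per record), written to
#'   `path` when given.
#' @export
gen_mitab <- function(manifest, path = NULL) {
  rec <- manifest$interactions
  if (is.null(rec) || nrow(rec) == 0L) abort("manifest contains no interaction records.")
  known <- c(manifest$gene2protein$icrogid)
  ids <- c(rec$icrogid_a[rec$edge_type == "binary"], rec$icrogid_b)
  if (!all(ids %in% known)) {
    abort("manifest interaction records reference protein IDs outside the gene universe mapping.")
  }
  tmp <- tempfile(fileext = ".mitab")
  on.exit(unlink(tmp), add = TRUE)
  write_mitab(rec, tmp)
  lines <- readLines(tmp)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Render the GMT pathway file from a manifest
#'
#' @inheritParams gen_morbidmap
#' @return GMT lines (set name, description, tab-separated gene IDs).
#' @export
gen_genesets <- function(manifest, path = NULL) {
  gs <- manifest$genesets
  if (is.null(gs)) abort("manifest contains no gene sets.")
  lines <- vapply(seq_len(nrow(gs)), function(i)
    paste(c(gs$set_name[[i]], gs$description[[i]],
            as.character(gs$gene_ids[[i]])), collapse = "\t"), "")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Write all synthetic survey inputs to a directory
#'
#' Builds the manifest and renders `morbidmap.txt`, `gene_info.tsv`,
#' `gene2protein.tsv`, `interactions.mitab.tsv`, `pathways.gmt` and
#' `manifest.json` into `dir`. The seed determines every file byte for
#' byte.
#'
#' @param config Simulation parameters from [sim_config()].
#' @param dir Output directory (created if missing).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return The manifest, invisibly, with a `paths` attribute.
#' @export
simulate_survey <- function(config = sim_config(), dir, seed = config$seed) {
  manifest <- build_manifest(config, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(morbidmap = file.path(dir, "morbidmap.txt"),
             gene_info = file.path(dir, "gene_info.tsv"),
             gene2protein = file.path(dir, "gene2protein.tsv"),
             mitab = file.path(dir, "interactions.mitab.tsv"),
             gmt = file.path(dir, "pathways.gmt"),
             manifest = file.path(dir, "manifest.json"))
  gen_morbidmap(manifest, paths[["morbidmap"]])
  utils::write.table(manifest$gene_info, paths[["gene_info"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "-")
  utils::write.table(manifest$gene2protein, paths[["gene2protein"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gen_mitab(manifest, paths[["mitab"]])
  gen_genesets(manifest, paths[["gmt"]])
  jsonlite::write_json(manifest[setdiff(names(manifest), "config")],
                       paths[["manifest"]], auto_unbox = TRUE, digits = NA,
                       na = "null")
  attr(manifest, "paths") <- paths
  invisible(manifest)
}

#' Read a gene-info table written by [simulate_survey()]
#' @param path TSV path.
#' @return Tibble with the gene-info columns.
#' @export
read_gene_info <- function(path) {
  df <- utils::read.delim(path, na.strings = "-", colClasses = c(
    gene_id = "integer", symbol = "character", synonyms = "character",
    locus_tag = "character", map_location = "character", tax_id = "integer"))
  as_tibble(df)
}

#' Read a gene-to-protein mapping table
#' @param path TSV path with columns `gene_id`, `icrogid`.
#' @return Tibble.
#' @export
read_gene2protein <- function(path) {
  as_tibble(utils::read.delim(path, colClasses = c(gene_id = "integer",
                                                   icrogid = "integer")))
}
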