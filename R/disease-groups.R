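#' Parse a Morbid-Map-style file
#'
#' Reads a pipe-delimited disease-gene table with four columns per line:
#' (1) disease title with trailing OMIM identifier and parenthesized
#' evidence code, (2) comma-separated gene symbols (official symbol and
#' synonyms), (3) the OMIM identifier of the disease-gene relationship and
#' (4) the map location of the gene. Malformed lines (fewer than four
#' columns) are collected in the `rejects` attribute with their line
#' numbers, never silently dropped.
#'
#' @param path Path to the pipe-delimited file.
#' @return Tibble with one row per well-formed line: `title`,
#'   `disease_mim`, `evidence_code`, `gene_symbols` (list column),
#'   `entry_mim`, `map_location`, `line`; attribute `rejects`.
#' @export
parse_morbid_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read Morbid Map file '%s'.", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "|", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  rejects <- tibble(line = bad, text = lines[bad],
                    reason = sprintf("expected 4 pipe-delimited columns, found %d",
                                     lengths(fields)[bad]))
  ok <- setdiff(seq_along(fields), bad)
  if (length(ok) == 0L) {
    out <- tibble(title = character(), disease_mim = character(),
                  evidence_code = integer(), gene_symbols = list(),
                  entry_mim = character(), map_location = character(),
                  line = integer())
    attr(out, "rejects") <- rejects
    return(out)
  }
  col1 <- trimws(vapply(fields[ok], `[[`, "", 1L))
  # trailing "(code)" and optional preceding 6-digit OMIM id, e.g.
  # "Alport syndrome, 301050 (3)" or "Deafness (2)"
  code <- suppressWarnings(as.integer(sub("^.*\\((\\d)\\)\\s*$", "\\1", col1)))
  no_code <- !grepl("\\(\\d\\)\\s*$", col1)
  code[no_code] <- NA_integer_
  rest <- sub("\\s*\\(\\d\\)\\s*$", "", col1)
  mim <- ifelse(grepl("(\\d{6})\\s*$", rest),
                sub("^.*?(\\d{6})\\s*$", "\\1", rest), NA_character_)
  title <- trimws(sub(",?\\s*\\d{6}\\s*$", "", rest))
  out <- tibble(
    title = title,
    disease_mim = mim,
    evidence_code = code,
    gene_symbols = lapply(fields[ok], function(f)
      trimws(strsplit(f[[2L]], ",", fixed = TRUE)[[1L]])),
    entry_mim = trimws(vapply(fields[ok], `[[`, "", 3L)),
    map_location = trimws(vapply(fields[ok], `[[`, "", 4L)),
    line = ok
  )
  attr(out, "rejects") <- rejects
  out
}

#' Filter Morbid entries by evidence code
#'
#' Retains only the entries whose evidence code equals `code` (default 3:
#' both the disease-associated mutation and the phenotype itself were
#' mapped to the gene). The number of removed entries is reported as the
#' `n_removed` attribute.
#'
#' @param entries Tibble from [parse_morbid_map()].
#' @param code Evidence code to retain (default 3).
#' @return Filtered tibble with attribute `n_removed`.
#' @export
filter_evidence <- function(entries, code = 3L) {
  keep <- !is.na(entries$evidence_code) & entries$evidence_code == code
  out <- entries[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

roman_tokens <- function() {
  vapply(1:20, function(i) tolower(as.character(utils::as.roman(i))), "")
}

#' Normalize a disease title to a grouping search key
#'
#' Applies, in order: (1) truncation at the first comma (in the absence of
#' a comma, a trailing parenthesized evidence tag and OMIM identifier are
#' removed); (2) truncation before the keywords "due to" or "with", which
#' tend to introduce subtypes; (3) removal of extraneous white space and of
#' stand-alone digits and stand-alone roman numerals (I-XX); (4) a leading
#' "{" or "[" - the markers used for susceptibility phenotypes - is
#' recorded as a flag and stripped from the key; (5) case-folding.
#' The transformation is idempotent.
#'
#' @param titles Character vector of non-empty disease titles.
#' @return Tibble with columns `title` (input), `key` (search key) and
#'   `susceptibility` (logical bracket flag).
#' @examples
#' normalize_title("Alport syndrome, X-linked")$key   # "alport syndrome"
#' @export
normalize_title <- function(titles) {
  if (length(titles) == 0L) {
    return(tibble(title = character(), key = character(),
                  susceptibility = logical()))
  }
  if (any(is.na(titles) | !nzchar(trimws(titles)))) {
    abort("titles must be non-empty strings.")
  }
  romans <- roman_tokens()
  keys <- character(length(titles))
  flag <- logical(length(titles))
  for (i in seq_along(titles)) {
    t <- trimws(titles[[i]])
    flag[[i]] <- grepl("^[[{]", t)
    t <- gsub("[][{}]", "", t)
    if (grepl(",", t, fixed = TRUE)) {
      t <- sub(",.*$", "", t)
    } else {
      t <- sub("\\s*\\(\\d\\)\\s*$", "", t)     # disease evidence tag
      t <- sub(",?\\s*\\d{6}\\s*$", "", t)      # OMIM identifier
    }
    t <- sub("\\s+due\\s+to\\b.*$", "", t, ignore.case = TRUE)
    t <- sub("\\s+with\\b.*$", "", t, ignore.case = TRUE)
    words <- strsplit(trimws(t), "\\s+")[[1L]]
    drop <- grepl("^[0-9]+$", words) | tolower(words) %in% romans
    words <- words[!drop]
    key <- tolower(paste(words, collapse = " "))
    if (!nzchar(key)) key <- tolower(trimws(gsub("\\s+", " ", titles[[i]])))
    keys[[i]] <- key
  }
  tibble(title = titles, key = keys, susceptibility = flag)
}

# Per-word suffix stemming so that spelling variants such as "adenomatous"
# and "adenomatosis" reduce to a common stem ("adenoma") before matching.
stem_key <- function(keys) {
  vapply(strsplit(keys, " ", fixed = TRUE), function(words) {
    stemmed <- vapply(words, function(w) {
      if (nchar(w) > 6L && endsWith(w, "tosis")) {
        substr(w, 1L, nchar(w) - 5L)
      } else if (nchar(w) > 5L && endsWith(w, "tous")) {
        substr(w, 1L, nchar(w) - 4L)
      } else if (nchar(w) > 3L && endsWith(w, "s")) {
        substr(w, 1L, nchar(w) - 1L)
      } else w
    }, "")
    paste(stemmed, collapse = " ")
  }, "")
}

# Anchored partial hit between two stemmed keys: one must be a prefix of
# the other, and the match must end at the end of the longer key, at a word
# boundary or at punctuation.
keys_match <- function(stem_a, stem_b) {
  if (stem_a == stem_b) return(TRUE)
  short <- if (nchar(stem_a) < nchar(stem_b)) stem_a else stem_b
  long <- if (nchar(stem_a) < nchar(stem_b)) stem_b else stem_a
  if (!startsWith(long, short)) return(FALSE)
  nxt <- substr(long, nchar(short) + 1L, nchar(short) + 1L)
  nxt %in% c(" ", ",", "-", "/", "(")
}

#' Cluster normalized title keys into disease groups
#'
#' Deterministic clustering of search keys by anchored prefix matching:
#' keys are processed in sorted order; a key joins the first existing
#' cluster whose representative key it matches (identical keys always
#' co-group; a partial hit is accepted only when the shorter key ends at a
#' word boundary or punctuation of the longer one, after per-word suffix
#' stemming that equates the allowed suffix variants "s", "tous" and
#' "tosis"). Each cluster receives one integer DiG ID, assigned in sorted
#' order of the cluster representatives, so the assignment is invariant to
#' permutations of the input.
#'
#' @param keys Character vector of normalized keys (see [normalize_title()]).
#' @return Integer vector of DiG IDs aligned with `keys`.
#' @export
group_titles <- function(keys) {
  if (length(keys) == 0L) return(integer())
  uk <- sort(unique(keys))
  stems <- stem_key(uk)
  rep_stem <- character()   # cluster representatives, in creation order
  cluster_of <- integer(length(uk))
  for (i in seq_along(uk)) {
    hit <- 0L
    for (j in seq_along(rep_stem)) {
      if (keys_match(rep_stem[[j]], stems[[i]])) { hit <- j; break }
    }
    if (hit == 0L) {
      rep_stem <- c(rep_stem, stems[[i]])
      hit <- length(rep_stem)
    }
    cluster_of[[i]] <- hit
  }
  # renumber clusters by sorted representative for stable IDs
  ord <- order(rep_stem)
  dig_of_cluster <- integer(length(rep_stem))
  dig_of_cluster[ord] <- seq_along(ord)
  dig_of_cluster[cluster_of[match(keys, uk)]]
}

#' Resolve gene symbols against a gene-info table
#'
#' Two-pass resolution of the gene symbols of one Morbid entry to an
#' integer gene ID. Pass 1 matches the official Symbol at taxon 9606,
#' requiring the map location to match when one is given. If no hit is
#' found the search is broadened to Synonyms and LocusTag entries (pass 2).
#' At most one gene ID is returned; multiple surviving candidates yield an
#' unresolved result with reason `"ambiguous"` rather than a guess.
#'
#' @param symbols Character vector: official symbol and synonyms of one gene.
#' @param map_location Map location string from the Morbid entry (`NA` or
#'   `""` disables the location check).
#' @param gene_info Tibble with columns `gene_id`, `symbol`, `synonyms`
#'   (`|`-separated), `locus_tag`, `map_location`, `tax_id`.
#' @param taxon Taxon restriction (default 9606, human).
#' @return List with `gene_id` (integer or `NA`) and `status` (one of
#'   `"symbol"`, `"synonym"`, `"ambiguous"`, `"no_match"`).
#' @export
resolve_gene <- function(symbols, map_location, gene_info, taxon = 9606L) {
  gi <- gene_info[gene_info$tax_id == taxon, , drop = FALSE]
  has_loc <- !is.na(map_location) && nzchar(map_location)
  # pass 1: official symbol + map location
  cand <- gi[gi$symbol %in% symbols, , drop = FALSE]
  if (has_loc) cand <- cand[cand$map_location == map_location, , drop = FALSE]
  if (nrow(cand) == 1L) {
    return(list(gene_id = cand$gene_id[[1L]], status = "symbol"))
  }
  if (nrow(cand) > 1L) return(list(gene_id = NA_integer_, status = "ambiguous"))
  # pass 2: synonyms and locus tags
  syn_hit <- vapply(gi$synonyms, function(s) {
    !is.na(s) && any(strsplit(s, "|", fixed = TRUE)[[1L]] %in% symbols)
  }, NA)
  cand <- gi[syn_hit | (!is.na(gi$locus_tag) & gi$locus_tag %in% symbols), ,
             drop = FALSE]
  if (nrow(cand) > 1L && has_loc) {
    loc <- cand[cand$map_location == map_location, , drop = FALSE]
    if (nrow(loc) >= 1L) cand <- loc
  }
  if (nrow(cand) == 1L) {
    return(list(gene_id = cand$gene_id[[1L]], status = "synonym"))
  }
  if (nrow(cand) > 1L) return(list(gene_id = NA_integer_, status = "ambiguous"))
  list(gene_id = NA_integer_, status = "no_match")
}

#' Assemble disease groups from Morbid entries
#'
#' Builds disease groups (DiGs) from evidence-filtered Morbid entries:
#' titles are normalized ([normalize_title()]) and clustered
#' ([group_titles()]), genes are resolved against the gene-info table
#' ([resolve_gene()]), and resolved genes are mapped to canonical protein
#' identifiers. Genes with no canonical protein are retained as
#' non-mappable members: they can never intersect a protein group but
#' still count toward the DiG's size in all statistics. The DiG name is the
#' most frequent normalized key among the group's entries (ties broken by
#' shorter, then alphabetical).
#'
#' @param entries Morbid entries, already filtered to the evidence code of
#'   interest (see [filter_evidence()]).
#' @param gene_info Gene-info tibble (see [resolve_gene()]).
#' @param gene2protein Tibble with columns `gene_id`, `icrogid` mapping
#'   each gene to at most one canonical protein.
#' @return Tibble with one row per DiG: `dig_id`, `name`,
#'   `susceptibility`, `n_genes`, `gene_ids`, `mapped_protein_ids`,
#'   `unmapped_gene_ids` (list columns), `omim_ids`, `multigenic`.
#'   Attribute `unresolved` lists entries whose gene could not be resolved.
#' @export
build_disease_groups <- function(entries, gene_info, gene2protein) {
  norm <- normalize_title(entries$title)
  dig_ids <- group_titles(norm$key)
  res <- lapply(seq_len(nrow(entries)), function(i) {
    resolve_gene(entries$gene_symbols[[i]], entries$map_location[[i]], gene_info)
  })
  gene_id <- vapply(res, function(r) r$gene_id, NA_integer_)
  status <- vapply(res, function(r) r$status, "")
  unresolved <- tibble(line = entries$line, title = entries$title,
                       status = status)[is.na(gene_id), , drop = FALSE]
  df <- tibble(dig_id = dig_ids, key = norm$key,
               susceptibility = norm$susceptibility,
               gene_id = gene_id, disease_mim = entries$disease_mim)
  df <- df[!is.na(df$gene_id), , drop = FALSE]
  if (nrow(df) == 0L) {
    out <- tibble(dig_id = integer(), name = character(),
                  susceptibility = logical(), n_genes = integer(),
                  gene_ids = list(), mapped_protein_ids = list(),
                  unmapped_gene_ids = list(), omim_ids = list(),
                  multigenic = logical())
    attr(out, "unresolved") <- unresolved
    return(out)
  }
  out <- df %>%
    dplyr::group_by(.data$dig_id) %>%
    dplyr::summarise(
      name = {
        tab <- sort(table(.data$key), decreasing = TRUE)
        top <- names(tab)[tab == max(tab)]
        top[order(nchar(top), top)][[1L]]
      },
      susceptibility = any(.data$susceptibility),
      gene_ids = list(sort(unique(.data$gene_id))),
      omim_ids = list(sort(unique(.data$disease_mim[!is.na(.data$disease_mim)]))),
      .groups = "drop")
  out$n_genes <- lengths(out$gene_ids)
  prot <- lapply(out$gene_ids, function(g) {
    icro <- gene2protein$icrogid[match(g, gene2protein$gene_id)]
    list(mapped = sort(unique(icro[!is.na(icro)])), unmapped = g[is.na(icro)])
  })
  out$mapped_protein_ids <- lapply(prot, `[[`, "mapped")
  out$unmapped_gene_ids <- lapply(prot, `[[`, "unmapped")
  out$multigenic <- out$n_genes >= 2L
  out <- out[order(out$dig_id),
             c("dig_id", "name", "susceptibility", "n_genes", "gene_ids",
               "mapped_protein_ids", "unmapped_gene_ids", "omim_ids",
               "multigenic")]
  attr(out, "unresolved") <- unresolved
  out
}

#' Gene-sharing network of disease groups
#'
#' Connects every pair of multigenic DiGs that share at least one gene.
#' Edges carry the shared genes, the Jaccard index of the two gene sets and
#' a type-1 hypergeometric p-value (population: the union of genes over all
#' multigenic DiGs by default; sample: one DiG's genes; successes: the
#' shared genes), FDR-adjusted across all tested pairs.
#'
#' @param digs Disease-group tibble from [build_disease_groups()].
#' @param alpha Significance cutoff on the FDR-adjusted p (default 0.01).
#' @param population_size Population for the test; default is the union of
#'   genes across all multigenic DiGs.
#' @return Tibble with `dig_a`, `dig_b`, `shared_genes` (list), `n_shared`,
#'   `jaccard`, `p_raw`, `p_fdr`, `significant`.
#' @export
dig_overlap_network <- function(digs, alpha = 0.01, population_size = NULL) {
  md <- digs[digs$multigenic, , drop = FALSE]
  empty <- tibble(dig_a = integer(), dig_b = integer(), shared_genes = list(),
                  n_shared = integer(), jaccard = double(), p_raw = double(),
                  p_fdr = double(), significant = logical())
  if (nrow(md) < 2L) return(empty)
  if (is.null(population_size)) {
    population_size <- length(unique(unlist(md$gene_ids)))
  }
  pairs <- utils::combn(seq_len(nrow(md)), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    a <- md$gene_ids[[i]]; b <- md$gene_ids[[j]]
    shared <- intersect(a, b)
    if (length(shared) == 0L) return(NULL)
    tibble(dig_a = md$dig_id[[i]], dig_b = md$dig_id[[j]],
           shared_genes = list(sort(shared)), n_shared = length(shared),
           jaccard = length(shared) / length(union(a, b)),
           p_raw = hyper_upper_tail(length(shared), length(b),
                                    population_size, length(a)))
  })
  rows <- rows[!vapply(rows, is.null, NA)]
  if (length(rows) == 0L) return(empty)
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- adjust_pvalues(out$p_raw, "fdr")
  out$significant <- out$p_fdr < alpha
  out
}
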