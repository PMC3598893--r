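# MITAB dialect consumed by the pipeline: a tab-delimited file with a
# header line (leading "#" tolerated) and at least the mandatory columns
# uidA, uidB, method, pmids, sourcedb. Optional iRefIndex-style columns:
# interaction_id (icrigid for bipartite complex records), icrogidA,
# icrogidB, edgetype ("X" binary, "C" complex membership), numParticipants,
# lpr, experimentalRoleA, experimentalRoleB. Unknown extra columns are
# preserved opaquely. Complex-membership rows are recognized by
# edgetype == "C" or by a "complex:" prefix on uidA.

mitab_mandatory <- c("uidA", "uidB", "method", "pmids", "sourcedb")
mitab_known <- c(mitab_mandatory, "interaction_id", "icrogidA", "icrogidB",
                 "edgetype", "numParticipants", "lpr",
                 "experimentalRoleA", "experimentalRoleB")

#' Read a MITAB interaction file
#'
#' Parses a tab-delimited MITAB 2.6 file (iRefIndex-style dialect, see
#' Details) into one interaction record per row. Rows with the wrong number
#' of fields are not silently dropped: they are collected in the `rejects`
#' attribute with their line numbers.
#'
#' @details Mandatory columns: `uidA`, `uidB`, `method`, `pmids`,
#'   `sourcedb`. Recognized optional columns: `interaction_id`, `icrogidA`,
#'   `icrogidB`, `edgetype`, `numParticipants`, `lpr`,
#'   `experimentalRoleA`, `experimentalRoleB`. A record is classified as
#'   `complex_membership` when `edgetype == "C"` or `uidA` carries a
#'   `complex:` prefix; otherwise it is `binary`.
#'
#' @param path Path to the MITAB file.
#' @return Tibble of interaction records with columns `uid_a`, `uid_b`,
#'   `icrogid_a`, `icrogid_b`, `role_a`, `role_b`, `method_mi`, `pmid`,
#'   `source_db`, `edge_type`, `complex_id`, `num_participants`, `lpr`;
#'   attribute `rejects` holds malformed lines.
#' @export
read_mitab <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read MITAB file '%s'.", path))
  lines <- readLines(path)
  if (length(lines) == 0L) abort("MITAB file is empty (no header).")
  header <- strsplit(sub("^#\\s*", "", lines[[1L]]), "\t", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(mitab_mandatory, header)
  if (length(missing_cols) > 0L) {
    abort(sprintf("MITAB file is missing mandatory column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  body <- lines[-1L]
  if (length(body) == 0L) return(empty_mitab_records())
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  rejects <- tibble(line = bad + 1L, text = body[bad],
                    reason = sprintf("expected %d fields, found %d",
                                     length(header), nf[bad]))
  ok <- setdiff(seq_along(fields), bad)
  if (length(ok) == 0L) {
    out <- empty_mitab_records()
    attr(out, "rejects") <- rejects
    return(out)
  }
  mat <- do.call(rbind, fields[ok])
  colnames(mat) <- header
  col <- function(name, default = NA_character_) {
    if (name %in% header) {
      v <- mat[, name]
      v[v == "" | v == "-"] <- NA_character_
      v
    } else rep(default, length(ok))
  }
  int_col <- function(name) suppressWarnings(as.integer(col(name)))
  uid_a <- col("uidA")
  edgetype <- col("edgetype")
  is_cplx <- (!is.na(edgetype) & edgetype == "C") | startsWith(uid_a, "complex:")
  out <- tibble(
    uid_a = uid_a,
    uid_b = col("uidB"),
    icrogid_a = int_col("icrogidA"),
    icrogid_b = int_col("icrogidB"),
    role_a = col("experimentalRoleA"),
    role_b = col("experimentalRoleB"),
    method_mi = col("method"),
    pmid = col("pmids"),
    source_db = col("sourcedb"),
    edge_type = ifelse(is_cplx, "complex_membership", "binary"),
    complex_id = ifelse(is_cplx,
                        ifelse(startsWith(uid_a, "complex:"),
                               sub("^complex:", "", uid_a), col("interaction_id")),
                        NA_character_),
    num_participants = int_col("numParticipants"),
    lpr = int_col("lpr"),
    line = ok + 1L
  )
  extra <- setdiff(header, mitab_known)
  for (nm in extra) out[[paste0("extra_", nm)]] <- mat[, nm]
  attr(out, "rejects") <- rejects
  out
}

empty_mitab_records <- function() {
  out <- tibble(uid_a = character(), uid_b = character(),
                icrogid_a = integer(), icrogid_b = integer(),
                role_a = character(), role_b = character(),
                method_mi = character(), pmid = character(),
                source_db = character(), edge_type = character(),
                complex_id = character(), num_participants = integer(),
                lpr = integer(), line = integer())
  attr(out, "rejects") <- tibble(line = integer(), text = character(),
                                 reason = character())
  out
}

#' Write interaction records to a MITAB file
#'
#' Inverse of [read_mitab()] for the dialect the package consumes; a
#' written-then-reread table compares equal field by field.
#'
#' @param records Interaction-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mitab <- function(records, path) {
  fmt <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "-"
    x
  }
  lines <- paste(
    fmt(ifelse(records$edge_type == "complex_membership" &
                 !startsWith(records$uid_a, "complex:"),
               paste0("complex:", records$complex_id), records$uid_a)),
    fmt(records$uid_b), fmt(records$method_mi), fmt(records$pmid),
    fmt(records$source_db),
    fmt(ifelse(records$edge_type == "complex_membership",
               records$complex_id, NA_character_)),
    fmt(records$icrogid_a), fmt(records$icrogid_b),
    fmt(ifelse(records$edge_type == "complex_membership", "C", "X")),
    fmt(records$num_participants), fmt(records$lpr),
    fmt(records$role_a), fmt(records$role_b),
    sep = "\t")
  header <- paste0("#", paste(mitab_known, collapse = "\t"))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Canonicalize interactor identifiers
#'
#' Replaces interactor identifiers with canonical protein group identifiers
#' (icrogid) so that splice isoforms and aliases of one protein collapse to
#' a single network node and each gene maps to at most one node. With
#' `mapping = NULL` the records' own `icrogid_a`/`icrogid_b` columns are
#' taken as already canonical (the iRefIndex distribution ships them).
#'
#' Binary records whose two interactors collapse to the same canonical ID
#' are flagged `self_record`; records with an unmapped interactor are
#' flagged `unmapped` and retained, but both classes are excluded from the
#' network by [build_pin()].
#'
#' @param records Interaction-record tibble from [read_mitab()].
#' @param mapping Optional tibble with columns `uid`, `icrogid`.
#' @return The records with canonical `icrogid_a`/`icrogid_b` plus logical
#'   columns `self_record` and `unmapped`.
#' @export
canonicalize <- function(records, mapping = NULL) {
  out <- records
  if (!is.null(mapping)) {
    stopifnot(all(c("uid", "icrogid") %in% names(mapping)))
    map_a <- mapping$icrogid[match(out$uid_a, mapping$uid)]
    map_b <- mapping$icrogid[match(out$uid_b, mapping$uid)]
    out$icrogid_a <- ifelse(is.na(map_a), out$icrogid_a, map_a)
    out$icrogid_b <- ifelse(is.na(map_b), out$icrogid_b, map_b)
  }
  is_cplx <- out$edge_type == "complex_membership"
  out$unmapped <- (is.na(out$icrogid_b)) | (!is_cplx & is.na(out$icrogid_a))
  out$self_record <- !is_cplx & !out$unmapped & out$icrogid_a == out$icrogid_b
  out
}

#' Construct a protein interaction network
#'
#' Container for a deduplicated binary protein interaction network (PIN):
#' distinct canonical nodes, distinct unordered edges without self-loops,
#' and per-node degree.
#'
#' @param edges Tibble/data frame with columns `a` and `b` (canonical
#'   protein IDs); duplicates and orientation are normalized away.
#' @param nodes Optional node set; defaults to the nodes incident to
#'   `edges`, and may be a superset (isolated nodes are allowed).
#' @param provenance Optional tibble aligned with the deduplicated edges.
#' @return An object of class `protein_network` with elements `nodes`
#'   (sorted), `edges` (tibble, `a < b`, distinct), `degree` (named
#'   integer) and `provenance`.
#' @export
protein_network <- function(edges, nodes = NULL, provenance = NULL) {
  edges <- as_tibble(edges)
  stopifnot(all(c("a", "b") %in% names(edges)))
  keep <- edges$a != edges$b
  edges <- edges[keep, , drop = FALSE]
  ab <- tibble(a = pmin(edges$a, edges$b), b = pmax(edges$a, edges$b))
  dup <- duplicated(pair_key(ab$a, ab$b))
  ab <- ab[!dup, , drop = FALSE]
  if (!is.null(provenance)) provenance <- provenance[keep, , drop = FALSE][!dup, , drop = FALSE]
  nodes <- sort(unique(c(nodes, ab$a, ab$b)))
  deg <- table(factor(c(ab$a, ab$b), levels = nodes))
  degree <- stats::setNames(as.integer(deg), as.character(nodes))
  structure(list(nodes = nodes, edges = ab, degree = degree,
                 provenance = provenance),
            class = "protein_network")
}

#' @export
print.protein_network <- function(x, ...) {
  cat(sprintf("protein_network: %d nodes, %d edges (%s possible pairs)\n",
              length(x$nodes), nrow(x$edges),
              format(n_possible_pairs(length(x$nodes)), big.mark = ",")))
  invisible(x)
}

#' Build the binary protein interaction network
#'
#' Collapses canonicalized binary records into a deduplicated PIN: one edge
#' per unordered canonical pair no matter how many databases or
#' publications report it, with per-edge provenance (source databases,
#' publications, minimum lpr) retained for attribution. Self-records and
#' records with unmapped interactors are excluded.
#'
#' @param records Canonicalized records (see [canonicalize()]).
#' @param keep_self Include self-loops (default `FALSE`; the possible-pair
#'   population `n(n-1)/2` of the enrichment test assumes none).
#' @return A [protein_network()].
#' @export
build_pin <- function(records, keep_self = FALSE) {
  if (!all(c("self_record", "unmapped") %in% names(records))) {
    records <- canonicalize(records)
  }
  bin <- records[records$edge_type == "binary" & !records$unmapped &
                   (keep_self | !records$self_record), , drop = FALSE]
  if (nrow(bin) == 0L) {
    return(protein_network(tibble(a = integer(), b = integer())))
  }
  key <- pair_key(bin$icrogid_a, bin$icrogid_b)
  prov <- tibble(key = key, source_db = bin$source_db, pmid = bin$pmid,
                 lpr = bin$lpr) %>%
    dplyr::group_by(.data$key) %>%
    dplyr::summarise(source_dbs = list(sort(unique(.data$source_db))),
                     pmids = list(sort(unique(.data$pmid))),
                     lpr_min = if (all(is.na(.data$lpr))) NA_integer_
                               else min(.data$lpr, na.rm = TRUE),
                     .groups = "drop")
  ab <- tibble(a = pmin(bin$icrogid_a, bin$icrogid_b),
               b = pmax(bin$icrogid_a, bin$icrogid_b))
  dedup <- !duplicated(pair_key(ab$a, ab$b))
  ab <- ab[dedup, , drop = FALSE]
  prov <- prov[match(pair_key(ab$a, ab$b), prov$key), , drop = FALSE]
  protein_network(ab, provenance = prov)
}

#' Extract bipartite complexes from complex-membership records
#'
#' Groups complex-membership rows (one row per member protein linked to an
#' artificial complex node) by complex identifier into complex records with
#' deduplicated canonical member sets. Complexes left with fewer than two
#' distinct members after canonicalization are dropped with a warning.
#'
#' @param records Canonicalized records.
#' @return Tibble with `complex_id`, `members` (list of canonical IDs),
#'   `n_members`, `source_dbs`, `pmids`, `lpr_min`.
#' @export
extract_complexes <- function(records) {
  if (!"unmapped" %in% names(records)) records <- canonicalize(records)
  cm <- records[records$edge_type == "complex_membership" & !records$unmapped, ,
                drop = FALSE]
  if (nrow(cm) == 0L) {
    return(tibble(complex_id = character(), members = list(),
                  n_members = integer(), source_dbs = list(), pmids = list(),
                  lpr_min = integer()))
  }
  out <- cm %>%
    dplyr::group_by(complex_id = .data$complex_id) %>%
    dplyr::summarise(members = list(sort(unique(.data$icrogid_b))),
                     source_dbs = list(sort(unique(.data$source_db))),
                     pmids = list(sort(unique(.data$pmid))),
                     lpr_min = if (all(is.na(.data$lpr))) NA_integer_
                               else min(.data$lpr, na.rm = TRUE),
                     .groups = "drop") %>%
    dplyr::mutate(n_members = lengths(.data$members), .after = "members")
  degenerate <- out$n_members < 2L
  if (any(degenerate)) {
    warn(sprintf("dropping %d complex(es) with < 2 distinct canonical members: %s",
                 sum(degenerate),
                 paste(out$complex_id[degenerate], collapse = ", ")))
    out <- out[!degenerate, , drop = FALSE]
  }
  out[order(out$complex_id), , drop = FALSE]
}
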