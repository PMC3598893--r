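#' Default experimental-method whitelist for complex regeneration
#'
#' MI ontology codes of interaction-detection methods that can produce
#' n-ary results and are therefore candidates for spoke-model encoding
#' (affinity chromatography, coimmunoprecipitation, pull down, cosedimentation
#' and related techniques).
#'
#' @return Character vector of MI codes.
#' @export
default_method_whitelist <- function() {
  c("MI:0004", "MI:0006", "MI:0007", "MI:0019", "MI:0027", "MI:0028",
    "MI:0029", "MI:0059", "MI:0061", "MI:0071", "MI:0096", "MI:0114",
    "MI:0226", "MI:0227", "MI:0401", "MI:0437", "MI:0676", "MI:0858",
    "MI:0963")
}

# MI codes may appear bare ("MI:0004") or annotated ("MI:0004(affinity
# chromatography technology)"); compare on the bare code.
mi_code <- function(x) sub("^(MI:\\d{4}).*$", "\\1", x)

role_is_bait <- function(role) {
  !is.na(role) & grepl("MI:0496|bait", role, ignore.case = TRUE)
}

#' Regenerate spoke-represented complexes from binary records
#'
#' Some source databases encode n-ary results (e.g. one immunoprecipitation
#' pulling down several preys) as a fan of bait-centred binary rows. Such
#' rows are indistinguishable from genuine binary data except that they
#' share the same source database, publication, experimental method and
#' bait. This function detects those groups and reconstructs the candidate
#' member list ("regenerated complex": bait plus preys).
#'
#' Only records whose method is in `method_whitelist` (methods capable of
#' producing n-ary data) are considered. Records lacking a bait role are
#' skipped for grouping and reported in the `skipped_no_bait` attribute. A
#' group must contain at least `min_preys` prey records (hence at least
#' `min_preys + 1` distinct proteins) to qualify: a single bait-prey row is
#' indistinguishable from a plain binary record.
#'
#' @param records Canonicalized binary interaction records.
#' @param method_whitelist MI codes to consider
#'   (default [default_method_whitelist()]).
#' @param min_preys Minimum distinct prey proteins per group (default 2).
#' @return Tibble with `key` (rendered `database.pmid.method.bait`),
#'   `source_db`, `pmid`, `method_mi`, `bait`, `members` (list column,
#'   bait included), `n_members`, `n_records`; attribute `skipped_no_bait`
#'   counts whitelisted records without a bait annotation.
#' @export
regenerate <- function(records, method_whitelist = default_method_whitelist(),
                       min_preys = 2L) {
  if (length(method_whitelist) == 0L) {
    abort("`method_whitelist` must contain at least one MI code.")
  }
  min_preys <- check_count(min_preys, "min_preys")
  if (!"unmapped" %in% names(records)) records <- canonicalize(records)
  bin <- records[records$edge_type == "binary" & !records$unmapped, , drop = FALSE]
  bin <- bin[mi_code(bin$method_mi) %in% mi_code(method_whitelist), , drop = FALSE]
  bait_a <- role_is_bait(bin$role_a)
  bait_b <- role_is_bait(bin$role_b)
  no_bait <- !bait_a & !bait_b
  skipped <- sum(no_bait)
  bin <- bin[!no_bait, , drop = FALSE]
  empty <- tibble(key = character(), source_db = character(),
                  pmid = character(), method_mi = character(),
                  bait = integer(), members = list(), n_members = integer(),
                  n_records = integer())
  if (nrow(bin) == 0L) {
    attr(empty, "skipped_no_bait") <- skipped
    return(empty)
  }
  bait <- ifelse(bait_a, bin$icrogid_a, bin$icrogid_b)
  prey <- ifelse(bait_a, bin$icrogid_b, bin$icrogid_a)
  grp <- tibble(source_db = bin$source_db, pmid = bin$pmid,
                method_mi = bin$method_mi, bait = bait, prey = prey) %>%
    dplyr::group_by(.data$source_db, .data$pmid, .data$method_mi, .data$bait) %>%
    dplyr::summarise(preys = list(sort(setdiff(unique(.data$prey), .data$bait[[1L]]))),
                     n_records = dplyr::n(), .groups = "drop")
  grp <- grp[lengths(grp$preys) >= min_preys, , drop = FALSE]
  if (nrow(grp) == 0L) {
    attr(empty, "skipped_no_bait") <- skipped
    return(empty)
  }
  out <- tibble(
    key = paste(grp$source_db, grp$pmid, grp$method_mi, grp$bait, sep = "."),
    source_db = grp$source_db, pmid = grp$pmid, method_mi = grp$method_mi,
    bait = grp$bait,
    members = Map(function(b, p) sort(c(b, p)), grp$bait, grp$preys),
    n_records = grp$n_records
  )
  out$n_members <- lengths(out$members)
  out <- out[, c("key", "source_db", "pmid", "method_mi", "bait", "members",
                 "n_members", "n_records")]
  out <- out[order(out$key), , drop = FALSE]
  attr(out, "skipped_no_bait") <- skipped
  out
}
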