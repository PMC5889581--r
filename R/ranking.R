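# Similarity of a configuration's contact zone to the primary
# configuration's, scored with three additive rules:
#   +1 for every reference-side contact residue shared with the primary,
#   +4 for every shared contact pair,
#   -1 for every primary pair missing from the compared zone.
# Extra pairs present only in the compared zone are unpenalized; the score
# measures agreement with the primary, not symmetric difference.

#' Score a contact zone against the primary configuration's zone
#'
#' @param compared,primary `contact_zone`s computed with the same
#'   [contact_params()] and the same reference-side convention.
#' @return a `similarity_score`: list with `config_id`,
#'   `residue_matches`, `pair_matches`, `missing_pairs` and integer
#'   `score = residue_matches + 4 * pair_matches - missing_pairs`.
#' @export
similarity_score <- function(compared, primary) {
  if (!identical(compared$ref_side, primary$ref_side)) {
    stop_dz("dz_validation_error",
      "zones use different reference-side conventions ('",
      compared$ref_side, "' vs '", primary$ref_side, "')")
  }
  ref_c <- unique(compared$pairs$ref_key)
  ref_p <- unique(primary$pairs$ref_key)
  residue_matches <- length(intersect(ref_c, ref_p))
  pk <- function(z) paste(z$pairs$ref_key, z$pairs$paired_key, sep = "\r")
  pairs_c <- pk(compared)
  pairs_p <- pk(primary)
  pair_matches <- length(intersect(pairs_c, pairs_p))
  missing_pairs <- length(pairs_p) - pair_matches
  structure(list(
    config_id = compared$config_id,
    residue_matches = residue_matches,
    pair_matches = pair_matches,
    missing_pairs = missing_pairs,
    score = residue_matches + 4L * pair_matches - missing_pairs
  ), class = "similarity_score")
}

#' Rank ensemble members by similarity to the primary configuration
#'
#' The primary is always listed first; members follow in descending score,
#' ties broken by ensemble input order (stable sort).
#'
#' @param ensemble an `ensemble` (fixes the input order).
#' @param primary_zone the primary configuration's `contact_zone`.
#' @param zones named list of member zones (one per configuration).
#' @return data.frame `config_id`, `residue_matches`, `pair_matches`,
#'   `missing_pairs`, `score`, `rank`, `is_primary`, in display order.
#' @export
rank_configurations <- function(ensemble, primary_zone, zones) {
  ids <- names(ensemble$configurations)
  missing <- setdiff(ids, names(zones))
  if (length(missing)) {
    stop_dz("dz_validation_error", "missing zone for configuration(s): ",
      paste(missing, collapse = ", "))
  }
  scores <- lapply(ids, function(id) {
    similarity_score(zones[[id]], primary_zone)
  })
  df <- data.frame(
    config_id = ids,
    residue_matches = vapply(scores, `[[`, 0L, "residue_matches"),
    pair_matches = vapply(scores, `[[`, 0L, "pair_matches"),
    missing_pairs = vapply(scores, `[[`, 0L, "missing_pairs"),
    score = vapply(scores, `[[`, 0L, "score"),
    stringsAsFactors = FALSE
  )
  # drop the primary from the member list when it is itself a member
  pid <- primary_zone$config_id
  member_rows <- df[df$config_id != pid, , drop = FALSE]
  member_rows <- member_rows[order(-member_rows$score), , drop = FALSE]
  pscore <- similarity_score(primary_zone, primary_zone)
  prow <- data.frame(
    config_id = pid,
    residue_matches = pscore$residue_matches,
    pair_matches = pscore$pair_matches,
    missing_pairs = pscore$missing_pairs,
    score = pscore$score,
    stringsAsFactors = FALSE
  )
  out <- rbind(prow, member_rows)
  out$rank <- seq_len(nrow(out))
  out$is_primary <- out$config_id == pid & seq_len(nrow(out)) == 1L
  rownames(out) <- NULL
  out
}

#' Export a ranking as TSV
#'
#' @param ranking data.frame from [rank_configurations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_ranking_tsv <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
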