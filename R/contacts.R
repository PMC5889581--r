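# Residue-residue contact detection.
#
# The distance between two amino acids is the minimum Euclidean distance
# over their heavy-atom pairs. A cross-unit pair is a contact when that
# distance lies in the closed interval [d_min, d_max] (default 3-5 A); a
# pair strictly below d_min is a collision, reported separately and never
# counted as a contact.

#' Contact detection parameters
#'
#' @param d_min lower interaction bound (Angstrom, default 3). Pairs
#'   strictly closer are collisions.
#' @param d_max upper interaction bound (Angstrom, default 5).
#' @return a `contact_params`.
#' @export
contact_params <- function(d_min = 3, d_max = 5) {
  if (!(d_min > 0 && d_min <= d_max)) {
    stop_dz("dz_validation_error",
      "need 0 < d_min <= d_max, got [", d_min, ", ", d_max, "]")
  }
  structure(list(d_min = d_min, d_max = d_max), class = "contact_params")
}

heavy_coords_df <- function(res) {
  at <- res[!res$is_hydrogen, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop_dz("dz_degenerate_error", "residue '", res$key[1],
      "' has no heavy atoms")
  }
  as.matrix(at[, c("x", "y", "z")])
}

#' Minimum heavy-atom distance between two residues
#'
#' @param res_a,res_b residue atom tables (rows of a unit's `atoms` for one
#'   residue key), each with at least one heavy atom.
#' @return minimum over all heavy-atom pairs of the Euclidean distance
#'   (Angstrom); symmetric in its arguments.
#' @export
min_residue_distance <- function(res_a, res_b) {
  A <- heavy_coords_df(res_a)
  B <- heavy_coords_df(res_b)
  d2 <- outer(A[, 1], B[, 1], "-")^2 +
        outer(A[, 2], B[, 2], "-")^2 +
        outer(A[, 3], B[, 3], "-")^2
  sqrt(min(d2))
}

# all cross-unit residue-pair minimum distances of a configuration;
# returns a data.frame with residue identity columns and `distance`
cross_unit_min_distances <- function(conf) {
  pack <- function(unit) {
    at <- unit$atoms[!unit$atoms$is_hydrogen, , drop = FALSE]
    if (nrow(at) == 0L) {
      stop_dz("dz_degenerate_error", "unit '", unit$label,
        "' has no heavy atoms")
    }
    keys <- unique(at$key)
    list(at = at, keys = keys,
         idx = factor(at$key, levels = keys))
  }
  rp <- pack(conf$reference)
  pp <- pack(conf$paired)
  A <- as.matrix(rp$at[, c("x", "y", "z")])
  B <- as.matrix(pp$at[, c("x", "y", "z")])
  d2 <- outer(A[, 1], B[, 1], "-")^2 +
        outer(A[, 2], B[, 2], "-")^2 +
        outer(A[, 3], B[, 3], "-")^2
  # minimum over atoms within each (ref residue, paired residue) block
  nr <- length(rp$keys)
  colmin <- matrix(NA_real_, nr, ncol(d2))
  rsplit <- split(seq_len(nrow(d2)), rp$idx)
  for (i in seq_len(nr)) {
    rows <- rsplit[[i]]
    colmin[i, ] <- if (length(rows) == 1L) d2[rows, ] else
      do.call(pmin, lapply(rows, function(r) d2[r, ]))
  }
  np <- length(pp$keys)
  minmat <- matrix(NA_real_, nr, np)
  csplit <- split(seq_len(ncol(d2)), pp$idx)
  for (j in seq_len(np)) {
    cols <- csplit[[j]]
    minmat[, j] <- if (length(cols) == 1L) colmin[, cols] else
      do.call(pmin, lapply(cols, function(cc) colmin[, cc]))
  }
  meta <- function(at, keys) {
    first <- at[!duplicated(at$key), , drop = FALSE]
    first[match(keys, first$key), c("key", "chain", "resnum", "inscode",
                                    "resname")]
  }
  rm <- meta(rp$at, rp$keys)
  pm <- meta(pp$at, pp$keys)
  data.frame(
    ref_key = rep(rm$key, times = np),
    ref_chain = rep(rm$chain, times = np),
    ref_number = rep(rm$resnum, times = np),
    ref_ins = rep(rm$inscode, times = np),
    ref_name = rep(rm$resname, times = np),
    paired_key = rep(pm$key, each = nr),
    paired_chain = rep(pm$chain, each = nr),
    paired_number = rep(pm$resnum, each = nr),
    paired_ins = rep(pm$inscode, each = nr),
    paired_name = rep(pm$resname, each = nr),
    distance = sqrt(as.vector(minmat)),
    stringsAsFactors = FALSE
  )
}

pair_order <- function(df) {
  order(df$ref_chain, df$ref_number, df$ref_ins,
        df$paired_chain, df$paired_number, df$paired_ins)
}

#' Compute the contact zone of a configuration
#'
#' Enumerates all cross-unit residue pairs; pairs with minimum heavy-atom
#' distance in `[d_min, d_max]` (closed interval) form the contact zone,
#' pairs strictly below `d_min` are collisions.
#'
#' @param conf a `configuration`.
#' @param params a [contact_params()].
#' @return a `contact_zone`: list with `config_id`, `pairs` and
#'   `collisions` (data.frames with residue identity columns and
#'   `distance`), `params`, and `ref_side` (unit label used as reference).
#' @export
compute_contact_zone <- function(conf, params = contact_params()) {
  d <- cross_unit_min_distances(conf)
  pairs <- d[d$distance >= params$d_min & d$distance <= params$d_max, ,
             drop = FALSE]
  coll <- d[d$distance < params$d_min, , drop = FALSE]
  pairs <- pairs[pair_order(pairs), , drop = FALSE]
  coll <- coll[pair_order(coll), , drop = FALSE]
  rownames(pairs) <- rownames(coll) <- NULL
  structure(list(config_id = conf$id, pairs = pairs, collisions = coll,
                 params = params, ref_side = "reference"),
            class = "contact_zone")
}

#' Contact zones of every ensemble member
#'
#' @param ensemble an `ensemble`.
#' @param params a [contact_params()].
#' @return named list of `contact_zone`s (ids as names).
#' @export
compute_zones <- function(ensemble, params = contact_params()) {
  lapply(ensemble$configurations, compute_contact_zone, params = params)
}

#' Closest contact pair of a zone
#'
#' @param zone a `contact_zone`.
#' @return single-row data.frame (the pair with minimal distance, ties
#'   broken by reference chain, reference number, paired chain, paired
#'   number ascending), or `NULL` for an empty zone.
#' @export
closest_pair <- function(zone) {
  p <- zone$pairs
  if (nrow(p) == 0L) return(NULL)
  best <- p[p$distance == min(p$distance), , drop = FALSE]
  best <- best[order(best$ref_chain, best$ref_number, best$ref_ins,
                     best$paired_chain, best$paired_number,
                     best$paired_ins), , drop = FALSE]
  best[1L, , drop = FALSE]
}

#' Swap the reference/paired sides of a contact zone
#'
#' Used when the list-view is anchored on the paired protein.
#'
#' @param zone a `contact_zone`.
#' @return the side-swapped `contact_zone` (`ref_side` flipped).
#' @export
swap_zone_sides <- function(zone) {
  flip <- function(df) {
    out <- df
    names(out) <- sub("^ref_", "tmp_", names(out))
    names(out) <- sub("^paired_", "ref_", names(out))
    names(out) <- sub("^tmp_", "paired_", names(out))
    out[pair_order(out), , drop = FALSE]
  }
  zone$pairs <- flip(zone$pairs)
  zone$collisions <- flip(zone$collisions)
  zone$ref_side <- if (zone$ref_side == "reference") "paired" else "reference"
  zone
}

#' Export contact zones as a TSV table
#'
#' One row per contact or collision: config_id, reference residue, paired
#' residue, distance, is_collision.
#'
#' @param zones named list of `contact_zone`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_contacts_tsv <- function(zones, path) {
  rows <- lapply(zones, function(z) {
    both <- rbind(
      if (nrow(z$pairs)) cbind(z$pairs, is_collision = FALSE),
      if (nrow(z$collisions)) cbind(z$collisions, is_collision = TRUE)
    )
    if (is.null(both) || nrow(both) == 0L) return(NULL)
    cbind(config_id = z$config_id, both)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(config_id = character(), ref_key = character(),
                      ref_name = character(), paired_key = character(),
                      paired_name = character(), distance = double(),
                      is_collision = logical())
  } else {
    tab <- tab[, c("config_id", "ref_key", "ref_name", "paired_key",
                   "paired_name", "distance", "is_collision")]
    tab$distance <- sprintf("%.6f", tab$distance)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
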