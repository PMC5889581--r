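# Contact-zone list views: an ordered left column of reference-side
# residues with their paired-side partners repeated underneath (one right
# entry per contact pair, so connections drawn in listed order never
# cross), plus primary-vs-compared comparison models.

#' Kyte-Doolittle hydrophobicity scale
#'
#' Unitless hydropathy values for the 20 standard amino acids; unknown
#' residue names map to 0 with a warning.
#'
#' @param resnames character vector of 3-letter residue names.
#' @return numeric vector of hydropathy values.
#' @export
kyte_doolittle <- function(resnames) {
  kd <- c(ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5,
          MET = 1.9, ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
          TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2, GLU = -3.5,
          GLN = -3.5, ASP = -3.5, ASN = -3.5, LYS = -3.9, ARG = -4.5)
  v <- kd[toupper(resnames)]
  if (anyNA(v)) {
    warning("unknown residue name(s) mapped to hydrophobicity 0: ",
            paste(unique(resnames[is.na(v)]), collapse = ", "))
    v[is.na(v)] <- 0
  }
  unname(v)
}

left_sort_values <- function(left, pairs, sort_key, matrix) {
  switch(sort_key,
    hydrophobicity = kyte_doolittle(left$name),
    distance = vapply(left$key, function(k) {
      min(pairs$distance[pairs$ref_key == k])
    }, 0),
    frequency = vapply(seq_len(nrow(left)), function(i) {
      k <- left$key[i]
      partners <- pairs$paired_key[pairs$ref_key == k]
      max(vapply(partners, function(p) matrix_count(matrix, k, p), 0L))
    }, 0)
  )
}

#' Build a contact-zone list-view model
#'
#' The left column holds the zone's reference-side residues (or
#' paired-side ones when `side = "paired"`), ordered by the chosen key:
#' hydrophobicity descending (Kyte-Doolittle), mutual distance ascending
#' (each residue's closest connection), or frequency descending (the
#' maximum matrix count over the residue's pairs); ties fall back to
#' chain/residue number. The right column emits one entry per contact pair,
#' grouped under its left residue in left order, so connection lines never
#' cross.
#'
#' @param zone a `contact_zone`.
#' @param sort_key `"hydrophobicity"`, `"distance"` or `"frequency"`.
#' @param matrix a `contact_matrix`; required for the frequency sort.
#' @param side `"reference"` (default) or `"paired"` for the left column.
#' @return a `listview_model`: list with `config_id`, `left` (key, name,
#'   sort_value), `right` (key, name, distance, left_index) and
#'   `connections` (left_index, right_index, distance).
#' @export
build_listview <- function(zone,
                           sort_key = c("hydrophobicity", "distance",
                                        "frequency"),
                           matrix = NULL, side = c("reference", "paired")) {
  sort_key <- match.arg(sort_key)
  side <- match.arg(side)
  if (sort_key == "frequency" && is.null(matrix)) {
    stop_dz("dz_validation_error",
      "frequency sort requires a contact matrix")
  }
  if (side == "paired") zone <- swap_zone_sides(zone)
  pairs <- zone$pairs
  left <- data.frame(key = unique(pairs$ref_key), stringsAsFactors = FALSE)
  meta <- pairs[!duplicated(pairs$ref_key), ]
  left$name <- meta$ref_name[match(left$key, meta$ref_key)]
  left$chain <- meta$ref_chain[match(left$key, meta$ref_key)]
  left$number <- meta$ref_number[match(left$key, meta$ref_key)]
  if (nrow(left) > 0L) {
    left$sort_value <- left_sort_values(left, pairs, sort_key, matrix)
    dir <- if (sort_key == "distance") 1 else -1
    left <- left[order(dir * left$sort_value, left$chain, left$number), ,
                 drop = FALSE]
    rownames(left) <- NULL
  } else {
    left$sort_value <- numeric(0)
  }
  right <- list(); conn <- list()
  for (i in seq_len(nrow(left))) {
    sub <- pairs[pairs$ref_key == left$key[i], , drop = FALSE]
    sub <- sub[order(sub$paired_chain, sub$paired_number, sub$paired_ins), ,
               drop = FALSE]
    right[[i]] <- data.frame(
      key = sub$paired_key, name = sub$paired_name,
      distance = sub$distance, left_index = i, stringsAsFactors = FALSE)
  }
  right <- if (length(right)) do.call(rbind, right) else data.frame(
    key = character(), name = character(), distance = double(),
    left_index = integer(), stringsAsFactors = FALSE)
  rownames(right) <- NULL
  connections <- data.frame(
    left_index = right$left_index,
    right_index = seq_len(nrow(right)),
    distance = right$distance
  )
  structure(list(config_id = zone$config_id, sort_key = sort_key,
                 side = side, left = left, right = right,
                 connections = connections),
            class = "listview_model")
}

#' Compare list views of ranked configurations against the primary
#'
#' All panels reuse the primary's left ordering (so rows line up across
#' panels). For each compared zone, `matched_pairs` is its pair-key
#' intersection with the primary and `missing_left` the primary left
#' residues absent from the compared zone. In `compare` mode the missing
#' residues become explicit placeholders; `compact` mode drops them.
#'
#' @param primary_zone the primary `contact_zone`.
#' @param compared_zones list of `contact_zone`s in display (rank) order.
#' @param mode `"compare"` or `"compact"`.
#' @param sort_key,matrix,side passed to [build_listview()] for the
#'   primary's left ordering.
#' @return a `comparison_model`: list with `primary` (its
#'   `listview_model`), `panels` (per compared zone: `model` restricted to
#'   the primary's left order, `matched_pairs`, `missing_left`,
#'   `placeholders`), and `mode`.
#' @export
compare_listviews <- function(primary_zone, compared_zones,
                              mode = c("compare", "compact"),
                              sort_key = "hydrophobicity", matrix = NULL,
                              side = "reference") {
  mode <- match.arg(mode)
  pm <- build_listview(primary_zone, sort_key, matrix, side)
  pz <- if (side == "paired") swap_zone_sides(primary_zone) else primary_zone
  ppairs <- paste(pz$pairs$ref_key, pz$pairs$paired_key, sep = "\r")
  panels <- lapply(compared_zones, function(z) {
    if (!identical(z$ref_side, primary_zone$ref_side)) {
      stop_dz("dz_validation_error",
        "zones use different reference-side conventions")
    }
    zz <- if (side == "paired") swap_zone_sides(z) else z
    cpairs <- paste(zz$pairs$ref_key, zz$pairs$paired_key, sep = "\r")
    matched <- intersect(ppairs, cpairs)
    z_left <- unique(zz$pairs$ref_key)
    missing_left <- setdiff(pm$left$key, z_left)
    # panel left = primary left order restricted to residues present in
    # this zone, extras of the compared zone appended in its own order
    model <- build_listview(z, sort_key = sort_key, matrix = matrix,
                            side = side)
    present <- pm$left$key[pm$left$key %in% z_left]
    extras <- setdiff(model$left$key, pm$left$key)
    ord <- c(present, model$left$key[model$left$key %in% extras])
    model <- reorder_listview(model, ord)
    placeholders <- if (mode == "compare") missing_left else character(0)
    list(model = model,
         matched_pairs = matched,
         missing_left = missing_left,
         placeholders = placeholders)
  })
  structure(list(primary = pm, panels = panels, mode = mode,
                 sort_key = sort_key, side = side),
            class = "comparison_model")
}

# impose an explicit left-key order on a listview model, rebuilding the
# right column and connections (grouping invariants preserved)
reorder_listview <- function(model, left_keys) {
  left <- model$left[match(left_keys, model$left$key), , drop = FALSE]
  rownames(left) <- NULL
  old_left_key <- model$left$key[model$right$left_index]
  right <- list()
  for (i in seq_len(nrow(left))) {
    sub <- model$right[old_left_key == left$key[i], , drop = FALSE]
    if (nrow(sub)) sub$left_index <- i
    right[[i]] <- sub
  }
  right <- if (length(right)) do.call(rbind, right) else model$right[0, ]
  rownames(right) <- NULL
  model$left <- left
  model$right <- right
  model$connections <- data.frame(
    left_index = right$left_index,
    right_index = seq_len(nrow(right)),
    distance = right$distance
  )
  model
}

#' Export a comparison model as JSON
#'
#' @param cmp a `comparison_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_listview_json <- function(cmp, path) {
  strip <- function(m) {
    list(config_id = m$config_id, sort_key = m$sort_key, side = m$side,
         left = m$left, right = m$right, connections = m$connections)
  }
  obj <- list(
    mode = cmp$mode, sort_key = cmp$sort_key, side = cmp$side,
    primary = strip(cmp$primary),
    panels = lapply(cmp$panels, function(p) {
      list(model = strip(p$model), matched_pairs = p$matched_pairs,
           missing_left = p$missing_left, placeholders = p$placeholders)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
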