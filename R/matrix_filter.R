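# Contact frequency matrix over an ensemble, plus conjunctive pair
# filtering. Rows are reference-unit residues, columns paired-unit
# residues; a cell counts the configurations whose contact zone contains
# that pair (each configuration increments a cell at most once). Only
# residues in contact in at least one configuration appear; zero cells are
# never stored.

res_table_from_pairs <- function(pairs, prefix) {
  cols <- paste0(prefix, c("_key", "_chain", "_number", "_ins", "_name"))
  df <- pairs[, cols]
  names(df) <- c("key", "chain", "number", "inscode", "name")
  df <- df[!duplicated(df$key), , drop = FALSE]
  df <- df[order(df$chain, df$number, df$inscode), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build the contact frequency matrix of an ensemble
#'
#' @param ensemble an `ensemble`.
#' @param params a [contact_params()].
#' @param zones optional precomputed zones (named list); computed from
#'   `params` when omitted.
#' @return a `contact_matrix`: list with `rows` / `cols` (ordered residue
#'   tables, reference and paired side), `cells` (data.frame `row_key`,
#'   `col_key`, `count`; zero cells omitted), `n` (ensemble size) and
#'   `params`.
#' @export
build_frequency_matrix <- function(ensemble, params = contact_params(),
                                   zones = NULL) {
  if (length(ensemble$configurations) < 1L) {
    stop_dz("dz_empty_ensemble_error", "ensemble is empty")
  }
  zones <- zones %||% compute_zones(ensemble, params)
  allp <- do.call(rbind, lapply(zones, function(z) {
    if (nrow(z$pairs) == 0L) return(NULL)
    # a configuration increments each cell at most once by construction
    # (residue pairs are unique within one zone)
    z$pairs
  }))
  n <- length(ensemble$configurations)
  if (is.null(allp)) {
    return(structure(list(
      rows = res_table_from_pairs(empty_pairs_df(), "ref"),
      cols = res_table_from_pairs(empty_pairs_df(), "paired"),
      cells = data.frame(row_key = character(), col_key = character(),
                         count = integer(), stringsAsFactors = FALSE),
      n = n, params = params), class = "contact_matrix"))
  }
  rows <- res_table_from_pairs(allp, "ref")
  cols <- res_table_from_pairs(allp, "paired")
  cellkey <- paste(allp$ref_key, allp$paired_key, sep = "\r")
  tab <- table(cellkey)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  cells <- data.frame(row_key = parts[, 1], col_key = parts[, 2],
                      count = as.integer(tab), stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$row_key, rows$key),
                       match(cells$col_key, cols$key)), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(rows = rows, cols = cols, cells = cells, n = n,
                 params = params), class = "contact_matrix")
}

empty_pairs_df <- function() {
  data.frame(ref_key = character(), ref_chain = character(),
             ref_number = integer(), ref_ins = character(),
             ref_name = character(), paired_key = character(),
             paired_chain = character(), paired_number = integer(),
             paired_ins = character(), paired_name = character(),
             distance = double(), stringsAsFactors = FALSE)
}

#' Cell count lookup
#'
#' @param matrix a `contact_matrix`.
#' @param ref_key,paired_key residue keys (see [res_key()]).
#' @return integer occurrence count (0 when the cell is absent).
#' @export
matrix_count <- function(matrix, ref_key, paired_key) {
  hit <- matrix$cells$row_key == ref_key & matrix$cells$col_key == paired_key
  if (any(hit)) matrix$cells$count[hit][1] else 0L
}

#' Row and column marginal totals
#'
#' The per-residue totals behind the matrix axes (readable as histograms of
#' contact participation).
#'
#' @param matrix a `contact_matrix`.
#' @return list with `rows` and `cols` data.frames (`key`, `name`,
#'   `total`).
#' @export
marginal_counts <- function(matrix) {
  marg <- function(keys, names_, cell_keys) {
    tot <- vapply(keys, function(k) {
      sum(matrix$cells$count[cell_keys == k])
    }, 0L)
    data.frame(key = keys, name = names_, total = as.integer(tot),
               stringsAsFactors = FALSE)
  }
  list(rows = marg(matrix$rows$key, matrix$rows$name,
                   matrix$cells$row_key),
       cols = marg(matrix$cols$key, matrix$cols$name,
                   matrix$cells$col_key))
}

#' Pair selection for conjunctive filtering
#'
#' @param ref_keys,paired_keys equal-length residue key vectors; element i
#'   requires contact pair (ref_keys[i], paired_keys[i]).
#' @return a `pair_selection`.
#' @export
pair_selection <- function(ref_keys, paired_keys) {
  if (length(ref_keys) != length(paired_keys)) {
    stop_dz("dz_validation_error", "key vectors must have equal length")
  }
  structure(list(required = data.frame(ref_key = as.character(ref_keys),
                                       paired_key = as.character(paired_keys),
                                       stringsAsFactors = FALSE)),
            class = "pair_selection")
}

#' Filter configurations by required contact pairs
#'
#' Keeps exactly the configurations whose contact zone (at `params`, which
#' may tighten the range used for the matrix, e.g. d_max = 4) contains
#' every required pair simultaneously. Order is preserved; an empty
#' selection is the identity.
#'
#' @param ensemble an `ensemble`.
#' @param selection a [pair_selection()].
#' @param params a [contact_params()] used to recompute zones for the
#'   filter (default 3-5 Angstrom).
#' @param zones optional precomputed zones at `params`.
#' @return the filtered `ensemble` (subset, order preserved).
#' @export
filter_configurations <- function(ensemble, selection,
                                  params = contact_params(),
                                  zones = NULL) {
  req <- selection$required
  if (nrow(req) == 0L) return(ensemble)
  ref_keys <- unique(unlist(lapply(ensemble$configurations, function(cf) {
    unit_residue_keys(cf$reference)
  })))
  paired_keys <- unique(unlist(lapply(ensemble$configurations, function(cf) {
    unit_residue_keys(cf$paired)
  })))
  unknown_r <- setdiff(req$ref_key, ref_keys)
  unknown_p <- setdiff(req$paired_key, paired_keys)
  if (length(unknown_r) || length(unknown_p)) {
    stop_dz("dz_validation_error", "unknown residue key(s) in selection: ",
      paste(c(unknown_r, unknown_p), collapse = ", "))
  }
  zones <- zones %||% compute_zones(ensemble, params)
  keep <- vapply(ensemble$configurations, function(cf) {
    z <- zones[[cf$id]]
    zp <- paste(z$pairs$ref_key, z$pairs$paired_key, sep = "\r")
    all(paste(req$ref_key, req$paired_key, sep = "\r") %in% zp)
  }, TRUE)
  ensemble$configurations <- ensemble$configurations[keep]
  if (!is.na(ensemble$primary_id) &&
      !ensemble$primary_id %in% names(ensemble$configurations)) {
    ensemble$primary_id <- NA_character_
  }
  ensemble
}

#' Export the frequency matrix
#'
#' JSON form `{rows, cols, cells, n}` and/or a long-form TSV
#' (`ref_key`, `ref_name`, `paired_key`, `paired_name`, `count`).
#'
#' @param matrix a `contact_matrix`.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @return invisible list of written paths.
#' @export
export_matrix <- function(matrix, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(
      n = matrix$n,
      d_min = matrix$params$d_min, d_max = matrix$params$d_max,
      rows = matrix$rows, cols = matrix$cols, cells = matrix$cells
    )
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    cells <- matrix$cells
    long <- data.frame(
      ref_key = cells$row_key,
      ref_name = matrix$rows$name[match(cells$row_key, matrix$rows$key)],
      paired_key = cells$col_key,
      paired_name = matrix$cols$name[match(cells$col_key, matrix$cols$key)],
      count = cells$count, stringsAsFactors = FALSE
    )
    utils::write.table(long, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(json = json_path, tsv = tsv_path))
}
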