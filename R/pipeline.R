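# End-to-end pipeline mirroring the expert workflow: contacts -> frequency
# matrix -> (optional) conjunctive pair filter -> similarity ranking ->
# list views -> exploded layout -> open-book transforms, with every
# artifact written to the output directory alongside the serialized run
# configuration.

#' Build a validated run configuration
#'
#' @param inputs character vector of PDB paths (or one multi-MODEL file),
#'   or an in-memory `ensemble` (then chain selectors are ignored).
#' @param ref_chains,paired_chains chain selectors.
#' @param d_min,d_max contact range (Angstrom).
#' @param primary optional primary PDB path.
#' @param filter_pairs optional character vector `"A:23-B:97"` of required
#'   pairs (conjunction) applied at `filter_d_max`.
#' @param filter_d_max d_max used for filtering (default `d_max`).
#' @param sort_key list-view sort key.
#' @param mode list-view comparison mode.
#' @param out_dir output directory.
#' @param include_het keep HETATM records?
#' @param seed integer seed recorded for provenance.
#' @return a `run_config`.
#' @export
run_config <- function(inputs, ref_chains = "A", paired_chains = "B",
                       d_min = 3, d_max = 5, primary = NULL,
                       filter_pairs = NULL, filter_d_max = NULL,
                       sort_key = "hydrophobicity", mode = "compare",
                       out_dir = "dockzones_out", include_het = FALSE,
                       seed = 1L) {
  params <- contact_params(d_min, d_max)  # validates the range
  sort_key <- match.arg(sort_key, c("hydrophobicity", "distance",
                                    "frequency"))
  mode <- match.arg(mode, c("compare", "compact"))
  structure(list(
    inputs = inputs, ref_chains = ref_chains,
    paired_chains = paired_chains, params = params, primary = primary,
    filter_pairs = filter_pairs,
    filter_d_max = filter_d_max %||% d_max,
    sort_key = sort_key, mode = mode, out_dir = out_dir,
    include_het = include_het, seed = as.integer(seed)
  ), class = "run_config")
}

parse_pair_flag <- function(flags) {
  # "A:23-B:97" -> (ref_key, paired_key)
  parts <- strsplit(flags, "-", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop_dz("dz_validation_error", "malformed --pair flag(s): ",
      paste(flags[bad], collapse = ", "))
  }
  pair_selection(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}

serialize_run_config <- function(config, path) {
  obj <- config
  class(obj) <- NULL
  obj$params <- list(d_min = config$params$d_min,
                     d_max = config$params$d_max)
  if (inherits(obj$inputs, "ensemble")) {
    obj$inputs <- paste0("<in-memory ensemble, n=",
                         length(obj$inputs$configurations), ">")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full contact-zone analysis pipeline
#'
#' Executes the workflow stages in order and writes: `contacts.tsv`,
#' `matrix.json` + `matrix.svg`, `ranks.tsv` (when a primary is set),
#' `listview.json` + `listview.svg`, `layout.json`, `openbook.json`,
#' per-configuration aligned/exploded PDBs under `pdb/`, `run_config.json`
#' and `log.txt`. Stage errors abort with the stage name; a filter that
#' removes every configuration downgrades the downstream stages to valid
#' empty outputs with a warning.
#'
#' @param config a [run_config()].
#' @return invisible list of artifact paths.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(...) file.path(config$out_dir, ...)
  logf <- outp("log.txt")
  logcon <- file(logf, open = "wt")
  on.exit(close(logcon), add = TRUE)
  log_line <- function(...) writeLines(paste0(...), logcon)
  artifacts <- list(run_config = outp("run_config.json"), log = logf)
  serialize_run_config(config, artifacts$run_config)

  stage <- function(name, expr) {
    log_line("stage ", name)
    tryCatch(expr, error = function(e) {
      log_line("stage ", name, " FAILED: ", conditionMessage(e))
      stop_dz("dz_stage_error", "stage '", name, "': ",
        conditionMessage(e))
    })
  }

  ens <- stage("load", {
    if (inherits(config$inputs, "ensemble")) config$inputs
    else read_ensemble(config$inputs, config$ref_chains,
                       config$paired_chains, primary = config$primary,
                       include_het = config$include_het)
  })
  log_line("loaded n = ", length(ens$configurations))

  zones <- stage("contacts", compute_zones(ens, config$params))
  artifacts$contacts <- outp("contacts.tsv")
  export_contacts_tsv(zones, artifacts$contacts)

  mat <- stage("matrix", build_frequency_matrix(ens, config$params,
                                                zones = zones))
  artifacts$matrix_json <- outp("matrix.json")
  export_matrix(mat, json_path = artifacts$matrix_json)
  if (nrow(mat$cells) > 0L) {
    artifacts$matrix_svg <- outp("matrix.svg")
    export_heatmap(mat, artifacts$matrix_svg)
  } else {
    warning("empty frequency matrix; heat map skipped")
    log_line("matrix empty; heat map skipped")
  }

  if (!is.null(config$filter_pairs) && length(config$filter_pairs)) {
    sel <- parse_pair_flag(config$filter_pairs)
    fparams <- contact_params(config$params$d_min, config$filter_d_max)
    ens <- stage("filter",
                 filter_configurations(ens, sel, params = fparams))
    zones <- zones[names(ens$configurations)]
    log_line("filter retained n = ", length(ens$configurations))
    if (length(ens$configurations) == 0L) {
      warning("filter removed all configurations; ",
              "downstream outputs are empty")
    }
  }

  primary_conf <- get_primary(ens)
  if (!is.null(primary_conf) && length(ens$configurations) > 0L) {
    pzone <- stage("contacts",
                   compute_contact_zone(primary_conf, config$params))
    ranking <- stage("rank", rank_configurations(ens, pzone, zones))
    artifacts$ranks <- outp("ranks.tsv")
    export_ranking_tsv(ranking, artifacts$ranks)
    ranked_ids <- setdiff(ranking$config_id, pzone$config_id)
    cmp <- stage("listview", compare_listviews(
      pzone, zones[ranked_ids], mode = config$mode,
      sort_key = config$sort_key,
      matrix = if (config$sort_key == "frequency") mat))
    artifacts$listview_json <- outp("listview.json")
    export_listview_json(cmp, artifacts$listview_json)
    artifacts$listview_svg <- outp("listview.svg")
    export_listview_svg(cmp, artifacts$listview_svg)
    display_ids <- intersect(ranking$config_id, names(ens$configurations))
    ens <- reorder_ensemble(ens, display_ids)
    zones <- zones[display_ids]
  } else if (length(ens$configurations) > 0L) {
    log_line("no primary configuration; rank/listview skipped")
  }

  if (length(ens$configurations) > 0L &&
      any(vapply(zones, function(z) nrow(z$pairs) > 0L, TRUE))) {
    aligned <- stage("align", align_ensemble(ens))
    zones_al <- stage("contacts",
                      compute_zones(aligned$ensemble, config$params))
    plan <- stage("explode",
                  exploded_layout(aligned$ensemble, zones_al))
    artifacts$layout <- outp("layout.json")
    export_layout_json(plan, artifacts$layout)
    pdb_dir <- outp("pdb")
    dir.create(pdb_dir, showWarnings = FALSE)
    for (id in names(aligned$ensemble$configurations)) {
      cf <- aligned$ensemble$configurations[[id]]
      tf <- plan$transforms[[id]]
      tr <- if (!is.null(tf)) list(paired = tf) else NULL
      write_configuration(cf, file.path(pdb_dir,
                                        paste0(id, "_exploded.pdb")), tr)
    }
    artifacts$pdb_dir <- pdb_dir
    first_id <- names(zones_al)[
      vapply(zones_al, function(z) nrow(z$pairs) > 0L, TRUE)][1]
    ob <- stage("openbook", open_book_transforms(
      aligned$ensemble$configurations[[first_id]], zones_al[[first_id]]))
    artifacts$openbook <- outp("openbook.json")
    export_openbook_json(ob, artifacts$openbook)
  } else {
    log_line("no configurations (or no contacts); 3D stages skipped")
  }
  log_line("done")
  invisible(artifacts)
}

reorder_ensemble <- function(ens, ids) {
  ids <- ids[ids %in% names(ens$configurations)]
  ens$configurations <- ens$configurations[ids]
  ens
}
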