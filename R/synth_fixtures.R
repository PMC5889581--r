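# Synthetic two-protein docking ensembles with exactly planted contacts.
#
# Chain A (reference) lies on a straight backbone along x; chain B (paired)
# lies on a parallel line 60 A away in z. A planted pair (A:i, B:j, t)
# relocates residue B:j to a copy of A:i's template translated by exactly
# t along +z. The template is z-planar, so every atom pair of the planted
# couple is separated by exactly t in z and the minimum heavy-atom
# distance equals t (attained atom-for-atom where the xy offsets vanish).
# Residue spacing (12 A) guarantees every non-planted cross-unit residue
# pair stays > d_max + 2 A away, so the planted table IS the complete
# ground truth under the contact definition.

RES_TEMPLATE <- matrix(
  c(0.000, 0.000, 0.000,   # N
    1.458, 0.000, 0.000,   # CA
    2.009, 1.420, 0.000,   # C
    1.251, 2.390, 0.000,   # O
    2.000, -1.000, 0.000), # CB
  ncol = 3, byrow = TRUE,
  dimnames = list(c("N", "CA", "C", "O", "CB"), c("x", "y", "z"))
)
RES_ELEMENTS <- c("N", "C", "C", "O", "C")
RES_SPACING <- 12
FAR_Z <- 60

#' Specify a synthetic docking ensemble
#'
#' @param n_configs number of configurations (>= 1).
#' @param residues_per_unit residues in each chain (A = reference,
#'   B = paired).
#' @param plants data.frame with columns `config` (1-based configuration
#'   index), `ref_resnum`, `paired_resnum`, `distance` (target minimum
#'   heavy-atom distance, Angstrom, > 0). Distances below `collision_below`
#'   are recorded as collision plants. May be empty.
#' @param collision_below distances strictly below this are flagged
#'   `is_collision` in the ground truth (default 3, the d_min default).
#' @param seed integer recorded in the spec; generation is fully
#'   deterministic given the spec, so equal specs give byte-identical
#'   output.
#' @return an `ensemble_spec`.
#' @export
ensemble_spec <- function(n_configs, residues_per_unit,
                          plants = NULL, collision_below = 3,
                          seed = 1L) {
  if (n_configs < 1L) stop_dz("dz_validation_error", "n_configs must be >= 1")
  if (residues_per_unit < 1L) {
    stop_dz("dz_validation_error", "residues_per_unit must be >= 1")
  }
  if (is.null(plants)) {
    plants <- data.frame(config = integer(), ref_resnum = integer(),
                         paired_resnum = integer(), distance = double())
  }
  plants <- as.data.frame(plants)
  if (nrow(plants) > 0L) {
    if (any(plants$distance <= 0)) {
      stop_dz("dz_validation_error", "planted distances must be > 0")
    }
    if (any(plants$config < 1L | plants$config > n_configs)) {
      stop_dz("dz_validation_error", "plant config index out of range")
    }
    if (any(plants$ref_resnum < 1L | plants$ref_resnum > residues_per_unit) ||
        any(plants$paired_resnum < 1L |
            plants$paired_resnum > residues_per_unit)) {
      stop_dz("dz_validation_error", "plant residue number out of range")
    }
    dup <- duplicated(plants[, c("config", "paired_resnum")])
    if (any(dup)) {
      bad <- plants[dup, , drop = FALSE][1, ]
      stop_dz("dz_generation_error",
        "unsatisfiable geometry: paired residue B:", bad$paired_resnum,
        " planted twice in configuration ", bad$config)
    }
  }
  structure(list(n_configs = as.integer(n_configs),
                 residues_per_unit = as.integer(residues_per_unit),
                 plants = plants, collision_below = collision_below,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Random ensemble specification
#'
#' Draws, per configuration, 0 to `max_plants` planted pairs on distinct
#' paired residues, with target distances uniform in `dist_range` rounded
#' to the 0.001-Angstrom grid (so the plants survive PDB 3-decimal
#' round-trips exactly). A fraction of plants is drawn below 3 A as
#' collisions.
#'
#' @param n_configs,residues_per_unit ensemble dimensions.
#' @param max_plants maximum plants per configuration (default 6).
#' @param dist_range contact target range (default `c(3, 5)`).
#' @param p_collision probability that a plant is a collision, drawn in
#'   `[1, 3)` (default 0.15).
#' @param p_outside probability that a plant falls beyond d_max (in
#'   `(5, 7]`), exercising the "no contact" branch (default 0.1).
#' @param seed RNG seed.
#' @return an `ensemble_spec`.
#' @export
random_ensemble_spec <- function(n_configs, residues_per_unit,
                                 max_plants = 6, dist_range = c(3, 5),
                                 p_collision = 0.15, p_outside = 0.1,
                                 seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (cfg in seq_len(n_configs)) {
    k <- sample(0:min(max_plants, residues_per_unit), 1L)
    if (k == 0L) next
    pj <- sample(seq_len(residues_per_unit), k)
    ri <- sample(seq_len(residues_per_unit), k, replace = TRUE)
    u <- stats::runif(k)
    d <- ifelse(u < p_collision,
                stats::runif(k, 1, 2.999),
                ifelse(u < p_collision + p_outside,
                       stats::runif(k, 5.001, 7),
                       stats::runif(k, dist_range[1], dist_range[2])))
    rows[[length(rows) + 1L]] <- data.frame(
      config = cfg, ref_resnum = ri, paired_resnum = pj,
      distance = round(d, 3))
  }
  plants <- if (length(rows)) do.call(rbind, rows) else NULL
  ensemble_spec(n_configs, residues_per_unit, plants, seed = seed)
}

build_unit_atoms <- function(chain, n_res, origins, label) {
  n_at <- nrow(RES_TEMPLATE)
  atoms <- data.frame(
    serial = seq_len(n_res * n_at),
    name = rep(rownames(RES_TEMPLATE), n_res),
    altloc = "",
    resname = rep(STANDARD_AA[((seq_len(n_res) - 1L) %% 20L) + 1L],
                  each = n_at),
    chain = chain,
    resnum = rep(seq_len(n_res), each = n_at),
    inscode = "",
    x = rep(origins[, 1], each = n_at) + rep(RES_TEMPLATE[, 1], n_res),
    y = rep(origins[, 2], each = n_at) + rep(RES_TEMPLATE[, 2], n_res),
    z = rep(origins[, 3], each = n_at) + rep(RES_TEMPLATE[, 3], n_res),
    occupancy = 1,
    element = rep(RES_ELEMENTS, n_res),
    stringsAsFactors = FALSE
  )
  structure(list(label = label, atoms = finalize_atoms(atoms)),
            class = "protein_unit")
}

#' Generate a synthetic docking ensemble with planted contacts
#'
#' See [ensemble_spec()] for the geometric construction. When `out_dir` is
#' given, one PDB file per configuration (`conf_001.pdb`, ...) and a TSV
#' ground-truth manifest (`manifest.tsv`) are written; generation is fully
#' deterministic, so equal specs yield byte-identical files.
#'
#' In memory each planted pair's minimum heavy-atom distance equals its
#' target to better than 1e-9 Angstrom; through a PDB file (3-decimal
#' coordinates) targets on the 0.001-Angstrom grid survive exactly.
#'
#' @param spec an [ensemble_spec()].
#' @param out_dir optional output directory (created if needed).
#' @return list with `ensemble` (in-memory `ensemble`), `truth`
#'   (data.frame `config_id`, `ref_key`, `paired_key`, `distance`,
#'   `is_collision`), `files` (PDB paths or `NULL`), `manifest`
#'   (manifest path or `NULL`).
#' @export
generate_ensemble <- function(spec, out_dir = NULL) {
  n_res <- spec$residues_per_unit
  # gentle zig-zag in y keeps C-alphas non-collinear (required for
  # superposition) without touching the isolation margins
  zig <- 1.5 * ((seq_len(n_res) - 1L) %% 2L)
  origins_a <- cbind((seq_len(n_res) - 1) * RES_SPACING, zig, 0)
  confs <- list()
  truth <- list()
  for (cfg in seq_len(spec$n_configs)) {
    id <- sprintf("conf_%03d", cfg)
    origins_b <- cbind((seq_len(n_res) - 1) * RES_SPACING, zig, FAR_Z)
    pl <- spec$plants[spec$plants$config == cfg, , drop = FALSE]
    if (nrow(pl) > 0L) {
      for (r in seq_len(nrow(pl))) {
        i <- pl$ref_resnum[r]; j <- pl$paired_resnum[r]
        origins_b[j, ] <- origins_a[i, ] + c(0, 0, pl$distance[r])
      }
      truth[[length(truth) + 1L]] <- data.frame(
        config_id = id,
        ref_key = res_key("A", pl$ref_resnum),
        paired_key = res_key("B", pl$paired_resnum),
        distance = pl$distance,
        is_collision = pl$distance < spec$collision_below,
        stringsAsFactors = FALSE
      )
    }
    confs[[id]] <- new_configuration(
      id,
      build_unit_atoms("A", n_res, origins_a, "reference"),
      build_unit_atoms("B", n_res, origins_b, "paired")
    )
  }
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    config_id = character(), ref_key = character(),
    paired_key = character(), distance = double(), is_collision = logical(),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  ens <- structure(list(configurations = confs,
                        primary_id = NA_character_, primary = NULL),
                   class = "ensemble")
  files <- NULL; manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(names(confs), function(id) {
      p <- file.path(out_dir, paste0(id, ".pdb"))
      write_configuration(confs[[id]], p)
      p
    }, "")
    manifest <- file.path(out_dir, "manifest.tsv")
    mt <- truth
    mt$distance <- sprintf("%.6f", mt$distance)
    utils::write.table(mt, manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(ensemble = ens, truth = truth, files = files, manifest = manifest)
}

#' Check computed contact zones against a ground-truth manifest
#'
#' Recomputes every configuration's contact zone and compares it with the
#' manifest: contacts must equal the non-collision manifest rows with
#' distance inside `[d_min, d_max]`, collisions the rows flagged
#' `is_collision`. An empty report means exact agreement.
#'
#' @param ensemble the generated `ensemble` (or one re-read from disk).
#' @param truth ground-truth data.frame (or path to a manifest TSV).
#' @param params a [contact_params()].
#' @return data.frame of findings (`type`, `config_id`, `ref_key`,
#'   `paired_key`); zero rows on full agreement.
#' @export
verify_against_truth <- function(ensemble, truth,
                                 params = contact_params()) {
  if (is.character(truth)) {
    truth <- utils::read.delim(truth, stringsAsFactors = FALSE)
  }
  ids <- names(ensemble$configurations)
  alien <- setdiff(unique(truth$config_id), ids)
  if (length(alien)) {
    stop_dz("dz_validation_error",
      "manifest names configurations absent from the ensemble: ",
      paste(alien, collapse = ", "))
  }
  findings <- list()
  note <- function(type, config_id, rk, pk) {
    findings[[length(findings) + 1L]] <<- data.frame(
      type = type, config_id = config_id, ref_key = rk, paired_key = pk,
      stringsAsFactors = FALSE)
  }
  for (id in ids) {
    z <- compute_contact_zone(ensemble$configurations[[id]], params)
    tt <- truth[truth$config_id == id, , drop = FALSE]
    exp_contact <- tt[!tt$is_collision & tt$distance >= params$d_min &
                        tt$distance <= params$d_max, , drop = FALSE]
    exp_coll <- tt[tt$is_collision, , drop = FALSE]
    pk <- function(a, b) paste(a, b, sep = "\r")
    got_c <- pk(z$pairs$ref_key, z$pairs$paired_key)
    want_c <- pk(exp_contact$ref_key, exp_contact$paired_key)
    got_x <- pk(z$collisions$ref_key, z$collisions$paired_key)
    want_x <- pk(exp_coll$ref_key, exp_coll$paired_key)
    for (m in setdiff(want_c, got_c)) {
      s <- strsplit(m, "\r", fixed = TRUE)[[1]]
      note("missing_contact", id, s[1], s[2])
    }
    for (m in setdiff(got_c, want_c)) {
      s <- strsplit(m, "\r", fixed = TRUE)[[1]]
      note("unexpected_contact", id, s[1], s[2])
    }
    for (m in setdiff(want_x, got_x)) {
      s <- strsplit(m, "\r", fixed = TRUE)[[1]]
      note("missing_collision", id, s[1], s[2])
    }
    for (m in setdiff(got_x, want_x)) {
      s <- strsplit(m, "\r", fixed = TRUE)[[1]]
      note("unexpected_collision", id, s[1], s[2])
    }
  }
  if (length(findings)) do.call(rbind, findings) else data.frame(
    type = character(), config_id = character(), ref_key = character(),
    paired_key = character(), stringsAsFactors = FALSE)
}
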