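# PDB reading/writing and the Configuration/Ensemble containers.
#
# A protein unit is stored as a flat atom table (one row per atom); residue
# grouping is recovered from (chain, resnum, inscode). Hydrogens are kept in
# storage but flagged, and every distance computation in the package works
# on heavy atoms only.

ATOM_COLS <- c(
  "serial", "name", "altloc", "resname", "chain", "resnum", "inscode",
  "x", "y", "z", "occupancy", "element", "is_hydrogen", "key"
)

infer_element <- function(name) {
  # strip leading digits ("1HB " -> "HB"), take the leading letters
  core <- sub("^[0-9 ]*", "", name)
  core <- sub("[^A-Za-z].*$", "", core)
  two <- toupper(substr(core, 1, 2))
  one <- toupper(substr(core, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "SE"), two, one)
}

parse_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  al <- lines[is_atom]
  n <- length(al)
  if (n == 0L) {
    return(data.frame(
      record = character(), serial = integer(), name = character(),
      altloc = character(), resname = character(), chain = character(),
      resnum = integer(), inscode = character(), x = double(), y = double(),
      z = double(), occupancy = double(), element = character(),
      stringsAsFactors = FALSE
    ))
  }
  sstr <- function(a, b) trimws(substr(al, a, b))
  elem <- sstr(77, 78)
  name <- sstr(13, 16)
  no_elem <- elem == ""
  elem[no_elem] <- infer_element(name[no_elem])
  occ <- suppressWarnings(as.numeric(sstr(55, 60)))
  occ[is.na(occ)] <- 1
  data.frame(
    record = trimws(substr(al, 1, 6)),
    serial = as.integer(sstr(7, 11)),
    name = name,
    altloc = sstr(17, 17),
    resname = sstr(18, 20),
    chain = sstr(22, 22),
    resnum = as.integer(sstr(23, 26)),
    inscode = sstr(27, 27),
    x = as.numeric(sstr(31, 38)),
    y = as.numeric(sstr(39, 46)),
    z = as.numeric(sstr(47, 54)),
    occupancy = occ,
    element = toupper(elem),
    stringsAsFactors = FALSE
  )
}

# Split the lines of a PDB file into models (list of character vectors).
# Files without MODEL records yield a single unnamed model.
split_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  ids <- trimws(substr(lines[starts], 7, 20))
  ids[ids == ""] <- as.character(seq_along(starts))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    out[[i]] <- lines[(starts[i] + 1L):(ends[i] - 1L)]
  }
  names(out) <- ids
  out
}

# Altloc policy: keep the highest-occupancy conformer of each
# (chain, resnum, inscode, atom name) group; ties broken by altloc
# character order. Original record order is restored afterwards.
resolve_altlocs <- function(at) {
  if (nrow(at) == 0L || all(at$altloc == "")) return(at)
  grp <- paste(at$chain, at$resnum, at$inscode, at$name, sep = "\r")
  ord <- order(grp, -at$occupancy, at$altloc)
  at2 <- at[ord, , drop = FALSE]
  keep <- !duplicated(grp[ord])
  at2 <- at2[keep, , drop = FALSE]
  at2[order(at2$serial), , drop = FALSE]
}

finalize_atoms <- function(at) {
  at$is_hydrogen <- at$element %in% c("H", "D")
  at$key <- res_key(at$chain, at$resnum, at$inscode)
  at
}

read_pdb_source <- function(pdb_source) {
  if (length(pdb_source) == 1L && !grepl("\n", pdb_source) &&
      file.exists(pdb_source)) {
    lines <- tryCatch(readLines(pdb_source, warn = FALSE),
      error = function(e) stop_dz("dz_io_error", "cannot read PDB file '",
        pdb_source, "': ", conditionMessage(e)))
  } else if (length(pdb_source) == 1L && grepl("\n", pdb_source)) {
    lines <- strsplit(pdb_source, "\n", fixed = TRUE)[[1]]
  } else if (length(pdb_source) > 1L) {
    lines <- pdb_source
  } else {
    stop_dz("dz_io_error", "cannot read PDB source '", pdb_source,
      "': no such file")
  }
  lines
}

select_unit <- function(at, chains, label) {
  sel <- at[at$chain %in% chains, , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(label = label, atoms = sel), class = "protein_unit")
}

new_configuration <- function(id, reference, paired) {
  structure(list(id = id, reference = reference, paired = paired),
            class = "configuration")
}

#' Read one docking configuration from a PDB source
#'
#' Parses ATOM records (plus HETATM when `include_het = TRUE`), resolves
#' alternate locations to the highest-occupancy conformer, drops waters and
#' nucleic-acid residues, and partitions the selected chains into a
#' reference and a paired protein unit.
#'
#' Hydrogens are retained in storage but flagged; all distance computations
#' in the package ignore them.
#'
#' @param pdb_source path to a PDB file, or PDB text (single string with
#'   newlines, or a character vector of lines).
#' @param ref_chains,paired_chains disjoint chain-id sets designating the
#'   reference and the paired protein.
#' @param include_het keep non-water HETATM records? Default `FALSE`.
#' @param id configuration identifier; defaults to the file stem.
#' @return a `configuration`: list with `id` and two `protein_unit`s
#'   (`reference`, `paired`), each an atom table.
#' @examples
#' sp <- ensemble_spec(n_configs = 1, residues_per_unit = 4,
#'                     plants = data.frame(config = 1, ref_resnum = 2,
#'                                         paired_resnum = 3, distance = 4))
#' gen <- generate_ensemble(sp, out_dir = tempfile())
#' conf <- read_configuration(gen$files[1], ref_chains = "A",
#'                            paired_chains = "B")
#' length(unit_residue_keys(conf$reference))
#' @export
read_configuration <- function(pdb_source, ref_chains, paired_chains,
                               include_het = FALSE, id = NULL) {
  ref_chains <- as.character(ref_chains)
  paired_chains <- as.character(paired_chains)
  if (length(intersect(ref_chains, paired_chains)) > 0L) {
    stop_dz("dz_validation_error",
      "reference and paired chain sets overlap: ",
      paste(intersect(ref_chains, paired_chains), collapse = ", "))
  }
  lines <- read_pdb_source(pdb_source)
  models <- split_models(lines)
  at <- parse_pdb_atoms(models[[1]])
  at <- clean_atoms(at, include_het)
  for (chs in list(ref_chains, paired_chains)) {
    missing <- setdiff(chs, unique(at$chain))
    if (length(missing) > 0L) {
      stop_dz("dz_selector_error", "chain(s) not present in PDB source: ",
        paste(missing, collapse = ", "))
    }
  }
  if (is.null(id)) {
    id <- if (length(pdb_source) == 1L && !grepl("\n", pdb_source)) {
      tools::file_path_sans_ext(basename(pdb_source))
    } else "conf"
  }
  conf <- new_configuration(
    id,
    select_unit(at, ref_chains, "reference"),
    select_unit(at, paired_chains, "paired")
  )
  validate_configuration(conf)
  conf
}

clean_atoms <- function(at, include_het) {
  keep <- at$record == "ATOM" | (include_het & at$record == "HETATM")
  at <- at[keep & !(at$resname %in% WATER_RES) &
             !(at$resname %in% NUCLEIC_RES), , drop = FALSE]
  at <- resolve_altlocs(at)
  finalize_atoms(at[, setdiff(names(at), "record"), drop = FALSE])
}

validate_configuration <- function(conf) {
  for (side in c("reference", "paired")) {
    u <- conf[[side]]
    if (nrow(u$atoms) == 0L) {
      stop_dz("dz_validation_error", "configuration '", conf$id,
        "': ", side, " unit is empty")
    }
  }
  invisible(conf)
}

#' Residue keys of a protein unit
#'
#' @param unit a `protein_unit`.
#' @return character vector of unique residue keys in order of first
#'   appearance in the source.
#' @export
unit_residue_keys <- function(unit) unique(unit$atoms$key)

# per-residue atom index list, in order of first appearance
unit_residue_index <- function(unit, heavy_only = TRUE) {
  at <- unit$atoms
  if (heavy_only) at <- at[!at$is_hydrogen, , drop = FALSE]
  split(seq_len(nrow(at)), factor(at$key, levels = unique(at$key)))
}

#' Read a docking ensemble
#'
#' Loads one configuration per file, or one per MODEL record when a single
#' multi-MODEL file is given. Order is preserved; ids are file stems (or
#' MODEL numbers).
#'
#' When `primary` names one of `sources` the corresponding member is marked
#' via `primary_id`; an external primary (the typical crystal reference) is
#' read into the ensemble's `primary` field and kept out of
#' `configurations`, so ensemble statistics describe the docked set only.
#'
#' @param sources character vector of PDB paths (one pose each), or a
#'   single multi-MODEL PDB path.
#' @param ref_chains,paired_chains chain selectors, as in
#'   [read_configuration()].
#' @param primary optional path to the primary configuration; its chains
#'   must satisfy the same selectors.
#' @param include_het keep non-water HETATM records?
#' @return an `ensemble`: list with `configurations` (list of
#'   `configuration`), `primary_id` (or `NA`), `primary` (external primary
#'   `configuration` or `NULL`).
#' @export
read_ensemble <- function(sources, ref_chains, paired_chains,
                          primary = NULL, include_het = FALSE) {
  confs <- list()
  for (src in sources) {
    lines <- read_pdb_source(src)
    models <- split_models(lines)
    stem <- tools::file_path_sans_ext(basename(src))
    if (length(models) > 1L || !is.null(names(models))) {
      for (i in seq_along(models)) {
        id <- if (length(sources) == 1L) names(models)[i]
              else paste0(stem, ":", names(models)[i])
        confs[[length(confs) + 1L]] <- read_configuration(
          models[[i]], ref_chains, paired_chains, include_het, id = id)
      }
    } else {
      confs[[length(confs) + 1L]] <- read_configuration(
        models[[1]], ref_chains, paired_chains, include_het, id = stem)
    }
  }
  if (length(confs) == 0L) {
    stop_dz("dz_empty_ensemble_error", "no configurations could be read")
  }
  ids <- vapply(confs, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop_dz("dz_validation_error", "duplicate configuration ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(confs) <- ids
  ens <- structure(
    list(configurations = confs, primary_id = NA_character_, primary = NULL),
    class = "ensemble"
  )
  if (!is.null(primary)) {
    pstem <- tools::file_path_sans_ext(basename(primary))
    if (pstem %in% ids) {
      ens$primary_id <- pstem
    } else {
      ens$primary <- read_configuration(primary, ref_chains, paired_chains,
                                        include_het)
    }
  }
  ens
}

#' The primary configuration of an ensemble
#'
#' @param ensemble an `ensemble`.
#' @return the primary `configuration`, or `NULL` when none is designated.
#' @export
get_primary <- function(ensemble) {
  if (!is.null(ensemble$primary)) return(ensemble$primary)
  if (!is.na(ensemble$primary_id)) {
    return(ensemble$configurations[[ensemble$primary_id]])
  }
  NULL
}

#' @export
length.ensemble <- function(x) length(x$configurations)

#' @export
print.ensemble <- function(x, ...) {
  cat("docking ensemble: n =", length(x$configurations))
  p <- get_primary(x)
  if (!is.null(p)) cat(", primary =", p$id)
  cat("\n")
  invisible(x)
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf(
    "configuration '%s': reference %d residues / paired %d residues\n",
    x$id, length(unit_residue_keys(x$reference)),
    length(unit_residue_keys(x$paired))))
  invisible(x)
}

# PDB writing -------------------------------------------------------------

format_atom_name <- function(name, element) {
  # standard convention: element symbol occupies columns 13-14, so
  # single-letter-element names of length < 4 are indented by one space
  ifelse(nchar(name) >= 4L | nchar(element) >= 2L,
         sprintf("%-4s", name), sprintf(" %-3s", name))
}

pdb_atom_lines <- function(at, serial_start = 1L) {
  sprintf(
    "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq(serial_start, length.out = nrow(at)),
    format_atom_name(at$name, at$element), "", at$resname, at$chain,
    at$resnum, at$inscode, at$x, at$y, at$z, at$occupancy, 0, at$element
  )
}

#' Write a configuration to a PDB file
#'
#' Coordinates may be rigidly transformed per unit before formatting to the
#' standard 8.3 fixed-width fields. Read-back coordinates match the
#' (transformed) originals within 1e-3 Angstrom.
#'
#' @param conf a `configuration`.
#' @param path output path.
#' @param transforms optional named list with `reference` and/or `paired`
#'   entries, each a [rigid_transform()].
#' @return `path`, invisibly.
#' @export
write_configuration <- function(conf, path, transforms = NULL) {
  lines <- c(sprintf("REMARK   dockzones configuration %s", conf$id))
  serial <- 1L
  for (side in c("reference", "paired")) {
    at <- conf[[side]]$atoms
    tf <- transforms[[side]]
    if (!is.null(tf)) {
      check_rigid(tf)
      xyz <- apply_rigid(tf, as.matrix(at[, c("x", "y", "z")]))
      at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    }
    for (ch in unique(at$chain)) {
      ca <- at[at$chain == ch, , drop = FALSE]
      lines <- c(lines, pdb_atom_lines(ca, serial))
      serial <- serial + nrow(ca)
      last <- ca[nrow(ca), ]
      lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d%1s",
                                serial, last$resname, last$chain,
                                last$resnum, last$inscode))
      serial <- serial + 1L
    }
  }
  lines <- c(lines, "END")
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) stop_dz("dz_io_error", "cannot write '", path, "': ", ok)
  invisible(path)
}

#' Coordinate matrix of a protein unit
#'
#' @param unit a `protein_unit`.
#' @param heavy_only drop hydrogens first?
#' @return n x 3 matrix of atomic coordinates (Angstrom).
#' @export
unit_coords <- function(unit, heavy_only = FALSE) {
  at <- unit$atoms
  if (heavy_only) at <- at[!at$is_hydrogen, , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

#' C-alpha coordinates of a protein unit
#'
#' @param unit a `protein_unit`.
#' @return matrix of C-alpha coordinates, one row per residue key
#'   (rownames are the keys).
#' @export
unit_ca_coords <- function(unit) {
  at <- unit$atoms
  ca <- at[at$name == "CA" & !at$is_hydrogen, , drop = FALSE]
  ca <- ca[!duplicated(ca$key), , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$key
  m
}

#' Apply a rigid transform to one protein unit
#'
#' @param unit a `protein_unit`.
#' @param tf a [rigid_transform()].
#' @return the transformed `protein_unit`.
#' @export
transform_unit <- function(unit, tf) {
  xyz <- apply_rigid(tf, as.matrix(unit$atoms[, c("x", "y", "z")]))
  unit$atoms$x <- xyz[, 1]
  unit$atoms$y <- xyz[, 2]
  unit$atoms$z <- xyz[, 3]
  unit
}

#' Apply a rigid transform to a whole configuration
#'
#' @param conf a `configuration`.
#' @param tf a [rigid_transform()] applied to both units.
#' @return the transformed `configuration`.
#' @export
transform_configuration <- function(conf, tf) {
  conf$reference <- transform_unit(conf$reference, tf)
  conf$paired <- transform_unit(conf$paired, tf)
  conf
}
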