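#' @keywords internal
"_PACKAGE"

# Residue keys ------------------------------------------------------------
#
# A residue is identified by (chain, number, insertion code) exactly as
# printed in the source PDB; the residue name is carried for display and
# property lookup only, never for identity.

#' Build residue key strings
#'
#' Keys have the form `"<chain>:<number><inscode>"`, e.g. `"A:23"` or
#' `"B:52A"`. Two residues in one protein unit never share a key.
#'
#' @param chain chain identifier(s).
#' @param number residue sequence number(s) as printed in the PDB file.
#' @param inscode insertion code(s), `""` when absent.
#' @return character vector of keys.
#' @export
res_key <- function(chain, number, inscode = "") {
  inscode[is.na(inscode)] <- ""
  paste0(chain, ":", number, inscode)
}

#' Parse residue key strings
#'
#' Inverse of [res_key()]. Accepts `"A:23"`, `"B:52A"`.
#'
#' @param key character vector of keys.
#' @return data.frame with columns `chain`, `number`, `inscode`.
#' @export
parse_res_key <- function(key) {
  m <- regmatches(key, regexec("^([^:]+):(-?[0-9]+)([A-Za-z]?)$", key))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed residue key(s): ", paste(key[bad], collapse = ", "))
  }
  data.frame(
    chain = vapply(m, `[`, "", 2L),
    number = as.integer(vapply(m, `[`, "", 3L)),
    inscode = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

# the 20 standard amino acids, used by the synthetic generator (round-robin
# naming) and the hydrophobicity scale
STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

NUCLEIC_RES <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DI")
WATER_RES <- c("HOH", "WAT", "DOD", "H2O")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dz <- function(class, ...) {
  stop(structure(
    class = c(class, "dockzones_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
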