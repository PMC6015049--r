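# Residue component tables and modified-residue parent mapping.

# 3-letter -> 1-letter, standard amino acids
.aa_3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Standard RNA components (PDB uses single-letter names)
.rna_std <- c(A = "A", C = "C", G = "G", U = "U")

# Modified residue -> parent, seeded from the chemical component dictionary's
# parent field. Extensible at call time via the `extra` argument of
# map_modified_residue().
.mod_protein <- c(
  MSE = "M", FME = "M",                      # selenomethionine, N-formyl-Met
  SEP = "S", TPO = "T", PTR = "Y",           # phospho-Ser/Thr/Tyr
  CSO = "C", CSD = "C", OCS = "C", CME = "C", SEC = "C",
  MLY = "K", MLZ = "K", M3L = "K", ALY = "K", KCX = "K", LLP = "K",
  HYP = "P",                                 # hydroxyproline
  PCA = "E",                                 # pyroglutamate
  CGU = "E"                                  # gamma-carboxy-Glu
)

.mod_rna <- c(
  PSU = "U", H2U = "U", `5MU` = "U", `4SU` = "U", OMU = "U", UR3 = "U",
  `5MC` = "C", OMC = "C",
  `1MA` = "A", `2MA` = "A", MA6 = "A", A2M = "A",
  `1MG` = "G", `2MG` = "G", M2G = "G", `7MG` = "G", G7M = "G",
  OMG = "G", QUO = "G", YG = "G", YYG = "G"
)

.water_names <- c("HOH", "DOD", "WAT", "H2O")

#' Map a residue component name to its one-letter parent code
#'
#' Chemically modified residues are substituted by their standard parent
#' (pseudouridine -> U, selenomethionine -> M, ...) rather than being
#' discarded as "X", so modified positions keep their sequence information.
#' Standard residues map to themselves.
#'
#' @param raw_code residue component name(s) (1-3 letters, e.g. "PSU",
#'   "ALA", "G").
#' @param kind `"protein"` or `"rna"`.
#' @param extra optional named character vector of additional
#'   component -> parent entries, consulted before the packaged table.
#' @return Character vector of one-letter parent codes; unmappable
#'   components return the sentinel `"unknown"` (with a warning).
#' @examples
#' map_modified_residue("PSU", "rna")   # "U"
#' map_modified_residue("QUO", "rna")   # "G" (queuosine)
#' map_modified_residue("MSE", "protein")
#' @export
map_modified_residue <- function(raw_code, kind = c("protein", "rna"),
                                 extra = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(raw_code) >= 1, all(nzchar(raw_code)))
  code <- toupper(trimws(raw_code))
  out <- vapply(code, function(cc) {
    if (!is.null(extra) && cc %in% names(extra)) return(unname(extra[cc]))
    if (kind == "protein") {
      if (cc %in% names(.aa_3to1)) return(unname(.aa_3to1[cc]))
      if (cc %in% names(.mod_protein)) return(unname(.mod_protein[cc]))
      if (nchar(cc) == 1 && cc %in% .aa_3to1) return(cc)
    } else {
      if (cc %in% names(.rna_std)) return(unname(.rna_std[cc]))
      if (cc %in% names(.mod_rna)) return(unname(.mod_rna[cc]))
    }
    "unknown"
  }, character(1))
  if (any(out == "unknown")) {
    warning("unmappable ", kind, " component(s): ",
            paste(unique(code[out == "unknown"]), collapse = ", "),
            call. = FALSE)
  }
  unname(out)
}

# Classify a residue component name without warnings: returns list(kind, code)
# where kind is "protein", "rna", or NA, and code the one-letter parent.
.classify_component <- function(raw_code) {
  cc <- toupper(trimws(raw_code))
  if (cc %in% names(.aa_3to1)) return(list(kind = "protein", code = unname(.aa_3to1[cc]), modified = FALSE))
  if (cc %in% names(.rna_std)) return(list(kind = "rna", code = cc, modified = FALSE))
  if (cc %in% names(.mod_protein)) return(list(kind = "protein", code = unname(.mod_protein[cc]), modified = TRUE))
  if (cc %in% names(.mod_rna)) return(list(kind = "rna", code = unname(.mod_rna[cc]), modified = TRUE))
  list(kind = NA_character_, code = "unknown", modified = FALSE)
}

# Reverse lookup: one-letter amino acid -> 3-letter name (for PDB emission)
.aa_1to3 <- structure(names(.aa_3to1), names = unname(.aa_3to1))
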