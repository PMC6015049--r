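# Reduced alphabets: 20 amino acids -> 4 propensity-derived classes,
# nucleotides (with modified-residue parents) -> {A, C, G, U}.

#' Propensity-derived amino-acid classes
#'
#' The four groups were derived from amino-acid interaction propensities at
#' RNA-protein binding interfaces: the positively charged residues (R, K, H)
#' carry the highest propensity; aspartate behaves like the non-polar
#' hydrophobics (P, M, F, A, V, L, I) and is grouped with them; cysteine and
#' glutamate share the lowest propensity; the remaining seven polar/small
#' residues form the last group.
#'
#' @format A list of four character vectors partitioning the 20 standard
#'   amino acids (one-letter codes).
#' @export
amino_acid_classes <- list(
  positive    = c("R", "K", "H"),
  hydrophobic = c("D", "P", "M", "F", "A", "V", "L", "I"),
  low         = c("C", "E"),
  polar       = c("N", "W", "S", "Q", "Y", "G", "T")
)

#' Class index of a standard amino acid
#'
#' Maps a one-letter amino-acid code to its reduced-alphabet class index
#' (0-3). Codes must be one of the 20 standard amino acids; modified
#' residues should be mapped to their parents first (see
#' [map_modified_residue()]).
#'
#' @param code character vector of one-letter amino-acid codes.
#' @return Integer vector of class indices in 0..3.
#' @examples
#' amino_acid_class(c("R", "D", "C", "N"))
#' @export
amino_acid_class <- function(code) {
  map <- protein_class_map()
  code <- toupper(code)
  bad <- !(code %in% names(map))
  if (any(bad)) {
    stop("non-standard amino acid code(s): ",
         paste(unique(code[bad]), collapse = ", "))
  }
  unname(map[code])
}

#' Amino acid to class-index lookup
#'
#' @return Named integer vector over the 20 standard amino acids with
#'   values 0..3.
#' @export
protein_class_map <- function() {
  out <- integer(0)
  for (i in seq_along(amino_acid_classes)) {
    cls <- amino_acid_classes[[i]]
    out[cls] <- i - 1L
  }
  out[order(names(out))]
}

#' Nucleotide to letter-index lookup
#'
#' RNA keeps its four-letter alphabet (interaction propensities are similar
#' across the four nucleotides); T is read as U so DNA-style FASTA input is
#' accepted.
#'
#' @return Named integer vector mapping A, C, G, U (and T as U) to 0..3.
#' @export
rna_letter_map <- function() {
  c(A = 0L, C = 1L, G = 2L, U = 3L, T = 3L)
}

#' Alphabet map for k-mer encoding
#'
#' Bundles the protein 4-class map, the nucleotide map, and the window size
#' (the minimum structural unit, 5 residues) used by the encoder.
#'
#' @param window window size in residues; 5 is the minimum structural unit.
#' @return An object of class `alphabet_map`.
#' @export
default_alphabet_map <- function(window = 5L) {
  stopifnot(window >= 1)
  structure(
    list(protein_map = protein_class_map(),
         rna_map = rna_letter_map(),
         window = as.integer(window)),
    class = "alphabet_map"
  )
}

#' @export
print.alphabet_map <- function(x, ...) {
  cat("<alphabet_map> window =", x$window,
      "| protein classes =", length(unique(x$protein_map)),
      "| nucleotide letters =", length(unique(x$rna_map)), "\n")
  invisible(x)
}
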