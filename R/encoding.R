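# Minimum-structural-unit k-mer encoding: a sequence pair becomes a
# 2 x 4^window vector of normalized window frequencies (protein block first).

#' Reduced-alphabet k-mer counts of a sequence
#'
#' Slides a window of `window` residues with stride 1 over the sequence,
#' maps each window to a base-4 index (leftmost residue most significant)
#' through the residue -> class map, and tallies a histogram over all
#' 4^window possible windows. Windows containing a residue absent from the
#' map (unknown/unmappable) are skipped.
#'
#' @param seq character string (one-letter codes, case-insensitive; for RNA
#'   maps T is accepted as U).
#' @param map named integer vector mapping residues to 0..3 (see
#'   [protein_class_map()], [rna_letter_map()]).
#' @param window window size; 5 is the minimum structural unit.
#' @return Integer vector of length `4^window`. Sequences shorter than the
#'   window yield an all-zero vector with a warning.
#' @examples
#' kmer_counts("RRRRRR", protein_class_map())[1]  # two windows at index 0
#' @export
kmer_counts <- function(seq, map, window = 5L) {
  stopifnot(is.character(seq), length(seq) == 1, window >= 1)
  n_feat <- 4L^window
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) < window) {
    warning("sequence shorter than window (", length(chars), " < ", window,
            "): all-zero vector", call. = FALSE)
    return(integer(n_feat))
  }
  cls <- unname(map[chars])  # NA for unmappable residues
  wins <- embed(cls, window)[, window:1, drop = FALSE]
  ok <- !apply(is.na(wins), 1, any)
  if (!any(ok)) return(integer(n_feat))
  idx <- as.integer(wins[ok, , drop = FALSE] %*% 4^((window - 1):0))
  tabulate(idx + 1L, nbins = n_feat)
}

#' Scale a count vector into [0, 1]
#'
#' Subtracts the minimum and divides by the maximum of the vector, so the
#' most frequent window maps to 1 regardless of sequence length. All-zero
#' vectors are returned unchanged (no division).
#'
#' @param counts non-negative numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_vector <- function(counts) {
  stopifnot(all(counts >= 0))
  mx <- max(counts)
  if (mx == 0) return(as.numeric(counts))
  (counts - min(counts)) / mx
}

#' Encode an RNA-protein sequence pair as a feature vector
#'
#' Builds the window-5 k-mer histogram of the protein (over the 4-class
#' reduced alphabet) and of the RNA (over A/C/G/U), normalizes each block
#' into `[0, 1]`, and concatenates them: protein features occupy indices
#' 1..4^window, RNA features the next 4^window (F_0..F_1023 /
#' F_1024..F_2047 at window 5).
#'
#' @param protein_seq,rna_seq one-letter sequences (parent-mapped).
#' @param map an `alphabet_map` (see [default_alphabet_map()]).
#' @return Numeric vector of length `2 * 4^window`, class
#'   `pair_feature_vector`.
#' @export
encode_pair <- function(protein_seq, rna_seq, map = default_alphabet_map()) {
  stopifnot(inherits(map, "alphabet_map"),
            nzchar(protein_seq), nzchar(rna_seq))
  pv <- normalize_vector(kmer_counts(protein_seq, map$protein_map, map$window))
  rv <- normalize_vector(kmer_counts(rna_seq, map$rna_map, map$window))
  if (all(pv == 0) && all(rv == 0)) {
    warning("both blocks all-zero: pair carries no window information",
            call. = FALSE)
  }
  structure(c(pv, rv), class = "pair_feature_vector", window = map$window)
}

#' Encode a corpus of pairs as a sparse feature matrix
#'
#' @param corpus a `pair_corpus` (see [build_positive_set()],
#'   [generate_motif_corpus()]), or a data frame with `protein_seq` and
#'   `rna_seq` columns.
#' @param map an `alphabet_map`.
#' @return A sparse `dgCMatrix` with one row per pair (rownames =
#'   `protein_id:rna_id` when available) and `2 * 4^window` columns.
#' @export
encode_corpus <- function(corpus, map = default_alphabet_map()) {
  pairs <- if (inherits(corpus, "pair_corpus")) corpus$pairs else corpus
  stopifnot(all(c("protein_seq", "rna_seq") %in% names(pairs)))
  n <- nrow(pairs)
  vecs <- lapply(seq_len(n), function(i) {
    v <- suppressWarnings(
      encode_pair(pairs$protein_seq[i], pairs$rna_seq[i], map))
    j <- which(v != 0)
    list(j = j, x = v[j])
  })
  lens <- vapply(vecs, function(v) length(v$j), integer(1))
  m <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), lens),
    j = unlist(lapply(vecs, `[[`, "j")),
    x = unlist(lapply(vecs, `[[`, "x")),
    dims = c(n, 2L * 4L^map$window)
  )
  if (all(c("protein_id", "rna_id") %in% names(pairs))) {
    rownames(m) <- paste(pairs$protein_id, pairs$rna_id, sep = ":")
  }
  m
}

#' Write / read a feature matrix as tab-separated text
#'
#' One row per pair: `pair_id`, optional `label`, then the feature values.
#'
#' @param features matrix or sparse matrix of features.
#' @param path file path.
#' @param labels optional 0/1 vector written as a `label` column.
#' @return `write_features` returns the path invisibly; `read_features`
#'   returns a list with `features` (dgCMatrix), `pair_id`, and `labels`
#'   (NULL when absent).
#' @export
write_features <- function(features, path, labels = NULL) {
  df <- as.data.frame(as.matrix(features))
  names(df) <- paste0("F", seq_len(ncol(df)) - 1L)
  id <- rownames(features)
  if (is.null(id)) id <- as.character(seq_len(nrow(df)))
  out <- cbind(pair_id = id,
               if (!is.null(labels)) data.frame(label = labels), df)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df$label
    df$label <- NULL
  }
  id <- df$pair_id
  df$pair_id <- NULL
  m <- Matrix::Matrix(as.matrix(df), sparse = TRUE)
  rownames(m) <- id
  list(features = methods::as(m, "CsparseMatrix"), pair_id = id,
       labels = labels)
}
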