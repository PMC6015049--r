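# Independent oracles used to cross-check the package implementations.
# These are deliberately naive: plain double loops and dictionary counting,
# sharing no code with the functions they verify.

# all-pairs minimum inter-atomic distance (plain double loop)
bf_min_distance <- function(A, B) {
  m <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d < m) m <- d
    }
  }
  m
}

# residue positions of `chain` with any atom strictly within cutoff of any
# atom of `partner` (brute-force scan)
bf_interface_positions <- function(chain, partner, cutoff) {
  P <- as.matrix(partner$atoms[, c("x", "y", "z")])
  hits <- integer(0)
  for (r in unique(chain$atoms$residue)) {
    A <- as.matrix(chain$atoms[chain$atoms$residue == r, c("x", "y", "z"),
                               drop = FALSE])
    if (bf_min_distance(A, P) < cutoff) hits <- c(hits, r)
  }
  sort(hits)
}

# naive substring-histogram k-mer oracle; index from base-4 string parsing
bf_kmer_counts <- function(seq, map, window = 5L) {
  chars <- strsplit(toupper(seq), "")[[1]]
  counts <- integer(4L^window)
  if (length(chars) < window) return(counts)
  for (s in seq_len(length(chars) - window + 1L)) {
    cls <- map[chars[s:(s + window - 1L)]]
    if (anyNA(cls)) next
    idx <- strtoi(paste(cls, collapse = ""), base = 4L)
    counts[idx + 1L] <- counts[idx + 1L] + 1L
  }
  counts
}

# Gotoh affine-gap global alignment score; a gap of length L costs
# gap_open + L * gap_ext (matching the aligner's convention)
bf_nw_score <- function(a, b, match = 1, mismatch = 0, gap_open = 10,
                        gap_ext = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in aligned pair
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in y (x consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in x
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + i * gap_ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + j * gap_ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# nearest-centroid classifier accuracy under a simple split (independent
# check that a corpus carries recoverable signal)
bf_nearest_centroid_accuracy <- function(X, y, train_frac = 0.7, seed = 1) {
  set.seed(seed)
  X <- as.matrix(X)
  idx <- sample(nrow(X))
  ntr <- floor(train_frac * nrow(X))
  tr <- idx[seq_len(ntr)]; te <- idx[-seq_len(ntr)]
  c0 <- colMeans(X[tr[y[tr] == 0], , drop = FALSE])
  c1 <- colMeans(X[tr[y[tr] == 1], , drop = FALSE])
  pred <- apply(X[te, , drop = FALSE], 1, function(v) {
    as.integer(sum((v - c1)^2) < sum((v - c0)^2))
  })
  mean(pred == y[te])
}

# manually assembled chain/complex records for geometry-free tests
make_chain <- function(chain_id, kind, seq, origin = c(0, 0, 0),
                       spacing = 6) {
  codes <- strsplit(seq, "")[[1]]
  atoms <- data.frame(residue = seq_along(codes),
                      x = origin[1] + spacing * seq_along(codes),
                      y = origin[2], z = origin[3])
  rpiboost:::new_chain_record(
    chain_id, kind,
    data.frame(chain_position = seq_along(codes), parent_code = codes,
               raw_code = codes, is_modified = FALSE, n_atoms = 1L,
               stringsAsFactors = FALSE),
    atoms)
}

make_complex <- function(source_id, chains, resolution = 2.0) {
  rpiboost:::new_complex_record(source_id, resolution, "X-RAY DIFFRACTION",
                                chains)
}

make_corpus <- function(pairs) rpiboost:::new_pair_corpus(pairs)

pair_row <- function(rna_id, protein_id, rna_seq, protein_seq,
                     label = "negative", source_complex = "S1") {
  data.frame(rna_id = rna_id, protein_id = protein_id, rna_seq = rna_seq,
             protein_seq = protein_seq, label = label,
             source_complex = source_complex, stringsAsFactors = FALSE)
}

random_protein <- function(n) {
  paste(sample(names(protein_class_map()), n, replace = TRUE), collapse = "")
}
random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
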