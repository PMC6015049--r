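# Synthetic inputs: toy 3-D complexes with planted inter-chain contacts and
# labeled sequence-pair corpora with planted motif co-occurrences. These are
# first-class generators used by the test suite and by `simulate` in the
# CLI; they emit the same PDB / FASTA dialects as the real-data paths.

#' Specification of a toy RNA-protein complex
#'
#' Chains are laid out on two parallel straight lines ~20 Angstrom apart;
#' planted protein positions get a side-chain pseudo-atom displaced to
#' within 4-5 Angstrom of the matching RNA residue, while every other
#' protein residue stays more than 8 Angstrom from the RNA. One backbone and
#' one side-chain pseudo-atom per residue; sufficient for testing the
#' distance rules, no chemistry implied.
#'
#' @param protein_length,rna_length chain lengths in residues (defaults meet
#'   the validity minima of 25 / 15).
#' @param planted_contacts protein positions (1-based) to place in contact;
#'   each position p contacts RNA residue p, so `max(planted_contacts)` must
#'   not exceed `rna_length`.
#' @param spacing distance between consecutive residues along each chain, in
#'   Angstrom; must exceed 5 so only planted residues reach the cutoff.
#' @param contact_residue optional one-letter amino acid forced at every
#'   planted position (e.g. "R" for propensity fixtures).
#' @param resolution resolution written into the PDB header.
#' @param source_id identifier for the emitted complex.
#' @param seed integer seed.
#' @return A `toy_complex_spec`.
#' @export
toy_complex_spec <- function(protein_length = 30L, rna_length = 20L,
                             planted_contacts = c(3L, 7L), spacing = 6.0,
                             contact_residue = NULL, resolution = 2.0,
                             source_id = "TOY1", seed = 1L) {
  stopifnot(protein_length >= 1, rna_length >= 1, spacing > 5)
  planted_contacts <- sort(unique(as.integer(planted_contacts)))
  if (length(planted_contacts)) {
    if (min(planted_contacts) < 1 || max(planted_contacts) > protein_length) {
      stop("planted positions must lie within 1..protein_length")
    }
    if (max(planted_contacts) > rna_length) {
      stop("infeasible geometry: planted position ", max(planted_contacts),
           " has no matching RNA residue (rna_length = ", rna_length, ")")
    }
  }
  structure(list(protein_length = as.integer(protein_length),
                 rna_length = as.integer(rna_length),
                 planted_contacts = planted_contacts, spacing = spacing,
                 contact_residue = contact_residue, resolution = resolution,
                 source_id = source_id, seed = as.integer(seed)),
            class = "toy_complex_spec")
}

.pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                           element) {
  # fixed-column PDB ATOM record: name 13-16, resName 18-20, chain 22,
  # resSeq 23-26, x/y/z 31-54
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resname, chain, resno, x, y, z, 1.00, 0.00, element)
}

#' Generate a toy complex with planted contacts
#'
#' Deterministic given the spec's seed; the same spec yields byte-identical
#' PDB text.
#'
#' @param spec a [toy_complex_spec()].
#' @return A `complex_record` with the emitted PDB text in attribute
#'   `"pdb_text"` (see [write_toy_pdb()]).
#' @export
generate_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  set.seed(spec$seed)
  s <- spec$spacing
  aa <- names(protein_class_map())
  prot_seq <- sample(aa, spec$protein_length, replace = TRUE)
  if (!is.null(spec$contact_residue)) {
    prot_seq[spec$planted_contacts] <- toupper(spec$contact_residue)
  }
  rna_seq <- sample(c("A", "C", "G", "U"), spec$rna_length, replace = TRUE)
  contact_d <- stats::runif(length(spec$planted_contacts), 4.0, 4.9)

  lines <- c(
    sprintf("HEADER    SYNTHETIC RNA-PROTEIN COMPLEX           01-JAN-00   %s", spec$source_id),
    "EXPDTA    X-RAY DIFFRACTION",
    sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", spec$resolution)
  )
  serial <- 0L
  # protein chain A at y = 20 (backbone) / 21 (side chain); planted side
  # chains drop to 1.5 + d of the RNA base atom row at y = 1.5
  for (i in seq_len(spec$protein_length)) {
    resname <- .aa_1to3[prot_seq[i]]
    x <- s * i
    serial <- serial + 1L
    lines <- c(lines, .pdb_atom_line(serial, " CA ", resname, "A", i,
                                     x, 20, 0, "C"))
    k <- match(i, spec$planted_contacts)
    cb_y <- if (is.na(k)) 21 else 1.5 + contact_d[k]
    serial <- serial + 1L
    lines <- c(lines, .pdb_atom_line(serial, " CB ", resname, "A", i,
                                     x, cb_y, 0, "C"))
  }
  lines <- c(lines, "TER")
  # RNA chain B along y = 0 (P) / 1.5 (base pseudo-atom)
  for (i in seq_len(spec$rna_length)) {
    x <- s * i
    serial <- serial + 1L
    lines <- c(lines, .pdb_atom_line(serial, " P  ", rna_seq[i], "B", i,
                                     x, 0, 0, "P"))
    serial <- serial + 1L
    lines <- c(lines, .pdb_atom_line(serial, " N1 ", rna_seq[i], "B", i,
                                     x, 1.5, 0, "N"))
  }
  lines <- c(lines, "TER", "END")
  pdb_text <- paste0(paste(lines, collapse = "\n"), "\n")

  build_chain <- function(chain_id, kind, codes, raw, coords) {
    residues <- data.frame(chain_position = seq_along(codes),
                           parent_code = codes, raw_code = raw,
                           is_modified = FALSE,
                           n_atoms = rep(2L, length(codes)),
                           stringsAsFactors = FALSE)
    new_chain_record(chain_id, kind, residues, coords)
  }
  prot_atoms <- do.call(rbind, lapply(seq_len(spec$protein_length), function(i) {
    k <- match(i, spec$planted_contacts)
    cb_y <- if (is.na(k)) 21 else 1.5 + contact_d[k]
    data.frame(residue = i, x = c(s * i, s * i), y = c(20, cb_y), z = c(0, 0))
  }))
  rna_atoms <- do.call(rbind, lapply(seq_len(spec$rna_length), function(i) {
    data.frame(residue = i, x = c(s * i, s * i), y = c(0, 1.5), z = c(0, 0))
  }))
  cx <- new_complex_record(
    spec$source_id, spec$resolution, "X-RAY DIFFRACTION",
    list(build_chain("A", "protein", prot_seq,
                     unname(.aa_1to3[prot_seq]), prot_atoms),
         build_chain("B", "rna", rna_seq, rna_seq, rna_atoms)))
  attr(cx, "pdb_text") <- pdb_text
  cx
}

#' Write a toy complex's PDB text to disk
#'
#' @param complex a complex from [generate_toy_complex()].
#' @param path output path.
#' @export
write_toy_pdb <- function(complex, path) {
  txt <- attr(complex, "pdb_text")
  if (is.null(txt)) stop("complex carries no PDB text")
  writeLines(sub("\n$", "", txt), path)
  invisible(path)
}

#' Specification of a motif-planted sequence-pair corpus
#'
#' Positive pairs carry a protein motif (expressed over the 4-class reduced
#' alphabet) and an RNA motif co-occurring in the same pair; negatives are
#' motif-free i.i.d. background at the same length distribution. Background
#' residue frequencies are uniform over the alphabet.
#'
#' @param n_positive,n_negative pair counts.
#' @param protein_motif string of class digits 0-3, length = window.
#' @param rna_motif string over A/C/G/U, length = window.
#' @param motif_copies copies of each motif planted per positive pair.
#' @param protein_length_range,rna_length_range background length ranges
#'   (inclusive); minima respect the chain-validity cutoffs (25 / 15).
#' @param seed integer seed.
#' @return A `motif_corpus_spec`.
#' @export
motif_corpus_spec <- function(n_positive = 500L, n_negative = 500L,
                              protein_motif = "00000", rna_motif = "ACGUA",
                              motif_copies = 2L,
                              protein_length_range = c(30L, 80L),
                              rna_length_range = c(20L, 60L), seed = 1L) {
  stopifnot(n_positive >= 0, n_negative >= 0, motif_copies >= 1,
            grepl("^[0-3]+$", protein_motif),
            grepl("^[ACGU]+$", rna_motif),
            protein_length_range[1] >= 25, rna_length_range[1] >= 15,
            protein_length_range[1] >= motif_copies * nchar(protein_motif),
            rna_length_range[1] >= motif_copies * nchar(rna_motif))
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 protein_motif = protein_motif, rna_motif = rna_motif,
                 motif_copies = as.integer(motif_copies),
                 protein_length_range = as.integer(protein_length_range),
                 rna_length_range = as.integer(rna_length_range),
                 seed = as.integer(seed)),
            class = "motif_corpus_spec")
}

# realize a class-digit motif as amino acids (one draw per planted copy)
.realize_protein_motif <- function(motif) {
  digits <- as.integer(strsplit(motif, "")[[1]])
  vapply(digits, function(d) sample(amino_acid_classes[[d + 1L]], 1L),
         character(1))
}

# plant `copies` non-overlapping occurrences of motif characters in seq
.plant <- function(seq_chars, motif_chars_list) {
  w <- length(motif_chars_list[[1]])
  n <- length(seq_chars)
  starts <- integer(0)
  avail <- seq_len(n - w + 1L)
  for (m in motif_chars_list) {
    if (!length(avail)) stop("sequence too short to plant all motif copies")
    st <- if (length(avail) == 1) avail else sample(avail, 1L)
    seq_chars[st:(st + w - 1L)] <- m
    starts <- c(starts, st)
    avail <- setdiff(avail, (st - w + 1L):(st + w - 1L))
  }
  seq_chars
}

.protein_class_string <- function(seq) {
  paste(protein_class_map()[strsplit(seq, "")[[1]]], collapse = "")
}

#' Generate a labeled motif corpus
#'
#' Deterministic given the spec's seed. Positives contain the protein motif
#' at class level and the RNA motif; negatives are rejection-sampled so that
#' neither motif occurs.
#'
#' @param spec a [motif_corpus_spec()].
#' @return A `pair_corpus` with both labels.
#' @export
generate_motif_corpus <- function(spec) {
  stopifnot(inherits(spec, "motif_corpus_spec"))
  set.seed(spec$seed)
  aa <- names(protein_class_map())
  nt <- c("A", "C", "G", "U")
  rmot <- strsplit(spec$rna_motif, "")[[1]]

  draw_len <- function(rng) sample(rng[1]:rng[2], 1L)
  make_pos <- function(i) {
    pl <- draw_len(spec$protein_length_range)
    rl <- draw_len(spec$rna_length_range)
    pseq <- sample(aa, pl, replace = TRUE)
    pseq <- .plant(pseq, replicate(spec$motif_copies,
                                   .realize_protein_motif(spec$protein_motif),
                                   simplify = FALSE))
    rseq <- sample(nt, rl, replace = TRUE)
    rseq <- .plant(rseq, replicate(spec$motif_copies, rmot,
                                   simplify = FALSE))
    c(paste(pseq, collapse = ""), paste(rseq, collapse = ""))
  }
  make_neg <- function(i) {
    repeat {
      pl <- draw_len(spec$protein_length_range)
      pseq <- paste(sample(aa, pl, replace = TRUE), collapse = "")
      if (!grepl(spec$protein_motif, .protein_class_string(pseq),
                 fixed = TRUE)) break
    }
    repeat {
      rl <- draw_len(spec$rna_length_range)
      rseq <- paste(sample(nt, rl, replace = TRUE), collapse = "")
      if (!grepl(spec$rna_motif, rseq, fixed = TRUE)) break
    }
    c(pseq, rseq)
  }
  pos <- lapply(seq_len(spec$n_positive), make_pos)
  neg <- lapply(seq_len(spec$n_negative), make_neg)
  fmt <- function(lst, label, offset) {
    if (!length(lst)) return(.empty_pairs())
    data.frame(
      rna_id = sprintf("r%04d", offset + seq_along(lst)),
      protein_id = sprintf("p%04d", offset + seq_along(lst)),
      rna_seq = vapply(lst, `[`, "", 2),
      protein_seq = vapply(lst, `[`, "", 1),
      label = label, source_complex = "synthetic",
      stringsAsFactors = FALSE)
  }
  pairs <- rbind(fmt(pos, "positive", 0L), fmt(neg, "negative",
                                               spec$n_positive))
  rownames(pairs) <- NULL
  new_pair_corpus(pairs, provenance = c(unclass(spec), list(kind = "motif_corpus")))
}
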