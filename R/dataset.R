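# Positive/negative training-set construction: interacting chain pairs from
# complexes, exact-duplicate removal, combinatorial negative candidates,
# sequence-similarity filters, and ratio-matched balancing.

new_pair_corpus <- function(pairs, provenance = list()) {
  stopifnot(is.data.frame(pairs))
  structure(list(pairs = pairs, provenance = provenance),
            class = "pair_corpus")
}

#' @export
print.pair_corpus <- function(x, ...) {
  tab <- table(factor(x$pairs$label, levels = c("positive", "negative")))
  cat("<pair_corpus>", nrow(x$pairs), "pairs (",
      tab[["positive"]], "positive /", tab[["negative"]], "negative )\n")
  invisible(x)
}

.empty_pairs <- function() {
  data.frame(rna_id = character(0), protein_id = character(0),
             rna_seq = character(0), protein_seq = character(0),
             label = character(0), source_complex = character(0),
             stringsAsFactors = FALSE)
}

# valid chains of a (validated) complex, split by kind
.valid_chains <- function(complex) {
  kinds <- vapply(complex$chains, function(ch) ch$kind, character(1))
  list(rna = complex$chains[kinds == "rna"],
       protein = complex$chains[kinds == "protein"])
}

#' Build the deduplicated positive pair set
#'
#' Every RNA/protein chain pair within a complex whose minimal inter-atomic
#' distance is below `cutoff` contributes one positive pair; exact
#' duplicate (RNA sequence, protein sequence) tuples across the corpus are
#' collapsed to the first-seen occurrence.
#'
#' @param complexes list of validated `complex_record`s (rejected complexes
#'   are skipped).
#' @param cutoff interacting-pair distance cutoff in Angstrom (strict `<`).
#' @return A `pair_corpus` of positives.
#' @export
build_positive_set <- function(complexes, cutoff = 8.0) {
  rows <- list()
  for (cx in complexes) {
    if (isTRUE(cx$rejected)) next
    ip <- find_interacting_pairs(cx, cutoff = cutoff)
    for (i in seq_len(nrow(ip))) {
      rch <- .get_chain(cx, ip$rna_chain_id[i])
      pch <- .get_chain(cx, ip$protein_chain_id[i])
      rows[[length(rows) + 1L]] <- data.frame(
        rna_id = paste0(cx$source_id, "_", rch$chain_id),
        protein_id = paste0(cx$source_id, "_", pch$chain_id),
        rna_seq = chain_sequence(rch),
        protein_seq = chain_sequence(pch),
        label = "positive",
        source_complex = cx$source_id,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    warning("no interacting RNA-protein pairs found", call. = FALSE)
    return(new_pair_corpus(.empty_pairs(),
                           provenance = list(cutoff = cutoff)))
  }
  pairs <- do.call(rbind, rows)
  pairs <- pairs[!duplicated(paste(pairs$rna_seq, pairs$protein_seq,
                                   sep = "\r")), , drop = FALSE]
  rownames(pairs) <- NULL
  new_pair_corpus(pairs, provenance = list(cutoff = cutoff))
}

#' Generate negative pair candidates
#'
#' Complexes with exactly one valid RNA and one valid protein chain are
#' monomeric; each monomeric RNA is paired with the protein of every other
#' monomeric complex. In multimeric complexes each RNA is paired with the
#' proteins of the same complex it does not interact with (the R1-P2 swap).
#'
#' @param complexes list of validated `complex_record`s.
#' @param cutoff interacting-pair cutoff used to decide non-interaction
#'   within multimeric complexes.
#' @return Data frame of candidate pairs labeled `"negative"`.
#' @export
generate_negative_candidates <- function(complexes, cutoff = 8.0) {
  complexes <- Filter(function(cx) !isTRUE(cx$rejected), complexes)
  rows <- list()
  mono <- list()
  for (cx in complexes) {
    vc <- .valid_chains(cx)
    if (length(vc$rna) == 1 && length(vc$protein) == 1) {
      mono[[length(mono) + 1L]] <- list(cx = cx, rna = vc$rna[[1]],
                                        protein = vc$protein[[1]])
    } else {
      # multimeric: swap RNA against non-interacting proteins of the complex
      ip <- find_interacting_pairs(cx, cutoff = cutoff)
      for (r in vc$rna) {
        partners <- ip$protein_chain_id[ip$rna_chain_id == r$chain_id]
        for (p in vc$protein) {
          if (p$chain_id %in% partners) next
          rows[[length(rows) + 1L]] <- data.frame(
            rna_id = paste0(cx$source_id, "_", r$chain_id),
            protein_id = paste0(cx$source_id, "_", p$chain_id),
            rna_seq = chain_sequence(r), protein_seq = chain_sequence(p),
            label = "negative", source_complex = cx$source_id,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(mono) > 1) {
    for (i in seq_along(mono)) {
      for (j in seq_along(mono)) {
        if (i == j) next
        rows[[length(rows) + 1L]] <- data.frame(
          rna_id = paste0(mono[[i]]$cx$source_id, "_", mono[[i]]$rna$chain_id),
          protein_id = paste0(mono[[j]]$cx$source_id, "_",
                              mono[[j]]$protein$chain_id),
          rna_seq = chain_sequence(mono[[i]]$rna),
          protein_seq = chain_sequence(mono[[j]]$protein),
          label = "negative",
          source_complex = paste0(mono[[i]]$cx$source_id, "x",
                                  mono[[j]]$cx$source_id),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(.empty_pairs())
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(out$rna_seq, out$protein_seq, sep = "\r")), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent identity of two sequences under global alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0, gap open
#' -10, gap extension -1; identity is 100 x matches / alignment length,
#' counting gap columns in the length.
#'
#' @param a,b sequences of the same molecule kind (both protein or both
#'   nucleotide).
#' @param kind `"auto"` infers the kind from the alphabets and errors on a
#'   mix; or force `"protein"` / `"rna"`.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' sequence_identity("ACDEFGHIK", "ACDEFGHIW")  # 8/9
#' @export
sequence_identity <- function(a, b, kind = c("auto", "protein", "rna")) {
  kind <- match.arg(kind)
  stopifnot(nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  if (kind == "auto") {
    nuc <- function(s) all(strsplit(s, "")[[1]] %in%
                             c("A", "C", "G", "U", "T", "N", "X"))
    ka <- if (nuc(a)) "rna" else "protein"
    kb <- if (nuc(b)) "rna" else "protein"
    if (ka != kb) stop("mixed molecule kinds: ", ka, " vs ", kb)
  }
  letters_ab <- sort(unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])))
  sub <- matrix(0, length(letters_ab), length(letters_ab),
                dimnames = list(letters_ab, letters_ab))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b), type = "global",
    substitutionMatrix = sub, gapOpening = 10, gapExtension = 1)
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(ap == as_ & ap != "-") / length(ap)
}

# identity with memoization keyed on the two sequences (order-free)
.identity_cache <- function() {
  cache <- new.env(parent = emptyenv())
  function(a, b, kind) {
    key <- paste(sort(c(a, b)), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- sequence_identity(a, b, kind)
    cache[[key]] <- v
    v
  }
}

#' Filter negative candidates by the positive-overlap and similarity rules
#'
#' A candidate (R, P) is kept iff (1) it is not an exact positive pair;
#' (2) P has strictly less than `sim_threshold` percent identity to every
#' protein positively paired with R, and symmetrically R to every RNA
#' positively paired with P; and (3) within the surviving negative set,
#' proteins sharing an RNA partner and RNAs sharing a protein partner are
#' mutually below the threshold (greedy scan in deterministic input order,
#' first kept wins).
#'
#' @param candidates data frame of negative candidates.
#' @param positives a `pair_corpus` of positives.
#' @param sim_threshold percent-identity threshold (strict `<`).
#' @return The surviving candidates (same columns), in scan order.
#' @export
filter_negatives <- function(candidates, positives, sim_threshold = 30) {
  stopifnot(inherits(positives, "pair_corpus"))
  pos <- positives$pairs
  if (!nrow(candidates)) return(candidates)
  # deterministic scan order
  ord <- order(candidates$source_complex, candidates$protein_id,
               candidates$rna_id)
  candidates <- candidates[ord, , drop = FALSE]
  idy <- .identity_cache()
  pos_key <- paste(pos$rna_seq, pos$protein_seq, sep = "\r")

  ok1 <- !(paste(candidates$rna_seq, candidates$protein_seq, sep = "\r")
           %in% pos_key)

  pass2 <- function(i) {
    r <- candidates$rna_seq[i]; p <- candidates$protein_seq[i]
    prot_partners <- unique(pos$protein_seq[pos$rna_seq == r])
    for (q in prot_partners) {
      if (idy(p, q, "protein") >= sim_threshold) return(FALSE)
    }
    rna_partners <- unique(pos$rna_seq[pos$protein_seq == p])
    for (q in rna_partners) {
      if (idy(r, q, "rna") >= sim_threshold) return(FALSE)
    }
    TRUE
  }
  ok2 <- vapply(seq_len(nrow(candidates)), function(i) {
    ok1[i] && pass2(i)
  }, logical(1))
  surv <- candidates[ok2, , drop = FALSE]

  # rule 3: mutual dissimilarity among kept negatives sharing a partner
  kept <- integer(0)
  for (i in seq_len(nrow(surv))) {
    clash <- FALSE
    for (k in kept) {
      if (surv$rna_seq[k] == surv$rna_seq[i] &&
          idy(surv$protein_seq[k], surv$protein_seq[i],
              "protein") >= sim_threshold) { clash <- TRUE; break }
      if (surv$protein_seq[k] == surv$protein_seq[i] &&
          idy(surv$rna_seq[k], surv$rna_seq[i], "rna") >= sim_threshold) {
        clash <- TRUE; break
      }
    }
    if (!clash) kept <- c(kept, i)
  }
  out <- surv[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Audit a negative set against the construction rules
#'
#' Independent re-check of the three negative-set rules on an already
#' constructed set; used for post-hoc validation.
#'
#' @inheritParams filter_negatives
#' @param negatives data frame of negatives to audit.
#' @return Logical vector, one entry per negative, TRUE when all rules hold.
#' @export
audit_negatives <- function(negatives, positives, sim_threshold = 30) {
  pos <- positives$pairs
  pos_key <- paste(pos$rna_seq, pos$protein_seq, sep = "\r")
  n <- nrow(negatives)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    r <- negatives$rna_seq[i]; p <- negatives$protein_seq[i]
    if (paste(r, p, sep = "\r") %in% pos_key) { ok[i] <- FALSE; next }
    for (q in unique(pos$protein_seq[pos$rna_seq == r])) {
      if (sequence_identity(p, q, "protein") >= sim_threshold) ok[i] <- FALSE
    }
    for (q in unique(pos$rna_seq[pos$protein_seq == p])) {
      if (sequence_identity(r, q, "rna") >= sim_threshold) ok[i] <- FALSE
    }
    if (!ok[i]) next
    for (k in seq_len(n)) {
      if (k == i) next
      if (negatives$rna_seq[k] == r && negatives$protein_seq[k] != p &&
          sequence_identity(negatives$protein_seq[k], p,
                            "protein") >= sim_threshold) ok[i] <- FALSE
      if (negatives$protein_seq[k] == p && negatives$rna_seq[k] != r &&
          sequence_identity(negatives$rna_seq[k], r,
                            "rna") >= sim_threshold) ok[i] <- FALSE
    }
  }
  ok
}

# unique-protein : unique-RNA ratio of a pair table
.chain_ratio <- function(pairs) {
  length(unique(pairs$protein_seq)) / length(unique(pairs$rna_seq))
}

#' Select a balanced negative subset matching the positive chain ratio
#'
#' Picks exactly as many negatives as there are positives by a seeded
#' greedy procedure: candidates are shuffled, then at each step the
#' candidate whose addition brings the running unique-protein:unique-RNA
#' ratio closest to the positive set's ratio is taken (ties resolved by
#' shuffle order). Deterministic given the seed.
#'
#' @param negatives data frame of filtered negatives.
#' @param positives a `pair_corpus` of positives.
#' @param seed integer seed.
#' @return A `pair_corpus` holding the selected negatives (all negatives,
#'   with a warning, when fewer candidates than positives exist).
#' @export
balance_subset <- function(negatives, positives, seed = 1L) {
  n_target <- nrow(positives$pairs)
  if (nrow(negatives) < n_target) {
    warning("fewer negatives (", nrow(negatives), ") than positives (",
            n_target, "): returning all negatives", call. = FALSE)
    return(new_pair_corpus(negatives, provenance = list(seed = seed)))
  }
  if (nrow(negatives) == n_target) {
    return(new_pair_corpus(negatives, provenance = list(seed = seed)))
  }
  target <- .chain_ratio(positives$pairs)
  set.seed(seed)
  pool <- negatives[sample.int(nrow(negatives)), , drop = FALSE]
  sel <- integer(0)
  prot_seen <- character(0); rna_seen <- character(0)
  remaining <- seq_len(nrow(pool))
  for (step in seq_len(n_target)) {
    np <- length(prot_seen); nr <- length(rna_seen)
    cand_np <- np + !(pool$protein_seq[remaining] %in% prot_seen)
    cand_nr <- nr + !(pool$rna_seq[remaining] %in% rna_seen)
    dev <- abs(cand_np / cand_nr - target)
    pick <- remaining[which.min(dev)]
    sel <- c(sel, pick)
    prot_seen <- union(prot_seen, pool$protein_seq[pick])
    rna_seen <- union(rna_seen, pool$rna_seq[pick])
    remaining <- setdiff(remaining, pick)
  }
  out <- pool[sel, , drop = FALSE]
  rownames(out) <- NULL
  new_pair_corpus(out, provenance = list(seed = seed,
                                         target_ratio = target))
}

#' Assemble a labeled training corpus
#'
#' Convenience wrapper: positives from interacting chain pairs, negative
#' candidates, similarity filtering, and ratio-matched balancing, returned
#' as one labeled corpus with full provenance.
#'
#' @param complexes list of validated `complex_record`s.
#' @param sim_threshold percent-identity threshold for the negative filters.
#' @param seed integer seed for the balancing step.
#' @param cutoff interacting-pair distance cutoff in Angstrom.
#' @return A `pair_corpus` with both labels.
#' @export
build_training_corpus <- function(complexes, sim_threshold = 30, seed = 1L,
                                  cutoff = 8.0) {
  positives <- build_positive_set(complexes, cutoff = cutoff)
  cand <- generate_negative_candidates(complexes, cutoff = cutoff)
  neg <- filter_negatives(cand, positives, sim_threshold = sim_threshold)
  bal <- balance_subset(neg, positives, seed = seed)
  pairs <- rbind(positives$pairs, bal$pairs)
  rownames(pairs) <- NULL
  new_pair_corpus(pairs, provenance = list(cutoff = cutoff,
                                           sim_threshold = sim_threshold,
                                           seed = seed))
}

#' Write / read a pair corpus as FASTA + pair table
#'
#' Writes `<prefix>_proteins.fasta`, `<prefix>_rnas.fasta`, a tab-separated
#' `<prefix>_pairs.tsv` (protein_id, rna_id, label, source), and a
#' `<prefix>_config.txt` key=value provenance snapshot.
#'
#' @param corpus a `pair_corpus`.
#' @param prefix path prefix for the emitted files.
#' @return `write_corpus` returns the file paths invisibly; `read_corpus`
#'   returns a `pair_corpus`.
#' @export
write_corpus <- function(corpus, prefix) {
  p <- corpus$pairs
  prot <- p$protein_seq[!duplicated(p$protein_id)]
  names(prot) <- p$protein_id[!duplicated(p$protein_id)]
  rna <- p$rna_seq[!duplicated(p$rna_id)]
  names(rna) <- p$rna_id[!duplicated(p$rna_id)]
  paths <- c(proteins = paste0(prefix, "_proteins.fasta"),
             rnas = paste0(prefix, "_rnas.fasta"),
             pairs = paste0(prefix, "_pairs.tsv"),
             config = paste0(prefix, "_config.txt"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(prot), paths["proteins"])
  Biostrings::writeXStringSet(Biostrings::BStringSet(rna), paths["rnas"])
  utils::write.table(p[, c("protein_id", "rna_id", "label", "source_complex")],
                     paths["pairs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prov <- corpus$provenance
  writeLines(paste0(names(prov), "=",
                    vapply(prov, function(v)
                      paste(format(v), collapse = ","), character(1))),
             paths["config"])
  invisible(paths)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(prefix) {
  prot <- Biostrings::readBStringSet(paste0(prefix, "_proteins.fasta"))
  rna <- Biostrings::readBStringSet(paste0(prefix, "_rnas.fasta"))
  tab <- utils::read.delim(paste0(prefix, "_pairs.tsv"),
                           stringsAsFactors = FALSE)
  pairs <- data.frame(
    rna_id = tab$rna_id, protein_id = tab$protein_id,
    rna_seq = as.character(rna[tab$rna_id]),
    protein_seq = as.character(prot[tab$protein_id]),
    label = tab$label,
    source_complex = tab$source_complex,
    stringsAsFactors = FALSE
  )
  prov <- list()
  cfg <- paste0(prefix, "_config.txt")
  if (file.exists(cfg)) {
    kv <- strsplit(readLines(cfg), "=", fixed = TRUE)
    kv <- kv[lengths(kv) == 2]
    prov <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  }
  new_pair_corpus(pairs, provenance = prov)
}
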