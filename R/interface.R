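# Interface detection by distance cutoff, binding-interface segments, and
# amino-acid interaction propensities.

# squared-distance based minimum computations; blocks cap memory on large
# chains (a full n x m matrix is fine up to ~4e6 entries)
.cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

.chain_coords <- function(chain) {
  as.matrix(chain$atoms[, c("x", "y", "z")])
}

.get_chain <- function(complex, chain_id) {
  for (ch in complex$chains) if (ch$chain_id == chain_id) return(ch)
  stop("unknown chain ID: ", chain_id, " in ", complex$source_id)
}

# minimum inter-atomic distance between two coordinate sets, and per-atom
# minima for both sides, computed blockwise
.min_dist_profile <- function(A, B, block = 2000L) {
  na <- nrow(A); nb <- nrow(B)
  minA <- rep(Inf, na); minB <- rep(Inf, nb)
  for (i0 in seq(1, na, by = block)) {
    i1 <- min(i0 + block - 1L, na)
    d2 <- .cross_dist2(A[i0:i1, , drop = FALSE], B)
    minA[i0:i1] <- pmin(minA[i0:i1], apply(d2, 1, min))
    minB <- pmin(minB, apply(d2, 2, min))
  }
  list(min_a = sqrt(minA), min_b = sqrt(minB), min = sqrt(min(minA)))
}

#' Find interacting RNA-protein chain pairs
#'
#' An RNA chain and a protein chain in the same complex are classified as
#' interacting when their minimal inter-atomic distance is strictly below
#' `cutoff` (default 8 Angstrom). All atoms participate; waters and ions
#' were already excluded at parse time.
#'
#' @param complex a `complex_record`.
#' @param cutoff distance cutoff in Angstrom (strict `<`).
#' @return Data frame with columns `rna_chain_id`, `protein_chain_id`,
#'   `min_distance` (one row per interacting pair).
#' @export
find_interacting_pairs <- function(complex, cutoff = 8.0) {
  stopifnot(inherits(complex, "complex_record"))
  kinds <- vapply(complex$chains, function(ch) ch$kind, character(1))
  for (ch in complex$chains) {
    if (nrow(ch$atoms) == 0) stop("chain without atoms: ", ch$chain_id)
  }
  rna <- complex$chains[kinds == "rna"]
  prot <- complex$chains[kinds == "protein"]
  out <- data.frame(rna_chain_id = character(0),
                    protein_chain_id = character(0),
                    min_distance = numeric(0))
  for (r in rna) {
    for (p in prot) {
      md <- .min_dist_profile(.chain_coords(r), .chain_coords(p))$min
      if (md < cutoff) {
        out <- rbind(out, data.frame(rna_chain_id = r$chain_id,
                                     protein_chain_id = p$chain_id,
                                     min_distance = md))
      }
    }
  }
  out
}

#' Interface residues of an RNA-protein chain pair
#'
#' A residue belongs to the binding interface when any of its atoms lies
#' strictly within `cutoff` (default 5 Angstrom) of any atom of the partner
#' chain.
#'
#' @param complex a `complex_record`.
#' @param rna_chain_id,protein_chain_id chain identifiers.
#' @param cutoff distance cutoff in Angstrom (strict `<`).
#' @return A `contact_map`: list with the chain ids, the sets of 1-based
#'   interface positions on each chain, and the overall minimum distance.
#' @export
interface_residues <- function(complex, rna_chain_id, protein_chain_id,
                               cutoff = 5.0) {
  rch <- .get_chain(complex, rna_chain_id)
  pch <- .get_chain(complex, protein_chain_id)
  if (rch$kind != "rna") stop("chain ", rna_chain_id, " is not RNA")
  if (pch$kind != "protein") stop("chain ", protein_chain_id, " is not protein")
  prof <- .min_dist_profile(.chain_coords(rch), .chain_coords(pch))
  rna_pos <- sort(unique(rch$atoms$residue[prof$min_a < cutoff]))
  prot_pos <- sort(unique(pch$atoms$residue[prof$min_b < cutoff]))
  structure(list(rna_chain_id = rna_chain_id,
                 protein_chain_id = protein_chain_id,
                 interface_rna_positions = rna_pos,
                 interface_protein_positions = prot_pos,
                 min_distance = prof$min,
                 cutoff = cutoff),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> RNA %s / protein %s (< %.1f A): %d RNA + %d protein interface residues, min %.2f A\n",
              x$rna_chain_id, x$protein_chain_id, x$cutoff,
              length(x$interface_rna_positions),
              length(x$interface_protein_positions), x$min_distance))
  invisible(x)
}

#' Merge interacting positions into binding-interface segments
#'
#' Consecutive interacting positions are joined into one segment when at
#' most `max_gap` non-interacting residues intervene; the bordering
#' positions of every segment are interacting. The extent of a segment is
#' `end - start + 1`, counting admitted non-interacting residues: positions
#' 5 and 9 alone give one segment of extent 5.
#'
#' @param positions integer vector of 1-based interacting positions.
#' @param max_gap maximum number of intervening non-interacting residues.
#' @return Data frame with columns `start`, `end`, `extent`,
#'   `n_interacting`; zero rows for empty input.
#' @export
interface_segments <- function(positions, max_gap = 3L) {
  if (length(positions) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      extent = integer(0), n_interacting = integer(0)))
  }
  stopifnot(all(positions >= 1), all(positions == as.integer(positions)))
  pos <- sort(unique(as.integer(positions)))
  # a gap of g non-interacting residues between consecutive interacting
  # positions means diff = g + 1; join while g <= max_gap
  brk <- c(0L, which(diff(pos) > max_gap + 1L), length(pos))
  out <- data.frame(start = integer(0), end = integer(0),
                    extent = integer(0), n_interacting = integer(0))
  for (i in seq_len(length(brk) - 1L)) {
    seg <- pos[(brk[i] + 1L):brk[i + 1L]]
    out <- rbind(out, data.frame(start = seg[1], end = seg[length(seg)],
                                 extent = seg[length(seg)] - seg[1] + 1L,
                                 n_interacting = length(seg)))
  }
  out
}

#' Amino-acid interaction propensities at binding interfaces
#'
#' For each amino acid j, counts I_j interacting residues across all
#' interfaces and N_j non-interacting residues lying inside interface
#' segments (the residues admitted by the gap rule), then computes the
#' propensity P_j = (I_j / I_n) / (N_j / N_n) with I_n, N_n the
#' corresponding totals. Residues with unknown parent codes are skipped.
#'
#' @param contact_maps list of `contact_map` objects.
#' @param chains named list of `chain_record`s (names are chain ids)
#'   covering every protein chain referenced; alternatively a
#'   `complex_record` whose chains are used.
#' @param max_gap gap rule for interface segments.
#' @return A `propensity_table`: data frame with columns `aa`, `I_j`, `N_j`,
#'   `P_j`, `class`, with totals in attributes `I_n` and `N_n`.
#' @export
compute_propensities <- function(contact_maps, chains, max_gap = 3L) {
  if (inherits(contact_maps, "contact_map")) contact_maps <- list(contact_maps)
  if (inherits(chains, "complex_record")) chains <- chains$chains
  if (is.null(names(chains)) || !all(nzchar(names(chains)))) {
    names(chains) <- vapply(chains, function(ch) ch$chain_id, character(1))
  }
  aas <- sort(names(protein_class_map()))
  I_j <- stats::setNames(integer(length(aas)), aas)
  N_j <- stats::setNames(integer(length(aas)), aas)
  for (cm in contact_maps) {
    ch <- chains[[cm$protein_chain_id]]
    if (is.null(ch)) stop("chain lookup missing protein chain ",
                          cm$protein_chain_id)
    codes <- ch$residues$parent_code
    ipos <- cm$interface_protein_positions
    segs <- interface_segments(ipos, max_gap = max_gap)
    in_seg <- unlist(lapply(seq_len(nrow(segs)),
                            function(i) segs$start[i]:segs$end[i]))
    npos <- setdiff(in_seg, ipos)
    ic <- codes[ipos]; nc <- codes[npos]
    ic <- ic[ic %in% aas]; nc <- nc[nc %in% aas]
    ti <- table(ic); tn <- table(nc)
    I_j[names(ti)] <- I_j[names(ti)] + as.integer(ti)
    N_j[names(tn)] <- N_j[names(tn)] + as.integer(tn)
  }
  I_n <- sum(I_j); N_n <- sum(N_j)
  if (I_n == 0 || N_n == 0) {
    stop("undefined propensities: need at least one interacting and one ",
         "non-interacting residue at the interfaces (I_n=", I_n,
         ", N_n=", N_n, ")")
  }
  P_j <- numeric(length(aas))
  for (i in seq_along(aas)) {
    if (I_j[i] == 0) {
      P_j[i] <- 0
    } else if (N_j[i] == 0) {
      P_j[i] <- Inf
      warning("N_j = 0 with I_j > 0 for ", aas[i],
              ": propensity reported as +Inf", call. = FALSE)
    } else {
      P_j[i] <- (I_j[i] / I_n) / (N_j[i] / N_n)
    }
  }
  out <- data.frame(aa = aas, I_j = unname(I_j), N_j = unname(N_j),
                    P_j = P_j, class = amino_acid_class(aas),
                    stringsAsFactors = FALSE)
  attr(out, "I_n") <- I_n
  attr(out, "N_n") <- N_n
  class(out) <- c("propensity_table", "data.frame")
  out
}

#' Write a propensity table as tab-separated text
#'
#' @param tab a `propensity_table`.
#' @param path output path.
#' @export
write_propensity_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# I_n=%d\tN_n=%d", attr(tab, "I_n"), attr(tab, "N_n")),
             con)
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write interface segments as a BED-like table
#'
#' Coordinates are 1-based inclusive, as stated in the emitted header.
#'
#' @param segments data frame from [interface_segments()].
#' @param chain_id chain identifier for the first column.
#' @param path output path.
#' @export
write_segments <- function(segments, chain_id, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chain\tstart\tend\textent (1-based inclusive coordinates)", con)
  if (nrow(segments)) {
    utils::write.table(cbind(chain = chain_id,
                             segments[, c("start", "end", "extent")]),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
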