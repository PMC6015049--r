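# Reading and validating RNA-protein complex structures.
#
# A complex_record holds, per chain, the ordered residues (parent-mapped
# one-letter codes) and a flat atom table (residue ordinal, x, y, z) so the
# distance rules can operate on plain matrices.

#' @export
print.complex_record <- function(x, ...) {
  cat("<complex_record>", x$source_id,
      "| resolution:", ifelse(is.na(x$resolution), "NA", x$resolution),
      "| method:", x$method, "\n")
  for (ch in x$chains) {
    cat("  chain", ch$chain_id, sprintf("(%s, %d residues, %d atoms)\n",
        ch$kind, nrow(ch$residues), nrow(ch$atoms)))
  }
  if (isTRUE(x$rejected)) cat("  REJECTED:", x$reject_reason, "\n")
  invisible(x)
}

new_chain_record <- function(chain_id, kind, residues, atoms) {
  stopifnot(is.data.frame(residues), is.data.frame(atoms))
  structure(list(chain_id = chain_id, kind = kind,
                 residues = residues, atoms = atoms),
            class = "chain_record")
}

new_complex_record <- function(source_id, resolution, method, chains,
                               rejected = FALSE, reject_reason = NULL) {
  structure(list(source_id = source_id, resolution = resolution,
                 method = method, chains = chains,
                 rejected = rejected, reject_reason = reject_reason),
            class = "complex_record")
}

#' One-letter sequence of a chain
#'
#' Parent-mapped sequence; residues with no known parent appear as `X`.
#'
#' @param chain a `chain_record`.
#' @return Single character string.
#' @export
chain_sequence <- function(chain) {
  codes <- chain$residues$parent_code
  codes[codes == "unknown"] <- "X"
  paste(codes, collapse = "")
}

# Scrape resolution / experimental method from the raw file header.
.read_structure_header <- function(path, format) {
  lines <- readLines(path, n = 5000L, warn = FALSE)
  resolution <- NA_real_
  method <- "unknown"
  if (format == "pdb") {
    res_line <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(res_line)) {
      m <- regmatches(res_line[1],
                      regexpr("[0-9]+\\.?[0-9]*(?= +ANGSTROM)", res_line[1],
                              perl = TRUE))
      if (length(m)) resolution <- as.numeric(m)
    }
    exp_line <- grep("^EXPDTA", lines, value = TRUE)
    if (length(exp_line)) method <- trimws(substring(exp_line[1], 11))
  } else {
    res_line <- grep("_refine\\.ls_d_res_high", lines, value = TRUE)
    if (length(res_line)) {
      m <- regmatches(res_line[1], regexpr("[0-9]+\\.?[0-9]*", res_line[1]))
      if (length(m)) resolution <- as.numeric(m)
    }
    mi <- grep("^_exptl\\.method", lines)
    if (length(mi)) {
      mi <- mi[1]
      val <- trimws(sub("^_exptl\\.method", "", lines[mi]))
      if (nzchar(val)) {
        method <- gsub("['\"]", "", val)
      } else {
        # loop form: method position among the _exptl.* tags indexes the
        # data row that follows them
        first <- mi
        while (first > 1 && grepl("^_exptl\\.", lines[first - 1])) {
          first <- first - 1L
        }
        last <- mi
        while (last < length(lines) && grepl("^_exptl\\.", lines[last + 1])) {
          last <- last + 1L
        }
        toks <- scan(text = lines[last + 1L], what = character(),
                     quote = "'\"", quiet = TRUE)
        pos <- mi - first + 1L
        if (length(toks) >= pos) method <- toks[pos]
      }
    }
  }
  list(resolution = resolution, method = method)
}

# Minimal generic mmCIF _atom_site reader: resolves columns by tag name, so
# it tolerates dialects whose column order differs from the RCSB layout.
# Returns a bio3d-shaped list(atom = data.frame).
.read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag_idx <- grep("^_atom_site\\.", lines)
  if (!length(tag_idx)) stop("no _atom_site loop found")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1L
  body_end <- body_start
  while (body_end <= length(lines) &&
         !grepl("^\\s*(#|loop_|_|$)", lines[body_end])) {
    body_end <- body_end + 1L
  }
  rows <- lines[body_start:(body_end - 1L)]
  toks <- scan(text = rows, what = character(), quote = "'\"",
               quiet = TRUE)
  if (length(toks) %% length(tags) != 0) {
    stop("malformed _atom_site loop (ragged rows)")
  }
  m <- matrix(toks, ncol = length(tags), byrow = TRUE,
              dimnames = list(NULL, tags))
  col <- function(name, alt = NULL) {
    if (name %in% tags) m[, name]
    else if (!is.null(alt) && alt %in% tags) m[, alt]
    else rep(NA_character_, nrow(m))
  }
  blank <- function(x) ifelse(x %in% c(".", "?"), "", x)
  atom <- data.frame(
    type = col("group_PDB"),
    eleno = as.integer(col("id")),
    elety = blank(col("label_atom_id", "auth_atom_id")),
    alt = blank(col("label_alt_id")),
    resid = blank(col("label_comp_id", "auth_comp_id")),
    chain = blank(col("auth_asym_id", "label_asym_id")),
    resno = as.integer(blank(col("auth_seq_id", "label_seq_id"))),
    insert = blank(col("pdbx_PDB_ins_code")),
    x = as.numeric(col("Cartn_x")),
    y = as.numeric(col("Cartn_y")),
    z = as.numeric(col("Cartn_z")),
    stringsAsFactors = FALSE
  )
  if ("pdbx_PDB_model_num" %in% tags) {
    first_model <- m[1, "pdbx_PDB_model_num"]
    atom <- atom[m[, "pdbx_PDB_model_num"] == first_model, , drop = FALSE]
  }
  list(atom = atom)
}

#' Parse an RNA-protein complex structure
#'
#' Reads a PDB or mmCIF file and returns all polymer chains with per-residue
#' atom coordinates. Waters are dropped; HETATM residues with no known
#' parent component (free ions, ligands) are excluded from chain residue
#' lists; modified residues are mapped to their parents and flagged. When a
#' residue has alternate-location conformers only the first is kept.
#'
#' @param path path to the structure file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @return A `complex_record`.
#' @seealso [validate_complex()]
#' @export
parse_complex <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path) || file.size(path) == 0) {
    stop("cannot parse structure file (missing or empty): ", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) {
      # read.cif is beta and rejects some mmCIF dialects; fall back to a
      # generic by-name _atom_site reader
      if (format == "mmcif") {
        tryCatch(.read_mmcif_atoms(path),
                 error = function(e2) stop("failed to parse ", path, ": ",
                                           conditionMessage(e2),
                                           call. = FALSE))
      } else {
        stop("failed to parse ", path, ": ", conditionMessage(e),
             call. = FALSE)
      }
    }
  )
  atom <- parsed$atom
  if (is.null(atom) || nrow(atom) == 0) {
    stop("no atoms found in ", path)
  }

  # drop waters; keep first altloc per (chain, resno, insert, atom name)
  atom <- atom[!(toupper(atom$resid) %in% .water_names), , drop = FALSE]
  ins <- ifelse(is.na(atom$insert) | atom$insert == "", "", atom$insert)
  akey <- paste(atom$chain, atom$resno, ins, atom$elety, sep = "|")
  atom <- atom[!duplicated(akey), , drop = FALSE]
  if (nrow(atom) == 0) stop("no polymer chains found in ", path)

  header <- .read_structure_header(path, format)
  chains <- list()
  for (cid in unique(atom$chain)) {
    ca <- atom[atom$chain == cid, , drop = FALSE]
    ins <- ifelse(is.na(ca$insert) | ca$insert == "", "", ca$insert)
    # author residue order; insertion codes sort after their base number
    rkey <- paste(ca$resno, ins, sep = "|")
    ord <- order(ca$resno, ins)
    ca <- ca[ord, , drop = FALSE]
    rkey <- rkey[ord]
    resno_groups <- unique(rkey)

    info <- lapply(resno_groups, function(k) {
      rows <- which(rkey == k)
      raw <- toupper(ca$resid[rows[1]])
      cls <- .classify_component(raw)
      het <- all(ca$type[rows] == "HETATM")
      list(raw = raw, kind = cls$kind, code = cls$code,
           modified = cls$modified, rows = rows, hetatm = het)
    })
    # exclude HETATM residues with no known parent: ions / ligands
    keep <- vapply(info, function(r) !(r$hetatm && is.na(r$kind)), logical(1))
    info <- info[keep]
    if (!length(info)) next

    kinds <- vapply(info, function(r) r$kind, character(1))
    n_prot <- sum(kinds == "protein", na.rm = TRUE)
    n_rna <- sum(kinds == "rna", na.rm = TRUE)
    kind <- if (n_prot == 0 && n_rna == 0) "other"
            else if (n_prot >= n_rna) "protein" else "rna"
    if (kind == "other") next

    residues <- data.frame(
      chain_position = seq_along(info),
      parent_code = vapply(info, function(r) {
        if (identical(r$kind, kind)) r$code else "unknown"
      }, character(1)),
      raw_code = vapply(info, function(r) r$raw, character(1)),
      is_modified = vapply(info, function(r) isTRUE(r$modified), logical(1)),
      n_atoms = vapply(info, function(r) length(r$rows), integer(1)),
      stringsAsFactors = FALSE
    )
    atoms <- do.call(rbind, lapply(seq_along(info), function(i) {
      rows <- info[[i]]$rows
      data.frame(residue = i, x = ca$x[rows], y = ca$y[rows], z = ca$z[rows])
    }))
    chains[[length(chains) + 1L]] <- new_chain_record(cid, kind, residues, atoms)
  }
  if (!length(chains)) stop("no polymer chains found in ", path)

  src <- toupper(tools::file_path_sans_ext(basename(path)))
  new_complex_record(src, header$resolution, header$method, chains)
}

#' Validate a complex against resolution and chain-length rules
#'
#' Keeps protein chains of at least `min_protein_len` residues and RNA
#' chains of at least `min_rna_len` residues (inclusive bounds). A complex
#' is flagged rejected - not errored - when its resolution exceeds
#' `max_resolution`, when no resolution is recorded (non-crystallographic
#' structures), or when no valid protein or no valid RNA chain remains.
#'
#' @param complex a `complex_record`.
#' @param max_resolution maximum resolution in Angstrom (inclusive).
#' @param min_protein_len minimum protein chain length in residues.
#' @param min_rna_len minimum RNA chain length in residues.
#' @return The complex with invalid chains removed and `rejected` /
#'   `reject_reason` set. Idempotent.
#' @export
validate_complex <- function(complex, max_resolution = 3.0,
                             min_protein_len = 25L, min_rna_len = 15L) {
  stopifnot(inherits(complex, "complex_record"))
  keep <- vapply(complex$chains, function(ch) {
    n <- nrow(ch$residues)
    (ch$kind == "protein" && n >= min_protein_len) ||
      (ch$kind == "rna" && n >= min_rna_len)
  }, logical(1))
  complex$chains <- complex$chains[keep]
  kinds <- vapply(complex$chains, function(ch) ch$kind, character(1))

  if (is.na(complex$resolution)) {
    complex$rejected <- TRUE
    complex$reject_reason <- "no resolution record (not an X-ray crystal structure)"
  } else if (complex$resolution > max_resolution) {
    complex$rejected <- TRUE
    complex$reject_reason <- sprintf("resolution %.2f A exceeds %.2f A",
                                     complex$resolution, max_resolution)
  } else if (!any(kinds == "protein") || !any(kinds == "rna")) {
    complex$rejected <- TRUE
    complex$reject_reason <- "absence of any valid RNA or protein chain"
  } else {
    complex$rejected <- FALSE
    complex$reject_reason <- NULL
  }
  complex
}

#' Write chain sequences as FASTA
#'
#' Emits one record per chain with modified residues already mapped to their
#' parent codes (unknowns as `X`).
#'
#' @param complex a `complex_record`.
#' @param path output FASTA path.
#' @param kind optionally restrict to `"protein"` or `"rna"` chains.
#' @return Invisibly, the named character vector written.
#' @export
write_chain_fasta <- function(complex, path, kind = NULL) {
  chains <- complex$chains
  if (!is.null(kind)) {
    chains <- Filter(function(ch) ch$kind == kind, chains)
  }
  seqs <- vapply(chains, chain_sequence, character(1))
  names(seqs) <- vapply(chains, function(ch)
    paste0(complex$source_id, "_", ch$chain_id), character(1))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(seqs)
}
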