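#' Standard 20-letter amino-acid alphabet
#'
#' One-letter codes in alphabetical order. One-hot encodings, relaxed
#' sequence matrices and mutation counts all index rows by this vector
#' unless a different alphabet is supplied.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a C-alpha trace
#'
#' The basic unit of structure: an amino-acid sequence together with the
#' 3D coordinates of its alpha-carbon atoms, one row per residue, in
#' Angstrom. Discrete curvature/torsion need four points, so at least four
#' residues are required.
#'
#' @param sequence Single string over the amino-acid alphabet.
#' @param coords Numeric n x 3 matrix of C-alpha positions (Angstrom).
#' @param id Free-text label.
#' @return An object of class `ca_trace` with elements `sequence`,
#'   `coords`, `id`.
#' @examples
#' tr <- ca_trace("ACDE", matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0, 11.4, 0, 0),
#'                               ncol = 3, byrow = TRUE))
#' tr
#' @export
ca_trace <- function(sequence, coords, id = "trace") {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("`sequence` must be a single string")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nchar(sequence)
  if (ncol(coords) != 3L)
    stop("`coords` must have 3 columns (x, y, z)")
  if (nrow(coords) != n)
    stop(sprintf("coordinate rows (%d) must match sequence length (%d)",
                 nrow(coords), n))
  if (n < 4L)
    stop("a trace needs at least 4 residues")
  if (any(!is.finite(coords)))
    stop("non-finite coordinates in trace")
  structure(list(sequence = sequence, coords = unname(coords), id = id),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  n <- nchar(x$sequence)
  cat(sprintf("C-alpha trace '%s': %d residues\n", x$id, n))
  s <- x$sequence
  if (n > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("  sequence: ", s, "\n", sep = "")
  invisible(x)
}

#' @export
length.ca_trace <- function(x) nchar(x$sequence)

trace_coords <- function(x) {
  if (inherits(x, "ca_trace")) x$coords else as.matrix(x)
}

split_sequence <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

#' One-hot encode a sequence
#'
#' @param sequence A string or character vector of residue letters.
#' @param alphabet Row alphabet (default the 20 standard amino acids).
#' @return k x n binary matrix with rownames `alphabet`; each column sums
#'   to 1.
#' @export
sequence_onehot <- function(sequence, alphabet = AA_ALPHABET) {
  letters_ <- if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
    split_sequence(sequence) else as.character(sequence)
  idx <- match(letters_, alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("residue '%s' at position %d is not in the alphabet",
                 letters_[bad], bad))
  }
  S <- matrix(0, nrow = length(alphabet), ncol = length(letters_),
              dimnames = list(alphabet, NULL))
  S[cbind(idx, seq_along(idx))] <- 1
  S
}

onehot_sequence <- function(S, alphabet = AA_ALPHABET) {
  paste(alphabet[apply(S, 2, which.max)], collapse = "")
}

#' Read a C-alpha trace from a PDB file
#'
#' Extracts the CA atoms of one chain of (the first model of) a PDB file.
#' Author residue numbering is preserved in the `resno` attribute;
#' internal indexing is positional.
#'
#' @param path PDB file.
#' @param chain Chain identifier; default takes the first chain present.
#' @return A [ca_trace()].
#' @export
read_ca_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  sel <- pdb$atom$elety == "CA"
  if (!is.null(chain)) sel <- sel & pdb$atom$chain %in% chain
  atoms <- pdb$atom[sel, , drop = FALSE]
  if (nrow(atoms) == 0) stop("no CA atoms found in ", path)
  if (is.null(chain)) atoms <- atoms[atoms$chain == atoms$chain[1], , drop = FALSE]
  seq1 <- bio3d::aa321(atoms$resid)
  tr <- ca_trace(paste(seq1, collapse = ""),
                 as.matrix(atoms[, c("x", "y", "z")]),
                 id = basename(path))
  attr(tr, "resno") <- atoms$resno
  tr
}

#' Read a multi-model PDB file as a trajectory ensemble
#'
#' Each MODEL block contributes one frame of CA coordinates.
#'
#' @param path Multi-model PDB file.
#' @param chain Optional chain selection.
#' @return A [trajectory_ensemble()].
#' @export
read_trajectory_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  sel <- pdb$atom$elety == "CA"
  if (!is.null(chain)) sel <- sel & pdb$atom$chain %in% chain
  idx <- which(sel)
  if (length(idx) == 0) stop("no CA atoms found in ", path)
  xyz_cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  frames <- lapply(seq_len(nrow(pdb$xyz)), function(m) {
    matrix(pdb$xyz[m, xyz_cols], ncol = 3, byrow = TRUE)
  })
  trajectory_ensemble(frames)
}

#' Write a (possibly multi-model) C-alpha PDB file
#'
#' Writes plain ATOM records, one MODEL/ENDMDL block per frame when more
#' than one coordinate set is given.
#'
#' @param frames A single n x 3 matrix, a list of them, or a
#'   [trajectory_ensemble()].
#' @param sequence Residue sequence (one-letter codes) for the residue names.
#' @param path Output file.
#' @export
write_ca_pdb <- function(frames, sequence, path) {
  if (inherits(frames, "trajectory_ensemble")) frames <- frames$frames
  if (is.matrix(frames)) frames <- list(frames)
  aa3 <- bio3d::aa123(split_sequence(sequence))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (m in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    X <- frames[[m]]
    lines <- sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(X)), aa3, seq_len(nrow(X)), X[, 1], X[, 2], X[, 3])
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @export
write_fasta_sequences <- function(sequences, path) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
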