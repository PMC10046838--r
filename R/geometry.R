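#' Pairwise C-alpha distance matrix
#'
#' @param trace A [ca_trace()] or an n x 3 coordinate matrix.
#' @return Symmetric n x n matrix of Euclidean distances (Angstrom), zero
#'   diagonal.
#' @export
distance_matrix <- function(trace) {
  X <- trace_coords(trace)
  if (any(!is.finite(X))) stop("non-finite coordinates")
  D <- as.matrix(stats::dist(X))
  dimnames(D) <- NULL
  D
}

#' Gaussian soft adjacency from a distance matrix
#'
#' Dense weighted connectivity `A_ij = exp(-d_ij^2 / kernel_scale^2)` used
#' in place of a binary contact map. The diagonal is forced to zero so the
#' graph has no self-loops.
#'
#' @param dist Symmetric nonnegative distance matrix.
#' @param kernel_scale Kernel width in Angstrom (default 8, a typical
#'   residue contact scale).
#' @return Symmetric matrix with off-diagonal entries in (0, 1].
#' @export
soft_adjacency <- function(dist, kernel_scale = 8) {
  if (!is.numeric(kernel_scale) || length(kernel_scale) != 1L || kernel_scale <= 0)
    stop("`kernel_scale` must be a positive number")
  dist <- as.matrix(dist)
  if (any(dist < 0)) stop("distances must be nonnegative")
  A <- exp(-(dist / kernel_scale)^2)
  diag(A) <- 0
  A
}

#' Graph Laplacian of a weighted adjacency
#'
#' Combinatorial form `L = D - A`, or the degree-normalized form
#' `L = I - D^(-1/2) A D^(-1/2)` (default), whose spectrum lies in
#' `[0, 2]`. An isolated node (zero degree) under the normalized form gets
#' an identity row.
#'
#' @param adj Symmetric nonnegative adjacency with zero diagonal.
#' @param normalized Use the degree-normalized form (default `TRUE`).
#' @param kernel_scale Optional kernel scale (Angstrom) recorded as
#'   metadata when the adjacency came from [soft_adjacency()].
#' @return An object of class `graph_laplacian` with elements `matrix`,
#'   `normalized`, `kernel_scale`.
#' @export
graph_laplacian <- function(adj, normalized = TRUE, kernel_scale = NA_real_) {
  A <- as.matrix(adj)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (max(abs(A - t(A))) > 1e-10) stop("adjacency must be symmetric")
  d <- rowSums(A)
  if (normalized) {
    dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
    L <- diag(nrow(A)) - (dinv * A) %*% diag(dinv)
    L <- (L + t(L)) / 2
  } else {
    L <- diag(d) - A
  }
  structure(list(matrix = L, normalized = normalized,
                 kernel_scale = kernel_scale),
            class = "graph_laplacian")
}

#' @export
print.graph_laplacian <- function(x, ...) {
  cat(sprintf("%s graph Laplacian, %d nodes\n",
              if (x$normalized) "normalized" else "combinatorial",
              nrow(x$matrix)))
  invisible(x)
}

as_laplacian_matrix <- function(L) {
  if (inherits(L, "graph_laplacian")) L$matrix else L
}

#' Soft-adjacency graph Laplacian of a trace
#'
#' Convenience composition of [distance_matrix()], [soft_adjacency()] and
#' [graph_laplacian()].
#'
#' @inheritParams distance_matrix
#' @inheritParams soft_adjacency
#' @inheritParams graph_laplacian
#' @return A `graph_laplacian`.
#' @export
trace_laplacian <- function(trace, kernel_scale = 8, normalized = TRUE) {
  graph_laplacian(soft_adjacency(distance_matrix(trace), kernel_scale),
                  normalized = normalized, kernel_scale = kernel_scale)
}

#' Discrete Frenet-frame features of a C-alpha polyline
#'
#' Per-residue curvature and torsion from finite-difference derivatives of
#' the backbone curve, plus the consecutive C-alpha distance as a third
#' geometric channel. Curvature and torsion are the rotation/translation
#' invariants of a space curve; the finite-difference construction
#' converges to the continuous values as the sampling densifies.
#'
#' Curvature needs one interior neighbour on each side, torsion two;
#' boundary residues are filled with the nearest interior value. A
#' collinear triple has zero curvature, and its (undefined) torsion is set
#' to zero.
#'
#' @param trace A [ca_trace()] or an n x 3 coordinate matrix, n >= 4.
#' @return Object of class `geometric_features`: list of length-n numeric
#'   vectors `curvature` (1/Angstrom, nonnegative), `torsion`
#'   (1/Angstrom), `bond_length` (Angstrom, last value replicated).
#' @export
frenet_features <- function(trace) {
  P <- trace_coords(trace)
  n <- nrow(P)
  if (n < 4L) stop("Frenet features need at least 4 points")
  curvature <- numeric(n)
  torsion <- numeric(n)

  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  for (i in 2:(n - 1)) {
    d1 <- (P[i + 1, ] - P[i - 1, ]) / 2
    d2 <- P[i + 1, ] - 2 * P[i, ] + P[i - 1, ]
    cr <- cross3(d1, d2)
    n1 <- sqrt(sum(d1^2))
    ncr <- sqrt(sum(cr^2))
    curvature[i] <- if (n1 > 0) ncr / n1^3 else 0
    if (i >= 3 && i <= n - 2) {
      d3 <- (P[i + 2, ] - 2 * P[i + 1, ] + 2 * P[i - 1, ] - P[i - 2, ]) / 2
      torsion[i] <- if (ncr > 1e-12) sum(cr * d3) / ncr^2 else 0
    }
  }
  curvature[1] <- curvature[2]
  curvature[n] <- curvature[n - 1]
  torsion[c(1, 2)] <- torsion[3]
  torsion[c(n - 1, n)] <- torsion[n - 2]

  steps <- P[-1, , drop = FALSE] - P[-n, , drop = FALSE]
  bond <- sqrt(rowSums(steps^2))
  bond <- c(bond, bond[n - 1])

  structure(list(curvature = curvature, torsion = torsion,
                 bond_length = bond),
            class = "geometric_features")
}

#' @export
print.geometric_features <- function(x, ...) {
  cat(sprintf("geometric features for %d residues\n", length(x$curvature)))
  cat(sprintf("  curvature: mean %.3f 1/A, torsion: mean %.3f 1/A, bond: mean %.3f A\n",
              mean(x$curvature), mean(x$torsion), mean(x$bond_length)))
  invisible(x)
}

standardize_rows <- function(M) {
  t(apply(M, 1, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12) v - mean(v) else (v - mean(v)) / s
  }))
}

#' Build the per-residue feature matrix
#'
#' Stacks the one-hot sequence block over the three geometric channels
#' (curvature, torsion, bond length). Geometric channels are standardized
#' per protein (zero mean, unit variance per channel) so sequence and
#' geometry rows share scale; a constant channel is centred to zero.
#'
#' @param trace A [ca_trace()].
#' @param geo Optional precomputed [frenet_features()]; computed from the
#'   trace when missing.
#' @param alphabet Alphabet for the one-hot block.
#' @param standardize Standardize the geometric rows (default `TRUE`).
#' @return (k+3) x n numeric matrix; with the default alphabet, 23 rows.
#' @export
build_features <- function(trace, geo = NULL, alphabet = AA_ALPHABET,
                           standardize = TRUE) {
  if (is.null(geo)) geo <- frenet_features(trace)
  n <- length(trace)
  if (length(geo$curvature) != n)
    stop("geometric features and trace have different lengths")
  S <- sequence_onehot(trace$sequence, alphabet)
  G <- rbind(curvature = geo$curvature,
             torsion = geo$torsion,
             bond_length = geo$bond_length)
  if (standardize) G <- standardize_rows(G)
  rbind(S, G)
}

#' Standardized geometric feature rows of a trace
#'
#' The 3 x n geometric block of [build_features()], reused across designs
#' that share a target structure.
#'
#' @inheritParams build_features
#' @return 3 x n matrix with rows curvature, torsion, bond_length.
#' @export
geometry_rows <- function(trace, geo = NULL, standardize = TRUE) {
  if (is.null(geo)) geo <- frenet_features(trace)
  G <- rbind(curvature = geo$curvature,
             torsion = geo$torsion,
             bond_length = geo$bond_length)
  if (standardize) G <- standardize_rows(G)
  G
}

#' Write a feature matrix to CSV
#'
#' @param features (k+3) x n matrix from [build_features()].
#' @param path Output CSV; one row per residue, one named column per
#'   channel plus a residue index column.
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(residue = seq_len(ncol(features)), t(features),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
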