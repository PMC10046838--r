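#' Construct a trajectory ensemble
#'
#' A list of coordinate frames (n x 3 matrices, Angstrom) from a
#' simulation, optionally with a per-residue energy vector per frame
#' (kcal/mol) and frame timestamps (ns).
#'
#' @param frames List of n x 3 coordinate matrices sharing n.
#' @param frame_energies Optional list of length-n energy vectors, one per
#'   frame.
#' @param times Optional numeric timestamps, one per frame.
#' @return Object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(frames, frame_energies = NULL, times = NULL) {
  if (!is.list(frames) || length(frames) == 0)
    stop("`frames` must be a non-empty list of coordinate matrices")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 3L) stop("each frame must be an n x 3 matrix")
    unname(f)
  })
  n <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, 1L) != n))
    stop("all frames must share the same number of residues")
  if (!is.null(frame_energies)) {
    if (length(frame_energies) != length(frames))
      stop("`frame_energies` must have one vector per frame")
    if (any(vapply(frame_energies, length, 1L) != n))
      stop("each energy vector must have one entry per residue")
  }
  if (!is.null(times) && length(times) != length(frames))
    stop("`times` must have one entry per frame")
  structure(list(frames = frames, frame_energies = frame_energies,
                 times = times),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory ensemble: %d frames x %d residues%s\n",
              length(x$frames), nrow(x$frames[[1]]),
              if (is.null(x$frame_energies)) "" else ", with energies"))
  invisible(x)
}

#' @export
length.trajectory_ensemble <- function(x) length(x$frames)

#' Subsample trajectory frames at regular intervals
#'
#' Keeps `count` frames taken at regular index intervals and always
#' including the final frame, mirroring the extraction of a fixed number
#' of coordinate sets from a production run. If the trajectory has fewer
#' frames than requested, all frames are returned with a warning.
#'
#' @param traj A [trajectory_ensemble()].
#' @param count Number of frames to retain (default 50).
#' @return A `trajectory_ensemble` with `count` frames.
#' @export
subsample_frames <- function(traj, count = 50) {
  nf <- length(traj$frames)
  if (nf < count) {
    warning(sprintf("trajectory has %d frames, fewer than the %d requested; returning all",
                    nf, count))
    return(traj)
  }
  idx <- round(seq(nf / count, nf, length.out = count))
  trajectory_ensemble(traj$frames[idx],
                      frame_energies = if (!is.null(traj$frame_energies))
                        traj$frame_energies[idx],
                      times = if (!is.null(traj$times)) traj$times[idx])
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Rigidly transforms `frame` (rotation plus translation, no reflection)
#' to minimize the sum of squared distances to `target`.
#'
#' @param frame,target n x 3 coordinate matrices, n >= 3.
#' @return The transformed copy of `frame`.
#' @export
superpose <- function(frame, target) {
  P <- as.matrix(frame); Q <- as.matrix(target)
  if (!all(dim(P) == dim(Q))) stop("frame and target must have equal shapes")
  if (nrow(P) < 3L) stop("superposition needs at least 3 points")
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(P0 %*% t(R), 2, qc, "+")
}

#' Summarize a trajectory against a target structure
#'
#' Reduces a multi-frame ensemble (plus optional per-frame per-residue
#' energies) to the two design quantities: the time-averaged deviation of
#' each residue from the target fold and the time-averaged per-residue
#' energy. The time integral is realized as a uniform average over the
#' retained frames. Frames are superposed onto the target by default
#' before deviations are measured.
#'
#' @param traj A [trajectory_ensemble()].
#' @param target A [ca_trace()] or n x 3 matrix; the target fold.
#' @param align Superpose each frame onto the target first (default
#'   `TRUE`).
#' @return Object of class `trajectory_summary`: `per_residue_rmsd`
#'   (Angstrom), `per_residue_energy` (kcal/mol, `NULL` when the ensemble
#'   carries no energies, with attribute `has_energy`), `rmsd_total`,
#'   `energy_total`, `n_frames`.
#' @export
summarize_trajectory <- function(traj, target, align = TRUE) {
  X <- trace_coords(target)
  n <- nrow(X)
  if (nrow(traj$frames[[1]]) != n)
    stop("frame shape does not match target")
  sq <- matrix(0, nrow = length(traj$frames), ncol = n)
  for (t in seq_along(traj$frames)) {
    Ft <- traj$frames[[t]]
    if (align) Ft <- superpose(Ft, X)
    sq[t, ] <- rowSums((Ft - X)^2)
  }
  per_residue_rmsd <- sqrt(colMeans(sq))
  rmsd_total <- sqrt(mean(sq))
  has_energy <- !is.null(traj$frame_energies)
  if (has_energy) {
    E <- do.call(rbind, traj$frame_energies)
    per_residue_energy <- colMeans(E)
    energy_total <- sum(per_residue_energy)
  } else {
    per_residue_energy <- NULL
    energy_total <- NA_real_
  }
  structure(list(per_residue_rmsd = per_residue_rmsd,
                 per_residue_energy = per_residue_energy,
                 rmsd_total = rmsd_total,
                 energy_total = energy_total,
                 n_frames = length(traj$frames),
                 has_energy = has_energy),
            class = "trajectory_summary")
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat(sprintf("trajectory summary over %d frames, %d residues\n",
              x$n_frames, length(x$per_residue_rmsd)))
  cat(sprintf("  rmsd_total: %.3f A\n", x$rmsd_total))
  if (x$has_energy)
    cat(sprintf("  energy_total: %.3f kcal/mol\n", x$energy_total))
  else cat("  (no energies recorded)\n")
  invisible(x)
}

#' Read per-frame per-residue energies from CSV
#'
#' Expects columns `frame`, `residue_index`, `energy` (1-based indices).
#'
#' @param path CSV file.
#' @return List of per-residue energy vectors, one per frame.
#' @export
read_energies_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "residue_index", "energy")
  if (!all(need %in% names(df)))
    stop("energy CSV needs columns: ", paste(need, collapse = ", "))
  frames <- sort(unique(df$frame))
  lapply(frames, function(f) {
    sub <- df[df$frame == f, ]
    sub$energy[order(sub$residue_index)]
  })
}

#' Write per-frame per-residue energies to CSV
#'
#' @param frame_energies List of per-residue energy vectors.
#' @param path Output CSV.
#' @export
write_energies_csv <- function(frame_energies, path) {
  n <- length(frame_energies[[1]])
  df <- data.frame(
    frame = rep(seq_along(frame_energies), each = n),
    residue_index = rep(seq_len(n), times = length(frame_energies)),
    energy = unlist(frame_energies))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory summary to CSV
#'
#' @param summary A [summarize_trajectory()] result.
#' @param path Output CSV (per-residue rows; totals in a comment-free
#'   trailing row with residue 0).
#' @export
write_summary_csv <- function(summary, path) {
  n <- length(summary$per_residue_rmsd)
  df <- data.frame(residue = seq_len(n),
                   rmsd = summary$per_residue_rmsd,
                   energy = if (summary$has_energy) summary$per_residue_energy
                            else NA_real_)
  df <- rbind(df, data.frame(residue = 0, rmsd = summary$rmsd_total,
                             energy = summary$energy_total))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
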