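#' Define a synthetic molecular-dynamics world
#'
#' A seeded ground-truth model that emulates, at desk scale, the kind of
#' training data an explicit-solvent simulation pipeline would produce:
#' per-residue binding-energy decompositions with sequence-dependent mean
#' and a fluctuating structural ensemble whose per-residue amplitude
#' grows with that residue's energy. The energy model is a
#' distance-kernel pairwise field over the alphabet,
#' `e_i = a[s_i] + sum_{j != i} exp(-d_ij^2 / scale^2) * W[s_i, s_j]`,
#' rich enough that the graph surrogate is the right function class yet
#' simple enough for exact oracles.
#'
#' @param seed Seed for drawing the world parameters (recorded).
#' @param alphabet Residue alphabet.
#' @param letter_energies Optional k-vector of per-letter energies
#'   (kcal/mol); default drawn uniformly in `[-5, 5]`.
#' @param coupling Optional symmetric k x k pairwise coupling matrix
#'   (kcal/mol); default Gaussian with unit scale, symmetrized.
#' @param kernel_scale Distance-kernel width (Angstrom; default 8,
#'   matching the surrogate's soft adjacency).
#' @param base_amplitude Baseline per-residue fluctuation (Angstrom).
#' @param sensitivity Strength of the energy-to-fluctuation coupling;
#'   0 makes the two target channels statistically independent.
#' @param noise_sd Observation noise on per-frame per-residue energies
#'   (kcal/mol).
#' @return Object of class `synthetic_world`.
#' @export
synthetic_world <- function(seed = 1, alphabet = AA_ALPHABET,
                            letter_energies = NULL, coupling = NULL,
                            kernel_scale = 8, base_amplitude = 0.8,
                            sensitivity = 0.8, noise_sd = 0.3) {
  k <- length(alphabet)
  set.seed(seed)
  if (is.null(letter_energies))
    letter_energies <- stats::runif(k, -5, 5)
  if (is.null(coupling)) {
    W <- matrix(stats::rnorm(k * k), k, k)
    coupling <- (W + t(W)) / 2
  }
  if (max(abs(coupling - t(coupling))) > 1e-12)
    stop("coupling matrix must be symmetric")
  if (base_amplitude <= 0) stop("fluctuation amplitude must be positive")
  # world-level energy normalization for the fluctuation model: a
  # residue's amplitude depends on its own energy on a fixed scale
  e_center <- mean(letter_energies)
  e_scale <- 2 * stats::sd(letter_energies) + 1e-12
  structure(list(seed = seed, alphabet = alphabet,
                 letter_energies = letter_energies, coupling = coupling,
                 kernel_scale = kernel_scale,
                 base_amplitude = base_amplitude,
                 sensitivity = sensitivity, noise_sd = noise_sd,
                 e_center = e_center, e_scale = e_scale),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "synthetic MD world (seed %d): %d letters, kernel %.1f A, base amplitude %.2f A\n",
    x$seed, length(x$alphabet), x$kernel_scale, x$base_amplitude))
  invisible(x)
}

#' Generate a target backbone
#'
#' `helix` builds an ideal alpha-helical C-alpha curve (radius 2.3 A,
#' rise 1.5 A per residue, 100 degrees per residue); `random_smooth`
#' builds a seeded smoothed random walk with consecutive C-alpha
#' distances of 3.8 +/- 0.1 A. The placeholder sequence is poly-alanine.
#'
#' @param n Number of residues (>= 4).
#' @param kind `"helix"` or `"random_smooth"`.
#' @param seed Seed for the random walk.
#' @return A [ca_trace()].
#' @export
make_target <- function(n, kind = c("helix", "random_smooth"), seed = 1) {
  kind <- match.arg(kind)
  if (n < 4) stop("a target needs at least 4 residues")
  if (kind == "helix") {
    theta <- (seq_len(n) - 1) * 100 * pi / 180
    coords <- cbind(2.3 * cos(theta), 2.3 * sin(theta),
                    (seq_len(n) - 1) * 1.5)
  } else {
    set.seed(seed)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    coords <- matrix(0, n, 3)
    for (i in 2:n) {
      dir <- dir + stats::rnorm(3, sd = 0.35)
      dir <- dir / sqrt(sum(dir^2))
      step <- stats::runif(1, 3.7, 3.9)
      coords[i, ] <- coords[i - 1, ] + step * dir
    }
  }
  ca_trace(paste(rep("A", n), collapse = ""), coords,
           id = sprintf("%s_%d", kind, n))
}

#' Ground-truth per-residue energy
#'
#' The synthetic analogue of a per-residue decomposition of the average
#' binding energy: a per-letter term plus distance-kernel-weighted
#' pairwise couplings over the structure. Deterministic.
#'
#' @param sequence Sequence string over the world's alphabet.
#' @param trace A [ca_trace()] or coordinate matrix supplying the
#'   geometry.
#' @param world A [synthetic_world()].
#' @return Length-n energy vector (kcal/mol).
#' @export
true_energy <- function(sequence, trace, world) {
  letters_ <- split_sequence(sequence)
  idx <- match(letters_, world$alphabet)
  if (anyNA(idx)) stop("sequence contains letters outside the world alphabet")
  D <- distance_matrix(trace)
  if (nrow(D) != length(idx))
    stop("sequence and trace have different lengths")
  K <- exp(-(D / world$kernel_scale)^2)
  diag(K) <- 0
  world$letter_energies[idx] +
    rowSums(K * world$coupling[idx, idx, drop = FALSE])
}

residue_sigmas <- function(e, world) {
  z <- (e - world$e_center) / world$e_scale
  sig <- world$base_amplitude * (1 + world$sensitivity * z)
  if (any(sig <= 0)) {
    warning("fluctuation amplitude clipped to 0.05 A for some residues")
    sig <- pmax(sig, 0.05)
  }
  sig
}

#' Ground-truth expected per-residue deviation
#'
#' The expected per-residue RMSD of [simulate_trajectory()] in the
#' many-frame limit: `sqrt(3) * sigma_i` for isotropic Gaussian
#' displacements with per-residue amplitude `sigma_i`.
#'
#' @inheritParams true_energy
#' @return Length-n vector (Angstrom).
#' @export
true_deviation <- function(sequence, trace, world) {
  sqrt(3) * residue_sigmas(true_energy(sequence, trace, world), world)
}

#' Simulate a fluctuating trajectory around a target
#'
#' Each frame displaces every residue of the target by isotropic
#' Gaussian noise whose standard deviation grows with the residue's
#' (normalized) ground-truth energy, so high-energy residues fluctuate
#' more and the energy and deviation channels are correlated but not
#' identical. Per-frame per-residue energies are the ground truth plus
#' seeded observation noise.
#'
#' @param sequence Sequence string.
#' @param target Target [ca_trace()].
#' @param world A [synthetic_world()].
#' @param frames Number of frames (>= 2; default 50).
#' @param seed Seed for this trajectory.
#' @return A [trajectory_ensemble()] with energies.
#' @export
simulate_trajectory <- function(sequence, target, world, frames = 50,
                                seed = 1) {
  if (frames < 2) stop("need at least 2 frames")
  X <- trace_coords(target)
  n <- nrow(X)
  e <- true_energy(sequence, target, world)
  sig <- residue_sigmas(e, world)
  set.seed(seed)
  fr <- vector("list", frames)
  en <- vector("list", frames)
  for (t in seq_len(frames)) {
    fr[[t]] <- X + matrix(stats::rnorm(3 * n, sd = rep(sig, 3)), n, 3)
    en[[t]] <- e + stats::rnorm(n, sd = world$noise_sd)
  }
  trajectory_ensemble(fr, frame_energies = en,
                      times = seq_len(frames) * 0.1)
}

#' Generate a synthetic training dataset
#'
#' Draws random sequences on a shared target backbone, simulates each
#' one with [simulate_trajectory()] and reduces it with
#' [summarize_trajectory()] — the desk-scale emulation of a corpus of
#' simulated designs, 50 coordinate snapshots per design by default. The
#' manifest records everything needed to regenerate the dataset
#' bit-exactly.
#'
#' @param n_designs Number of designs.
#' @param n_residues Residues per design (default 25).
#' @param world A [synthetic_world()].
#' @param frames Frames per trajectory (default 50).
#' @param kind Target backbone kind (see [make_target()]).
#' @param seed Master seed; per-design seeds are derived from it.
#' @param align Superpose frames before summarizing. The generator adds
#'   no rigid-body drift, so the faithful reduction is the unaligned one
#'   (default `FALSE`); real trajectories should keep alignment on.
#' @return Object of class `synthetic_dataset` with elements `target`,
#'   `examples` (each: `trace`, `ensemble`, `summary`), `world`,
#'   `manifest`.
#' @export
make_dataset <- function(n_designs, n_residues = 25, world,
                         frames = 50, kind = "random_smooth", seed = 1,
                         align = FALSE) {
  target <- make_target(n_residues, kind, seed = seed)
  set.seed(seed)
  k <- length(world$alphabet)
  seqs <- replicate(n_designs, paste(
    sample(world$alphabet, n_residues, replace = TRUE), collapse = ""))
  traj_seeds <- sample.int(.Machine$integer.max %/% 2, n_designs)
  examples <- lapply(seq_len(n_designs), function(i) {
    tr <- ca_trace(seqs[i], target$coords, id = sprintf("design_%03d", i))
    ens <- simulate_trajectory(seqs[i], target, world, frames = frames,
                               seed = traj_seeds[i])
    list(trace = tr, ensemble = ens,
         summary = summarize_trajectory(ens, target, align = align))
  })
  manifest <- list(seed = seed, n_designs = n_designs,
                   n_residues = n_residues, frames = frames, kind = kind,
                   align = align, world_seed = world$seed,
                   world = list(letter_energies = world$letter_energies,
                                kernel_scale = world$kernel_scale,
                                base_amplitude = world$base_amplitude,
                                sensitivity = world$sensitivity,
                                noise_sd = world$noise_sd))
  structure(list(target = target, examples = examples, world = world,
                 manifest = manifest),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic dataset: %d designs x %d residues, %d frames each\n",
              length(x$examples), length(x$target),
              length(x$examples[[1]]$ensemble$frames)))
  invisible(x)
}

#' Convert a synthetic dataset to surrogate training examples
#'
#' Builds, for each design, the feature matrix (one-hot block over the
#' shared target geometry), the shared soft-adjacency Laplacian, and the
#' 2 x n target matrix (per-residue energy; per-residue deviation).
#'
#' @param dataset A [make_dataset()] result.
#' @param kernel_scale,normalized Laplacian construction parameters.
#' @return List of labeled examples for [fit_surrogate()], with the
#'   shared `laplacian` and `geo_rows` as attributes.
#' @export
as_training_data <- function(dataset, kernel_scale = 8, normalized = TRUE) {
  target <- dataset$target
  L <- trace_laplacian(target, kernel_scale = kernel_scale,
                       normalized = normalized)
  geo <- geometry_rows(target)
  out <- lapply(dataset$examples, function(ex) {
    S <- sequence_onehot(ex$trace$sequence, dataset$world$alphabet)
    list(features = rbind(S, geo), laplacian = L,
         targets = rbind(ex$summary$per_residue_energy,
                         ex$summary$per_residue_rmsd))
  })
  attr(out, "laplacian") <- L
  attr(out, "geo_rows") <- geo
  attr(out, "target") <- target
  out
}

#' Write a synthetic dataset to disk
#'
#' One multi-model PDB, one energy CSV and one summary CSV per design,
#' plus sequences as FASTA and a JSON manifest.
#'
#' @param dataset A [make_dataset()] result.
#' @param dir Output directory (created).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- character(length(dataset$examples))
  for (i in seq_along(dataset$examples)) {
    ex <- dataset$examples[[i]]
    stem <- file.path(dir, sprintf("design_%03d", i))
    write_ca_pdb(ex$ensemble, ex$trace$sequence, paste0(stem, ".pdb"))
    write_energies_csv(ex$ensemble$frame_energies,
                       paste0(stem, "_energies.csv"))
    write_summary_csv(ex$summary, paste0(stem, "_summary.csv"))
    seqs[i] <- ex$trace$sequence
  }
  names(seqs) <- sprintf("design_%03d", seq_along(seqs))
  write_fasta_sequences(seqs, file.path(dir, "sequences.fasta"))
  write_ca_pdb(dataset$target$coords, dataset$target$sequence,
               file.path(dir, "target.pdb"))
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Regenerate a dataset from its manifest
#'
#' @param manifest Manifest list (or path to a manifest JSON).
#' @return A `synthetic_dataset` bit-identical to the original.
#' @export
dataset_from_manifest <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  world <- synthetic_world(seed = manifest$world_seed,
                           kernel_scale = manifest$world$kernel_scale,
                           base_amplitude = manifest$world$base_amplitude,
                           sensitivity = manifest$world$sensitivity,
                           noise_sd = manifest$world$noise_sd)
  make_dataset(manifest$n_designs, manifest$n_residues, world,
               frames = manifest$frames, kind = manifest$kind,
               seed = manifest$seed, align = manifest$align)
}
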