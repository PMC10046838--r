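#' Design optimizer configuration
#'
#' Parameters of the projected-gradient sequence design loop and its
#' batch driver.
#'
#' @param mu Step size on the (standardized) objective; default 0.1.
#' @param niter Maximum iterations per design.
#' @param delta_stab Acceptable structural deviation (Angstrom) before
#'   the stability penalty activates.
#' @param lambda Stability penalty weight; 0 recovers pure energy
#'   minimization.
#' @param cap Per-design mutation cap (default 10): an iterate whose
#'   discrete sequence exceeds this many mutations from the start is
#'   rejected and the loop exits.
#' @param batch_stop Batch mean-mutation stop (default 5): the batch
#'   driver stops once the mean mutation count across designs reaches
#'   this value.
#' @param fp_tol Fixed-point tolerance on the Frobenius change of the
#'   relaxed matrix.
#' @param perturb_scale Scale of the seeded random perturbation the batch
#'   driver applies to restart a design stuck at a fixed point.
#' @param backtrack Halve the step when a move increases the objective
#'   (up to `max_halvings` times).
#' @param max_halvings Maximum step halvings per iteration.
#' @param max_sweeps Safety bound on round-robin sweeps in
#'   [batch_design()].
#' @param seed Seed for perturbations and start ordering.
#' @return List of class `design_config`.
#' @export
design_config <- function(mu = 0.1, niter = 200, delta_stab = 2,
                          lambda = 1, cap = 10, batch_stop = 5,
                          fp_tol = 1e-8, perturb_scale = 0.1,
                          backtrack = TRUE, max_halvings = 20,
                          max_sweeps = 500, seed = 1) {
  if (mu < 0) stop("`mu` must be nonnegative")
  if (cap < 1 || niter < 1) stop("caps and iteration counts must be positive")
  structure(list(mu = mu, niter = niter, delta_stab = delta_stab,
                 lambda = lambda, cap = cap, batch_stop = batch_stop,
                 fp_tol = fp_tol, perturb_scale = perturb_scale,
                 backtrack = backtrack, max_halvings = max_halvings,
                 max_sweeps = max_sweeps, seed = seed),
            class = "design_config")
}

project_simplex_column <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Project onto the feasible relaxed-sequence set
#'
#' Euclidean projection of each column onto the probability simplex
#' (entries in `[0, 1]`, column sums 1) by sort-and-threshold: each
#' column becomes `max(v - theta, 0)` for the unique threshold `theta`
#' restoring a unit sum. For matrices in this set the squared
#' column-group norm `sum_j sum_i S_ij^2` never exceeds n, so the group
#' sparsity bound holds automatically; it is asserted in tests rather
#' than enforced. The projection is idempotent.
#'
#' @param Sstar Any finite k x n matrix.
#' @return k x n matrix of class `relaxed_sequence` with feasible
#'   columns.
#' @export
project_feasible <- function(Sstar) {
  Sstar <- as.matrix(Sstar)
  if (any(!is.finite(Sstar))) stop("non-finite entries in relaxed matrix")
  out <- apply(Sstar, 2, project_simplex_column)
  dimnames(out) <- dimnames(Sstar)
  class(out) <- c("relaxed_sequence", class(out))
  out
}

#' Discretize a relaxed sequence matrix
#'
#' Per-column argmax letter; ties broken by the lowest alphabet index.
#'
#' @param S Feasible k x n matrix.
#' @param alphabet Row alphabet.
#' @return Sequence string of length n.
#' @export
discretize <- function(S, alphabet = AA_ALPHABET) {
  paste(alphabet[apply(S, 2, which.max)], collapse = "")
}

#' Count mutations between two sequences
#'
#' Hamming distance between equal-length sequences.
#'
#' @param seq,seq0 Sequence strings.
#' @return Integer mutation count.
#' @export
count_mutations <- function(seq, seq0) {
  a <- split_sequence(seq); b <- split_sequence(seq0)
  if (length(a) != length(b)) stop("sequences have different lengths")
  sum(a != b)
}

#' Randomly perturb a relaxed sequence matrix
#'
#' Adds seeded zero-mean Gaussian noise and re-projects, the random
#' exploration move of the design driver.
#'
#' @param S Feasible k x n matrix.
#' @param scale Noise standard deviation (0 returns `S` unchanged).
#' @param seed Optional seed.
#' @return Feasible `relaxed_sequence`.
#' @export
perturb <- function(S, scale, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (scale == 0) return(project_feasible(S))
  project_feasible(S + matrix(stats::rnorm(length(S), sd = scale),
                              nrow(S), ncol(S)))
}

#' Design objective
#'
#' `energy_total(S) + lambda * max(0, stability_total(S) - delta_stab)^2`:
#' the predicted total energy with a soft quadratic penalty on predicted
#' structural deviation beyond the acceptable threshold. With
#' `lambda = 0` this is pure energy minimization.
#'
#' @inheritParams predict_design_metrics
#' @param config A [design_config()] supplying `lambda` and `delta_stab`.
#' @return Scalar objective value.
#' @export
design_objective <- function(model, S, geo_rows, L, config = design_config()) {
  met <- predict_design_metrics(model, S, geo_rows, L)
  met$energy_total +
    config$lambda * max(0, met$stability_total - config$delta_stab)^2
}

design_step <- function(model, S, geo_rows, L, config, mu) {
  g <- gradient_wrt_sequence(model, S, geo_rows, L,
                             lambda = config$lambda,
                             delta_stab = config$delta_stab)
  if (any(!is.finite(g))) stop("non-finite design gradient")
  Snew <- project_feasible(S - mu * g)
  if (config$backtrack) {
    f0 <- design_objective(model, S, geo_rows, L, config)
    f1 <- design_objective(model, Snew, geo_rows, L, config)
    h <- 0
    while (f1 > f0 + 1e-12 && h < config$max_halvings) {
      mu <- mu / 2
      Snew <- project_feasible(S - mu * g)
      f1 <- design_objective(model, Snew, geo_rows, L, config)
      h <- h + 1
    }
  }
  Snew
}

#' Projected-gradient sequence design
#'
#' Iterates a steepest-descent step on the surrogate objective followed
#' by projection onto the feasible set, from a starting (relaxed or
#' one-hot) sequence matrix. Terminates at a fixed point of the
#' projected iteration, when the discrete mutation count would exceed
#' the per-design cap (the offending iterate is rejected, so every
#' returned design respects the cap), or at the iteration limit.
#'
#' @param S0 Starting k x n matrix (projected if not feasible) or a
#'   sequence string.
#' @param model Fitted surrogate.
#' @param geo_rows,L Geometry of the target structure.
#' @param config A [design_config()].
#' @param alphabet Alphabet for discretization.
#' @return Object of class `design_result`: `S` (final relaxed matrix),
#'   `sequence` (discrete design), `start_sequence`, `mutations`,
#'   `termination` (`fixed_point`, `cap_exceeded` or `max_iter`), and a
#'   `trace` data frame (iteration, objective, energy, stability,
#'   mutations).
#' @export
design <- function(S0, model, geo_rows, L, config = design_config(),
                   alphabet = AA_ALPHABET) {
  if (is.character(S0)) S0 <- sequence_onehot(S0, alphabet)
  S <- project_feasible(S0)
  seq0 <- discretize(S, alphabet)
  trace <- data.frame(iteration = integer(), objective = numeric(),
                      energy = numeric(), stability = numeric(),
                      mutations = integer())
  termination <- "max_iter"
  record <- function(i) {
    met <- predict_design_metrics(model, S, geo_rows, L)
    obj <- met$energy_total +
      config$lambda * max(0, met$stability_total - config$delta_stab)^2
    trace[nrow(trace) + 1, ] <<- list(i, obj, met$energy_total,
                                      met$stability_total,
                                      count_mutations(discretize(S, alphabet),
                                                      seq0))
  }
  record(0L)
  for (i in seq_len(config$niter)) {
    mu <- config$mu
    Snew <- design_step(model, S, geo_rows, L, config, mu)
    mc <- count_mutations(discretize(Snew, alphabet), seq0)
    # a single projected step can flip many columns at once; shorten the
    # step before giving up on the cap
    h <- 0
    while (mc > config$cap && h < config$max_halvings) {
      mu <- mu / 2
      Snew <- design_step(model, S, geo_rows, L, config, mu)
      mc <- count_mutations(discretize(Snew, alphabet), seq0)
      h <- h + 1
    }
    if (mc > config$cap) {
      termination <- "cap_exceeded"
      break
    }
    delta <- sqrt(sum((Snew - S)^2))
    S <- Snew
    record(i)
    if (delta <= config$fp_tol) {
      termination <- "fixed_point"
      break
    }
  }
  seq_final <- discretize(S, alphabet)
  structure(list(S = S, sequence = seq_final, start_sequence = seq0,
                 mutations = count_mutations(seq_final, seq0),
                 termination = termination, trace = trace),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("design result: %d mutations, terminated by %s\n",
              x$mutations, x$termination))
  cat("  start:  ", x$start_sequence, "\n", sep = "")
  cat("  design: ", x$sequence, "\n", sep = "")
  last <- utils::tail(x$trace, 1)
  if (nrow(last))
    cat(sprintf("  energy %.3f, stability %.3f after %d iterations\n",
                last$energy, last$stability, last$iteration))
  invisible(x)
}

#' @export
plot.design_result <- function(x, ...) {
  graphics::plot(x$trace$iteration, x$trace$energy, type = "l",
                 xlab = "iteration", ylab = "predicted energy (kcal/mol)",
                 ...)
  invisible(x)
}

# Partially revert a step so the design contributes at most `allowed`
# mutations: newly mutated columns are restored to their previous state,
# weakest (smallest max entry) first.
limit_new_mutations <- function(Snew, Sprev, seq0, allowed, alphabet) {
  s_new <- split_sequence(discretize(Snew, alphabet))
  s0 <- split_sequence(seq0)
  mutated <- which(s_new != s0)
  if (length(mutated) <= allowed) return(Snew)
  strength <- apply(Snew[, mutated, drop = FALSE], 2, max)
  keep <- mutated[order(strength, decreasing = TRUE)][seq_len(allowed)]
  revert <- setdiff(mutated, keep)
  Snew[, revert] <- Sprev[, revert]
  project_feasible(Snew)
}

#' Batch sequence design with a mean-mutation budget
#'
#' Runs the projected-gradient design for a batch of starting sequences
#' in round-robin sweeps: each active design takes one descent step per
#' sweep. The driver maintains a global mutation budget of `batch_stop *
#' n_designs` and stops accepting further mutations once the mean
#' mutation count across designs reaches `batch_stop`; a step that would
#' overshoot the budget is partially reverted so the final total equals
#' the budget exactly. A design stuck at a fixed point while budget
#' remains is restarted with a seeded random perturbation; a design at
#' its per-design cap is frozen.
#'
#' @param starts List (or character vector) of starting sequences or
#'   feasible matrices.
#' @param model Fitted surrogate.
#' @param geo_rows,L Target-structure geometry shared by all designs.
#' @param config A [design_config()].
#' @param alphabet Alphabet for discretization.
#' @return List of class `batch_design_result`: per-design
#'   `design_result`s plus `total_mutations` and `sweeps`.
#' @export
batch_design <- function(starts, model, geo_rows, L,
                         config = design_config(),
                         alphabet = AA_ALPHABET) {
  if (is.character(starts)) starts <- as.list(starts)
  if (length(starts) == 0) stop("need at least one start")
  set.seed(config$seed)
  nd <- length(starts)
  order_ <- sample.int(nd)
  Ss <- lapply(starts, function(s0) {
    if (is.character(s0)) s0 <- sequence_onehot(s0, alphabet)
    project_feasible(s0)
  })
  seq0s <- vapply(Ss, discretize, "", alphabet = alphabet)
  budget <- config$batch_stop * nd
  counts <- integer(nd)
  active <- rep(TRUE, nd)
  iter_counts <- integer(nd)
  sweeps <- 0L
  while (sum(counts) < budget && any(active) && sweeps < config$max_sweeps) {
    sweeps <- sweeps + 1L
    for (d in order_) {
      if (!active[d] || sum(counts) >= budget) next
      Sprev <- Ss[[d]]
      Snew <- tryCatch(design_step(model, Sprev, geo_rows, L, config,
                                   config$mu),
                       error = function(e) NULL)
      if (is.null(Snew)) { active[d] <- FALSE; next }
      iter_counts[d] <- iter_counts[d] + 1L
      if (sqrt(sum((Snew - Sprev)^2)) <= config$fp_tol) {
        if (config$perturb_scale > 0) {
          Snew <- perturb(Sprev, config$perturb_scale)
        } else {
          active[d] <- FALSE
          next
        }
      }
      mc_new <- count_mutations(discretize(Snew, alphabet), seq0s[d])
      if (mc_new > config$cap) {
        # trim the step to the cap (strongest new mutations survive),
        # then freeze the design
        Snew <- limit_new_mutations(Snew, Sprev, seq0s[d], config$cap,
                                    alphabet)
        mc_new <- count_mutations(discretize(Snew, alphabet), seq0s[d])
        active[d] <- FALSE
      }
      remaining <- budget - (sum(counts) - counts[d])
      if (mc_new > remaining) {
        Snew <- limit_new_mutations(Snew, Sprev, seq0s[d], remaining,
                                    alphabet)
        mc_new <- count_mutations(discretize(Snew, alphabet), seq0s[d])
      }
      Ss[[d]] <- Snew
      counts[d] <- mc_new
      if (iter_counts[d] >= config$niter) active[d] <- FALSE
    }
  }
  results <- lapply(seq_len(nd), function(d) {
    met <- predict_design_metrics(model, Ss[[d]], geo_rows, L)
    seq_final <- discretize(Ss[[d]], alphabet)
    structure(list(S = Ss[[d]], sequence = seq_final,
                   start_sequence = seq0s[d],
                   mutations = count_mutations(seq_final, seq0s[d]),
                   termination = if (counts[d] >= config$cap) "cap_exceeded"
                                 else if (sum(counts) >= budget) "batch_stop"
                                 else "fixed_point",
                   energy = met$energy_total,
                   stability = met$stability_total,
                   trace = NULL),
              class = "design_result")
  })
  structure(list(results = results,
                 total_mutations = sum(vapply(results, `[[`, 1L, "mutations")),
                 sweeps = sweeps),
            class = "batch_design_result")
}

#' @export
print.batch_design_result <- function(x, ...) {
  cat(sprintf("batch design: %d designs, %d total mutations (%d sweeps)\n",
              length(x$results), x$total_mutations, x$sweeps))
  invisible(x)
}

#' Projected-gradient design with random restarts
#'
#' Runs [design()] from the given start and from `restarts` perturbed
#' copies, returning the result whose discretized sequence has the best
#' (lowest) objective.
#'
#' @inheritParams design
#' @param restarts Number of perturbed restarts.
#' @param scale Perturbation scale for the restart starting points.
#' @return The best `design_result`.
#' @export
design_restarts <- function(S0, model, geo_rows, L,
                            config = design_config(), restarts = 10,
                            scale = 0.5, alphabet = AA_ALPHABET) {
  if (is.character(S0)) S0 <- sequence_onehot(S0, alphabet)
  S0 <- project_feasible(S0)
  best <- NULL; best_obj <- Inf
  for (r in 0:restarts) {
    Sr <- if (r == 0) S0 else perturb(S0, scale, seed = config$seed + r)
    res <- design(Sr, model, geo_rows, L, config, alphabet)
    obj <- design_objective(model, sequence_onehot(res$sequence, alphabet),
                            geo_rows, L, config)
    if (obj < best_obj) { best_obj <- obj; best <- res }
  }
  best
}
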