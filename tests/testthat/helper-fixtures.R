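# Shared fixtures, all generated in code.

random_trace <- function(n, seed = 1) {
  set.seed(seed)
  # smoothed random walk with realistic consecutive distances
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  P <- matrix(0, n, 3)
  for (i in 2:n) {
    dir <- dir + stats::rnorm(3, sd = 0.4)
    dir <- dir / sqrt(sum(dir^2))
    P[i, ] <- P[i - 1, ] + stats::runif(1, 3.7, 3.9) * dir
  }
  seq_ <- paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
  ca_trace(seq_, P, id = sprintf("random_%d", seed))
}

random_rigid_motion <- function(seed = 1) {
  set.seed(seed)
  A <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(A))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = stats::rnorm(3, sd = 10))
}

apply_rigid <- function(X, motion) {
  sweep(X %*% t(motion$R), 2, motion$t, "+")
}

small_surrogate <- function(c_in = 23, width = 7, depth = 3, seed = 42) {
  gnn_surrogate(input_channels = c_in, width = width, depth = depth,
                seed = seed)
}

# simplex projection by an independent method: bisection on the
# threshold theta such that sum(pmax(v - theta, 0)) == 1
project_simplex_bisect <- function(v, iters = 200) {
  lo <- min(v) - 1
  hi <- max(v)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (sum(pmax(v - mid, 0)) > 1) lo <- mid else hi <- mid
  }
  pmax(v - (lo + hi) / 2, 0)
}
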