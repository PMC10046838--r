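test_that("simplex projection has the known KKT solutions and is idempotent", {
  # already feasible: unchanged
  S <- sequence_onehot("ACD")
  expect_equal(unclass(project_feasible(S)), unclass(S), ignore_attr = TRUE)

  expect_equal(as.vector(project_feasible(matrix(c(2, 0, 0), 3, 1))),
               c(1, 0, 0))
  expect_equal(as.vector(project_feasible(matrix(c(0.6, 0.6, 0), 3, 1))),
               c(0.5, 0.5, 0))

  set.seed(21)
  for (i in 1:25) {
    M <- matrix(rnorm(5 * 7), 5, 7)
    P <- project_feasible(M)
    expect_equal(colSums(P), rep(1, 7), tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1 + 1e-12))
    # idempotent
    expect_equal(unclass(project_feasible(P)), unclass(P),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # group-sparsity bound holds automatically
    expect_lte(sum(P^2), 7 + 1e-12)
    # matches an independent bisection solver per column
    for (j in 1:7)
      expect_equal(P[, j], project_simplex_bisect(M[, j]), tolerance = 1e-8)
  }
  expect_error(project_feasible(matrix(c(1, NA), 2, 1)), "finite")
})

test_that("projection is a contraction toward any feasible point", {
  set.seed(31)
  for (i in 1:20) {
    M <- matrix(rnorm(4 * 6, sd = 2), 4, 6)
    P <- project_feasible(M)
    Y <- project_feasible(matrix(runif(4 * 6), 4, 6))  # a feasible point
    expect_lte(sqrt(sum((P - Y)^2)), sqrt(sum((M - Y)^2)) + 1e-12)
  }
})

test_that("discretization takes the argmax with deterministic ties", {
  S <- sequence_onehot("WAY")
  expect_equal(discretize(S), "WAY")
  expect_equal(discretize(matrix(c(0.5, 0.5), 2, 1), alphabet = c("A", "C")),
               "A")
  set.seed(5)
  S <- project_feasible(matrix(rnorm(20 * 9), 20, 9))
  expected <- paste(AA_ALPHABET[apply(S, 2, function(v)
    which(v == max(v))[1])], collapse = "")
  expect_equal(discretize(S), expected)
})

test_that("mutation counting is the Hamming distance", {
  expect_equal(count_mutations("ACDEF", "ACDEF"), 0)
  expect_equal(count_mutations("ACDEF", "ACDEW"), 1)
  expect_equal(count_mutations("AAAAA", "ACADA"), 2)
  set.seed(9)
  a <- paste(sample(AA_ALPHABET, 30, replace = TRUE), collapse = "")
  b <- paste(sample(AA_ALPHABET, 30, replace = TRUE), collapse = "")
  brute <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(count_mutations(a, b), brute)
  expect_error(count_mutations("ACD", "ACDE"), "length")
})

test_that("perturbation is seeded, feasible, and null at scale 0", {
  S <- project_feasible(matrix(runif(20 * 8), 20, 8))
  expect_equal(unclass(perturb(S, 0)), unclass(S), ignore_attr = TRUE,
               tolerance = 1e-12)
  p1 <- perturb(S, 0.5, seed = 11)
  p2 <- perturb(S, 0.5, seed = 11)
  expect_identical(p1, p2)
  expect_equal(colSums(p1), rep(1, 8), tolerance = 1e-12)
})

test_that("objective applies the soft stability penalty correctly", {
  model <- small_surrogate(seed = 2)
  model$norm_stats <- list(mean = c(0, 1), sd = c(1, 0.5))
  tr <- random_trace(12, seed = 3)
  L <- trace_laplacian(tr)
  geo <- geometry_rows(tr)
  S <- sequence_onehot(tr$sequence)
  met <- predict_design_metrics(model, S, geo, L)

  # inactive penalty: objective equals the energy exactly
  cfg <- design_config(lambda = 2, delta_stab = met$stability_total + 1)
  expect_equal(design_objective(model, S, geo, L, cfg), met$energy_total)
  # lambda = 0: no dependence on delta_stab
  expect_equal(
    design_objective(model, S, geo, L, design_config(lambda = 0, delta_stab = 0)),
    design_objective(model, S, geo, L, design_config(lambda = 0, delta_stab = 5)))
  # closed form one unit above the threshold
  cfg2 <- design_config(lambda = 2, delta_stab = met$stability_total - 1)
  expect_equal(design_objective(model, S, geo, L, cfg2),
               met$energy_total + 2)
})

test_that("zero step size is an immediate fixed point", {
  model <- small_surrogate(seed = 3)
  tr <- random_trace(10, seed = 4)
  res <- design(tr$sequence, model, geometry_rows(tr), trace_laplacian(tr),
                design_config(mu = 0, niter = 10, lambda = 0))
  expect_equal(res$termination, "fixed_point")
  expect_equal(res$sequence, tr$sequence)
  expect_equal(res$mutations, 0)
  expect_equal(max(res$trace$iteration), 1)
})

test_that("descent steps do not increase the objective at small step size", {
  model <- small_surrogate(seed = 6)
  model$norm_stats <- list(mean = c(0, 1), sd = c(1, 0.3))
  tr <- random_trace(12, seed = 7)
  res <- design(tr$sequence, model, geometry_rows(tr), trace_laplacian(tr),
                design_config(mu = 1e-3, niter = 40, lambda = 0,
                              backtrack = FALSE, cap = 12))
  expect_true(all(diff(res$trace$objective) <= 1e-8))
})

test_that("toy design recovers the enumerated global optimum", {
  # k = 3, n = 4: enumerate all 81 sequences as the oracle
  alph <- c("A", "C", "D")
  tr <- random_trace(4, seed = 10)
  L <- trace_laplacian(tr)
  geo <- geometry_rows(tr)
  model <- small_surrogate(c_in = 6, width = 8, depth = 2, seed = 12)
  cfg <- design_config(mu = 0.3, niter = 100, lambda = 0, cap = 4,
                       perturb_scale = 0.3)

  grid <- expand.grid(alph, alph, alph, alph, stringsAsFactors = FALSE)
  all_seqs <- apply(grid, 1, paste, collapse = "")
  objs <- vapply(all_seqs, function(s)
    design_objective(model, sequence_onehot(s, alph), geo, L, cfg), 0)
  best_seq <- all_seqs[which.min(objs)]

  hits <- 0
  for (seed in 1:20) {
    cfg$seed <- seed
    set.seed(seed)
    start <- paste(sample(alph, 4, replace = TRUE), collapse = "")
    res <- design_restarts(start, model, geo, L, cfg, restarts = 15,
                           scale = 0.8, alphabet = alph)
    if (res$sequence == best_seq) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of 20 seeded runs
})

test_that("batch design accounting: mean-mutation budget and zero stop", {
  model <- small_surrogate(seed = 15)
  model$norm_stats <- list(mean = c(0, 1), sd = c(2, 0.3))
  tr <- random_trace(15, seed = 16)
  L <- trace_laplacian(tr); geo <- geometry_rows(tr)
  set.seed(17)
  starts <- replicate(6, paste(sample(AA_ALPHABET, 15, replace = TRUE),
                               collapse = ""))
  cfg <- design_config(mu = 0.5, niter = 100, lambda = 0, cap = 10,
                       batch_stop = 3, seed = 2, perturb_scale = 0.2)
  res <- batch_design(starts, model, geo, L, cfg)
  expect_equal(res$total_mutations, 3 * 6)
  expect_true(all(vapply(res$results, `[[`, 1L, "mutations") <= 10))

  # batch stop 0: nothing mutates
  cfg0 <- design_config(batch_stop = 0, seed = 2)
  res0 <- batch_design(starts, model, geo, L, cfg0)
  expect_equal(res0$total_mutations, 0)
  expect_equal(vapply(res0$results, `[[`, "", "sequence"), unname(starts))

  # single design: batch stop m behaves as a per-design stop
  cfg1 <- design_config(mu = 0.5, niter = 200, lambda = 0, cap = 10,
                        batch_stop = 4, seed = 3, perturb_scale = 0.2)
  res1 <- batch_design(starts[1], model, geo, L, cfg1)
  expect_equal(res1$results[[1]]$mutations, 4)
})

test_that("per-design cap is never exceeded under aggressive steps", {
  model <- small_surrogate(seed = 18)
  model$norm_stats <- list(mean = c(0, 1), sd = c(5, 0.3))
  tr <- random_trace(20, seed = 19)
  L <- trace_laplacian(tr); geo <- geometry_rows(tr)
  set.seed(20)
  for (i in 1:5) {
    start <- paste(sample(AA_ALPHABET, 20, replace = TRUE), collapse = "")
    res <- design(start, model, geo, L,
                  design_config(mu = 5, niter = 100, lambda = 0, cap = 10,
                                backtrack = FALSE))
    expect_lte(res$mutations, 10)
    expect_lte(count_mutations(res$sequence, start), 10)
  }
})
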