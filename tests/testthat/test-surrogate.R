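test_that("parameter count follows the closed form and the flatten oracle", {
  m <- gnn_surrogate(input_channels = 4, width = 1, depth = 1, seed = 1)
  expect_equal(count_parameters(m), 1 * 4 + 1 + 2)
  for (dims in list(c(5, 8, 2), c(23, 16, 5), c(7, 3, 4))) {
    m <- gnn_surrogate(dims[1], dims[2], dims[3], seed = 1)
    flat <- length(m$K0) + sum(lengths(m$hidden)) + length(m$Kout)
    expect_equal(count_parameters(m), flat)
  }
  # doubling the width strictly increases the count
  expect_gt(count_parameters(gnn_surrogate(23, 32, 5, seed = 1)),
            count_parameters(gnn_surrogate(23, 16, 5, seed = 1)))
})

test_that("forward pass matches a hand-unrolled computation", {
  set.seed(30)
  n <- 5; c_in <- 4; s <- 7; N <- 3
  model <- gnn_surrogate(c_in, s, N, seed = 31)
  X <- matrix(rnorm(c_in * n), c_in, n)
  L <- trace_laplacian(random_trace(n, seed = 32))

  out <- surrogate_forward(model, X, L)

  # independent unroll
  lrelu <- function(z) ifelse(z > 0, z, 0.01 * z)
  Y <- model$K0 %*% X
  for (j in 1:N) Y <- Y + lrelu(model$hidden[[j]] %*% Y %*% L$matrix)
  expect_equal(out, model$Kout %*% Y, tolerance = 1e-12)

  # zero weights give zero output
  zm <- model
  zm$K0[] <- 0; zm$Kout[] <- 0
  for (j in 1:N) zm$hidden[[j]][] <- 0
  expect_equal(surrogate_forward(zm, X, L), matrix(0, 2, n))

  # degenerate depth: pure linear map
  m0 <- gnn_surrogate(c_in, s, 0, seed = 33)
  expect_equal(surrogate_forward(m0, X, L), m0$Kout %*% m0$K0 %*% X,
               tolerance = 1e-14)

  expect_error(surrogate_forward(model, X[1:3, ], L), "input channels")
  expect_error(surrogate_forward(model, X[, 1:3], L), "L is")
})

test_that("forward pass is node-permutation equivariant", {
  n <- 8
  tr <- random_trace(n, seed = 40)
  model <- small_surrogate(seed = 41)
  X <- build_features(tr)
  A <- soft_adjacency(distance_matrix(tr), 8)
  L <- graph_laplacian(A)$matrix
  out <- surrogate_forward(model, X, L)
  p <- sample(n)
  out_p <- surrogate_forward(model, X[, p], L[p, p])
  expect_equal(out_p, out[, p], tolerance = 1e-10)
})

test_that("target standardization is exact and invertible", {
  world <- synthetic_world(seed = 3)
  ds <- suppressWarnings(make_dataset(12, n_residues = 10, world = world,
                                      frames = 10, seed = 4))
  td <- as_training_data(ds)
  std <- standardize_targets(td)
  pooled <- do.call(cbind, lapply(std$dataset, `[[`, "targets"))
  expect_equal(rowMeans(pooled), c(0, 0), tolerance = 1e-8)
  expect_equal(apply(pooled, 1, sd), c(1, 1), tolerance = 1e-8)

  # round trip
  back <- pooled * std$norm_stats$sd + std$norm_stats$mean
  orig <- do.call(cbind, lapply(td, `[[`, "targets"))
  expect_equal(back, orig, tolerance = 1e-10)

  # constant channel errors
  degenerate <- lapply(td, function(ex) { ex$targets[2, ] <- 1; ex })
  expect_error(standardize_targets(degenerate), "zero variance")
  expect_error(standardize_targets(td[1]), "at least 2")
})

test_that("sequence gradient matches central finite differences", {
  tr <- random_trace(6, seed = 50)
  model <- small_surrogate(width = 8, depth = 2, seed = 51)
  model$norm_stats <- list(mean = c(0.5, 1.2), sd = c(2, 0.4))
  L <- trace_laplacian(tr); geo <- geometry_rows(tr)
  set.seed(52)
  S <- project_feasible(matrix(runif(20 * 6), 20, 6))

  for (params in list(c(lambda = 0, delta = Inf), c(lambda = 2, delta = 0))) {
    g <- gradient_wrt_sequence(model, S, geo, L, lambda = params[1],
                               delta_stab = params[2])
    obj <- function(Sm) {
      met <- suppressWarnings(predict_design_metrics(model, Sm, geo, L))
      met$energy_total + params[1] * max(0, met$stability_total - params[2])^2
    }
    h <- 1e-5
    fd <- matrix(0, 20, 6)
    for (i in 1:20) for (j in 1:6) {
      Sp <- S; Sp[i, j] <- Sp[i, j] + h
      Sm <- S; Sm[i, j] <- Sm[i, j] - h
      fd[i, j] <- (obj(Sp) - obj(Sm)) / (2 * h)
    }
    expect_lt(max(abs(fd - g)) / max(abs(g)), 1e-4)
  }

  # zero output head: zero gradient
  zm <- model; zm$Kout[] <- 0
  expect_equal(max(abs(gradient_wrt_sequence(zm, S, geo, L, lambda = 0))), 0)

  # lambda = 0: gradient ignores the deviation head entirely
  m2 <- model; m2$Kout[2, ] <- rnorm(8)
  expect_equal(gradient_wrt_sequence(model, S, geo, L, lambda = 0),
               gradient_wrt_sequence(m2, S, geo, L, lambda = 0),
               tolerance = 1e-12)
})

test_that("training learns a realizable linear target and is deterministic", {
  # targets are a fixed linear map of the one-hot features: representable
  set.seed(60)
  c_in <- 23; n <- 10
  Wtrue <- matrix(rnorm(2 * c_in), 2, c_in)
  tr <- random_trace(n, seed = 61)
  L <- trace_laplacian(tr)
  geo <- geometry_rows(tr)
  examples <- lapply(1:60, function(i) {
    s <- paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
    X <- rbind(sequence_onehot(s), geo)
    list(features = X, laplacian = L, targets = Wtrue %*% X)
  })
  cfg <- train_config(epochs = 200, seed = 62, patience = 200,
                      learning_rate = 5e-3, weight_decay = 0)
  fit <- fit_surrogate(examples, width = 16, depth = 2, config = cfg)
  # validation relative error on fresh examples
  set.seed(63)
  err <- num <- 0
  for (i in 1:20) {
    s <- paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
    X <- rbind(sequence_onehot(s), geo)
    pred <- predict(fit, X, L)
    truth <- Wtrue %*% X
    err <- err + sum((pred - truth)^2); num <- num + sum(truth^2)
  }
  expect_lt(sqrt(err / num), 0.05)

  # determinism: identical history under the same seed
  fit2 <- fit_surrogate(examples, width = 16, depth = 2, config = cfg)
  expect_identical(fit$history$val_loss, fit2$history$val_loss)
  expect_identical(fit$K0, fit2$K0)
})

test_that("a single example can be overfitted", {
  tr <- random_trace(8, seed = 70)
  L <- trace_laplacian(tr); geo <- geometry_rows(tr)
  X <- build_features(tr)
  set.seed(71)
  targets <- matrix(rnorm(16), 2, 8)
  ex <- list(features = X, laplacian = L, targets = targets)
  model <- gnn_surrogate(23, 16, 2, seed = 72)
  # bypass standardization: duplicate the example, train on raw targets
  res <- train_surrogate(model, list(ex, ex),
                         train_config(epochs = 400, seed = 73,
                                      patience = 400, learning_rate = 5e-3,
                                      batch_size = 1, val_fraction = 0.5,
                                      weight_decay = 0))
  expect_lt(tail(res$history$train_loss, 1), 1e-3)
})

test_that("training aborts with a diagnostic on divergence", {
  tr <- random_trace(6, seed = 80)
  X <- build_features(tr)
  ex <- list(features = X, laplacian = trace_laplacian(tr),
             targets = matrix(1e150, 2, 6))
  model <- gnn_surrogate(23, 8, 2, seed = 81)
  model$K0 <- model$K0 * 1e160
  expect_error(train_surrogate(model, list(ex, ex),
                               train_config(epochs = 2, patience = 5,
                                            val_fraction = 0.5)),
               "diverged")
})

test_that("design metrics de-normalize and respect equivariance", {
  tr <- random_trace(9, seed = 90)
  L <- trace_laplacian(tr); geo <- geometry_rows(tr)
  S <- sequence_onehot(tr$sequence)

  # zero-weight model predicts the stored channel means
  zm <- gnn_surrogate(23, 8, 2, seed = 91)
  zm$K0[] <- 0; zm$Kout[] <- 0
  for (j in 1:2) zm$hidden[[j]][] <- 0
  zm$norm_stats <- list(mean = c(-3, 1.5), sd = c(2, 0.5))
  met <- predict_design_metrics(zm, S, geo, L)
  expect_equal(met$per_residue[1, ], rep(-3, 9))
  expect_equal(met$per_residue[2, ], rep(1.5, 9))
  expect_equal(met$energy_total, -27)
  expect_equal(met$stability_total, 1.5)

  # permutation equivariance of per-residue outputs
  model <- small_surrogate(seed = 92)
  model$norm_stats <- list(mean = c(0, 0), sd = c(1, 1))
  p <- sample(9)
  Lm <- L$matrix
  m1 <- predict_design_metrics(model, S, geo, L)
  m2 <- predict_design_metrics(model, S[, p], geo[, p], Lm[p, p])
  expect_equal(m2$per_residue, m1$per_residue[, p], tolerance = 1e-10)
  expect_equal(m2$energy_total, m1$energy_total, tolerance = 1e-10)

  expect_warning(predict_design_metrics(model, S * 2, geo, L), "outside")
})

test_that("checkpoint round trip preserves the model exactly", {
  model <- small_surrogate(seed = 95)
  model$norm_stats <- list(mean = c(1, 2), sd = c(3, 4))
  tmp <- tempfile(fileext = ".json")
  write_checkpoint(model, tmp)
  back <- read_checkpoint(tmp)
  expect_equal(back$K0, model$K0, tolerance = 1e-14)
  expect_equal(back$hidden, model$hidden, tolerance = 1e-14)
  expect_equal(back$Kout, model$Kout, tolerance = 1e-14)
  expect_equal(back$norm_stats$mean, model$norm_stats$mean)
  tr <- random_trace(7, seed = 96)
  X <- build_features(tr); L <- trace_laplacian(tr)
  expect_equal(predict(back, X, L), predict(model, X, L), tolerance = 1e-12)
})
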