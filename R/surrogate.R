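#' Construct a residual graph-network surrogate
#'
#' The surrogate maps a (k+3) x n residue feature matrix `X` and an n x n
#' graph Laplacian `L` to a 2 x n output: per-residue binding energy and
#' per-residue structural deviation. The architecture is
#'
#' \deqn{Y_0 = K_0 X, \quad Y_j = Y_{j-1} + \sigma(K_j Y_{j-1} L), \quad
#'       X_{out} = K_{out} Y_N}
#'
#' with a leaky rectifier activation and no bias terms, so the learnable
#' parameter count is exactly `width * input_channels + depth * width^2 +
#' 2 * width`. The default profile (width 512, depth 5, 23 input channels)
#' has 1,323,520 parameters.
#'
#' @param input_channels Rows of the feature matrix (alphabet size + 3
#'   geometric channels; 23 by default).
#' @param width Hidden width s (default 512).
#' @param depth Number of residual graph layers N (default 5).
#' @param leaky_slope Negative-side slope of the leaky rectifier
#'   (default 0.01).
#' @param init_scale Multiplier on the hidden-layer initialization; small
#'   values start the residual chain near the identity.
#' @param seed Optional seed for weight initialization.
#' @return Object of class `gnn_surrogate` with weight matrices `K0`
#'   (s x c), `hidden` (list of N s x s), `Kout` (2 x s), and `norm_stats`
#'   (`NULL` until fitted).
#' @export
gnn_surrogate <- function(input_channels = 23, width = 512, depth = 5,
                          leaky_slope = 0.01, init_scale = 0.1,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  c_in <- input_channels
  rmat <- function(r, c, sd) matrix(stats::rnorm(r * c, sd = sd), r, c)
  model <- list(
    K0 = rmat(width, c_in, sqrt(1 / c_in)),
    hidden = lapply(seq_len(depth), function(j)
      rmat(width, width, init_scale * sqrt(1 / width))),
    Kout = rmat(2, width, sqrt(1 / width)),
    width = width, depth = depth, input_channels = c_in,
    leaky_slope = leaky_slope,
    norm_stats = NULL)
  class(model) <- "gnn_surrogate"
  model
}

#' Count learnable parameters of a surrogate
#'
#' `width * input_channels + depth * width^2 + 2 * width`; the model has
#' no bias terms.
#'
#' @param model A [gnn_surrogate()].
#' @return Integer-valued count (summed over members for an ensemble).
#' @export
count_parameters <- function(model) {
  if (inherits(model, "gnn_ensemble"))
    return(sum(vapply(model$members, count_parameters, 0)))
  s <- model$width
  s * model$input_channels + model$depth * s^2 + 2 * s
}

leaky_relu <- function(Z, slope) {
  pos <- Z > 0
  Z * pos + slope * Z * !pos
}

leaky_relu_grad <- function(Z, slope) {
  (Z > 0) + slope * (Z <= 0)
}

#' Forward pass of the surrogate
#'
#' Evaluates the residual graph network on a feature matrix. `L` may be a
#' [graph_laplacian()], a base matrix, or a sparse `Matrix` (used
#' internally to batch block-diagonal Laplacians).
#'
#' @param model A [gnn_surrogate()].
#' @param X Feature matrix, `input_channels` x n.
#' @param L n x n graph Laplacian.
#' @param keep Keep intermediate activations for backpropagation.
#' @return 2 x n output matrix (standardized target scale), or, with
#'   `keep = TRUE`, a list `out`, `Y`, `Z`, `M`.
#' @export
surrogate_forward <- function(model, X, L, keep = FALSE) {
  L <- as_laplacian_matrix(L)
  if (nrow(X) != model$input_channels)
    stop(sprintf("X has %d rows but the model expects %d input channels",
                 nrow(X), model$input_channels))
  if (ncol(X) != nrow(L))
    stop(sprintf("X has %d columns but L is %d x %d",
                 ncol(X), nrow(L), ncol(L)))
  slope <- model$leaky_slope
  Y <- model$K0 %*% X
  Ys <- if (keep) vector("list", model$depth + 1) else NULL
  Zs <- if (keep) vector("list", model$depth) else NULL
  Ms <- if (keep) vector("list", model$depth) else NULL
  if (keep) Ys[[1]] <- Y
  for (j in seq_len(model$depth)) {
    M <- as.matrix(Y %*% L)
    Z <- model$hidden[[j]] %*% M
    Y <- Y + leaky_relu(Z, slope)
    if (keep) { Ms[[j]] <- M; Zs[[j]] <- Z; Ys[[j + 1]] <- Y }
  }
  out <- as.matrix(model$Kout %*% Y)
  if (!keep) return(out)
  list(out = out, Y = Ys, Z = Zs, M = Ms, X = X, L = L)
}

# Backpropagate an output cotangent through the network.
# Returns weight gradients and the input gradient dX.
surrogate_backward <- function(model, cache, G_out) {
  slope <- model$leaky_slope
  L <- cache$L
  dKout <- G_out %*% t(cache$Y[[model$depth + 1]])
  G <- crossprod(model$Kout, G_out)
  dhidden <- vector("list", model$depth)
  for (j in rev(seq_len(model$depth))) {
    Gz <- G * leaky_relu_grad(cache$Z[[j]], slope)
    dhidden[[j]] <- Gz %*% t(cache$M[[j]])
    G <- G + as.matrix(crossprod(model$hidden[[j]], Gz) %*% Matrix::t(L))
  }
  dK0 <- G %*% t(cache$X)
  dX <- crossprod(model$K0, G)
  list(dK0 = dK0, dhidden = dhidden, dKout = as.matrix(dKout),
       dX = as.matrix(dX))
}

#' Training configuration for the surrogate
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size (examples per gradient step).
#' @param val_fraction Fraction of examples held out for validation, in
#'   (0, 1).
#' @param seed Seed controlling initialization, the split and batch
#'   order; recorded in the training history.
#' @param patience Early-stopping patience on validation loss, in epochs.
#' @param weight_decay Decoupled L2 weight decay per step (AdamW style).
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-3, epochs = 400, batch_size = 64,
                         val_fraction = 0.1, seed = 1, patience = 60,
                         weight_decay = 3e-4) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("`val_fraction` must be in (0, 1)")
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, val_fraction = val_fraction,
                 seed = seed, patience = patience,
                 weight_decay = weight_decay),
            class = "train_config")
}

#' Standardize the target channels of a training set
#'
#' Pools per-residue values across the whole dataset and transforms each
#' target channel (energy; deviation) to zero mean and unit standard
#' deviation. The statistics are returned for the inverse transform and
#' are stored in fitted models.
#'
#' @param dataset List of labeled examples; each a list with elements
#'   `features` ((k+3) x n), `laplacian`, `targets` (2 x n: energy row,
#'   deviation row).
#' @return List with elements `dataset` (standardized) and `norm_stats`
#'   (`mean`, `sd`, each length 2).
#' @export
standardize_targets <- function(dataset) {
  if (length(dataset) < 2) stop("standardization needs at least 2 examples")
  all_t <- do.call(cbind, lapply(dataset, function(ex) ex$targets))
  mu <- rowMeans(all_t)
  sd_ <- apply(all_t, 1, stats::sd)
  if (any(sd_ < 1e-12))
    stop("a target channel has zero variance; cannot standardize")
  dataset <- lapply(dataset, function(ex) {
    ex$targets <- (ex$targets - mu) / sd_
    ex
  })
  list(dataset = dataset, norm_stats = list(mean = mu, sd = sd_))
}

# Stack a set of examples into one wide problem: features side by side,
# Laplacians block-diagonal (sparse). All network ops are column-local up
# to L, so this is exact.
stack_examples <- function(examples) {
  X <- do.call(cbind, lapply(examples, function(ex) ex$features))
  T_ <- do.call(cbind, lapply(examples, function(ex) ex$targets))
  L <- Matrix::bdiag(lapply(examples, function(ex)
    as_laplacian_matrix(ex$laplacian)))
  list(X = X, targets = T_, L = L)
}

batch_loss_grad <- function(model, stacked) {
  cache <- surrogate_forward(model, stacked$X, stacked$L, keep = TRUE)
  resid <- cache$out - stacked$targets
  loss <- mean(resid^2)
  if (!is.finite(loss)) stop("training diverged: non-finite loss")
  G_out <- 2 * resid / length(resid)
  grads <- surrogate_backward(model, cache, G_out)
  list(loss = loss, grads = grads)
}

batch_loss <- function(model, stacked) {
  out <- surrogate_forward(model, stacked$X, stacked$L)
  mean((out - stacked$targets)^2)
}

#' Train a surrogate on standardized examples
#'
#' Minimizes the mean squared per-node error between the network output
#' and the standardized (energy, deviation) targets with the Adam
#' optimizer, early-stopping on validation loss. Fully deterministic
#' given the config seed.
#'
#' @param model A [gnn_surrogate()].
#' @param dataset Standardized examples (see [standardize_targets()]).
#' @param config A [train_config()].
#' @return List with the trained `model` (best validation weights) and a
#'   `history` data frame (`epoch`, `train_loss`, `val_loss`) carrying the
#'   seed as an attribute.
#' @export
train_surrogate <- function(model, dataset, config = train_config()) {
  set.seed(config$seed)
  m <- length(dataset)
  n_val <- max(1L, round(config$val_fraction * m))
  val_idx <- sample.int(m, n_val)
  train_idx <- setdiff(seq_len(m), val_idx)
  if (length(train_idx) == 0) stop("no training examples left after split")

  batches <- split(sample(train_idx),
                   ceiling(seq_along(train_idx) / config$batch_size))
  stacked_batches <- lapply(batches, function(ix) stack_examples(dataset[ix]))
  stacked_train <- stack_examples(dataset[train_idx])
  stacked_val <- stack_examples(dataset[val_idx])

  # Adam state, one slot per weight matrix
  zero_like <- function(w) w * 0
  mstate <- list(K0 = zero_like(model$K0),
                 hidden = lapply(model$hidden, zero_like),
                 Kout = zero_like(model$Kout))
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L

  wd <- config$weight_decay %||% 0
  adam_update <- function(w, g, m_, v_) {
    m_ <- b1 * m_ + (1 - b1) * g
    v_ <- b2 * v_ + (1 - b2) * g^2
    mhat <- m_ / (1 - b1^step)
    vhat <- v_ / (1 - b2^step)
    list(w = w - lr * (mhat / (sqrt(vhat) + eps) + wd * w), m = m_, v = v_)
  }

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf; best_model <- model; wait <- 0L
  for (epoch in seq_len(config$epochs)) {
    for (sb in stacked_batches) {
      lg <- batch_loss_grad(model, sb)
      step <- step + 1L
      u <- adam_update(model$K0, lg$grads$dK0, mstate$K0, vstate$K0)
      model$K0 <- u$w; mstate$K0 <- u$m; vstate$K0 <- u$v
      for (j in seq_len(model$depth)) {
        u <- adam_update(model$hidden[[j]], lg$grads$dhidden[[j]],
                         mstate$hidden[[j]], vstate$hidden[[j]])
        model$hidden[[j]] <- u$w; mstate$hidden[[j]] <- u$m
        vstate$hidden[[j]] <- u$v
      }
      u <- adam_update(model$Kout, lg$grads$dKout, mstate$Kout, vstate$Kout)
      model$Kout <- u$w; mstate$Kout <- u$m; vstate$Kout <- u$v
    }
    tl <- batch_loss(model, stacked_train)
    vl <- batch_loss(model, stacked_val)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tl,
                                         val_loss = vl))
    if (vl < best_val - 1e-12) {
      best_val <- vl; best_model <- model; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  attr(history, "seed") <- config$seed
  best_model$history <- history
  list(model = best_model, history = history)
}

#' Fit the graph-network surrogate to a training set
#'
#' The main fitting entry point: standardizes the targets, initializes a
#' network and trains it. The returned model carries the normalization
#' statistics, so [predict.gnn_surrogate()] and design-time metrics are
#' reported on the original scale (kcal/mol; Angstrom).
#'
#' With `members > 1` a small deep ensemble is fitted: independent
#' networks trained from different initializations (seeds `seed`,
#' `seed + 1`, ...) whose predictions are averaged. At desk-scale sample
#' sizes the averaging reduces the seed-to-seed variance of the surrogate
#' substantially and is the recommended profile for design work.
#'
#' @param dataset List of labeled examples (`features`, `laplacian`,
#'   `targets`), e.g. from [as_training_data()].
#' @param width,depth Network dimensions; the desk-scale default is width
#'   64, depth 5. Use width 512 for the full-scale profile.
#' @param config A [train_config()].
#' @param leaky_slope,init_scale Passed to [gnn_surrogate()].
#' @param members Number of ensemble members (default 1: a single
#'   network).
#' @return A fitted `gnn_surrogate` with `norm_stats`, `history` and
#'   `config` attached, or a `gnn_ensemble` of such models when
#'   `members > 1`.
#' @examples
#' \donttest{
#' world <- synthetic_world(seed = 1)
#' ds <- make_dataset(40, n_residues = 12, world = world, seed = 1)
#' td <- as_training_data(ds)
#' fit <- fit_surrogate(td, width = 16, config = train_config(epochs = 30))
#' fit
#' }
#' @export
fit_surrogate <- function(dataset, width = 64, depth = 5,
                          config = train_config(), leaky_slope = 0.01,
                          init_scale = 0.1, members = 1) {
  std <- standardize_targets(dataset)
  c_in <- nrow(dataset[[1]]$features)
  fit_one <- function(seed) {
    cfg <- config
    cfg$seed <- seed
    set.seed(seed)
    model <- gnn_surrogate(input_channels = c_in, width = width,
                           depth = depth, leaky_slope = leaky_slope,
                           init_scale = init_scale)
    trained <- train_surrogate(model, std$dataset, cfg)
    fit <- trained$model
    fit$norm_stats <- std$norm_stats
    fit$config <- cfg
    fit
  }
  if (members == 1) return(fit_one(config$seed))
  fits <- lapply(config$seed + seq_len(members) - 1, fit_one)
  structure(list(members = fits, norm_stats = std$norm_stats,
                 config = config),
            class = "gnn_ensemble")
}

#' @export
print.gnn_ensemble <- function(x, ...) {
  cat(sprintf("deep ensemble of %d graph-network surrogates\n",
              length(x$members)))
  print(x$members[[1]])
  invisible(x)
}

#' @export
print.gnn_surrogate <- function(x, ...) {
  cat(sprintf("graph-network surrogate: %d -> %d channels, depth %d, width %d\n",
              x$input_channels, 2L, x$depth, x$width))
  cat(sprintf("  parameters: %s (no biases)\n",
              format(count_parameters(x), big.mark = ",")))
  if (!is.null(x$norm_stats))
    cat(sprintf("  fitted; target scales: energy sd %.3f, deviation sd %.3f\n",
                x$norm_stats$sd[1], x$norm_stats$sd[2]))
  if (!is.null(x$history))
    cat(sprintf("  final validation loss: %.4g (%d epochs)\n",
                utils::tail(x$history$val_loss, 1), nrow(x$history)))
  invisible(x)
}

#' @export
summary.gnn_surrogate <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("training history (last rows):\n")
    print(utils::tail(object$history, 3), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.gnn_surrogate <- function(object, ...) {
  c(K0 = list(object$K0), hidden = list(object$hidden),
    Kout = list(object$Kout))
}

#' @export
plot.gnn_surrogate <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "MSE loss", log = "y", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

denormalize_output <- function(out_std, norm_stats) {
  if (is.null(norm_stats)) return(out_std)
  out_std * norm_stats$sd + norm_stats$mean
}

#' Predict per-residue energy and deviation
#'
#' @param object A fitted [gnn_surrogate()].
#' @param X Feature matrix ((k+3) x n), e.g. from [build_features()].
#' @param L Graph Laplacian for the same structure.
#' @param ... Unused.
#' @return 2 x n matrix on the original target scale: row `energy`
#'   (kcal/mol), row `deviation` (Angstrom).
#' @export
predict.gnn_surrogate <- function(object, X, L, ...) {
  out <- denormalize_output(surrogate_forward(object, X, L), object$norm_stats)
  rownames(out) <- c("energy", "deviation")
  out
}

#' Design metrics of a relaxed sequence under the surrogate
#'
#' Stacks a relaxed sequence matrix over the (fixed) geometric rows of the
#' target structure, evaluates the surrogate, and de-normalizes. The
#' scalar aggregates are the design objective ingredients: total energy
#' (sum over residues) and total stability (root mean square of the
#' per-residue deviation channel).
#'
#' @param model Fitted surrogate.
#' @param S k x n relaxed (or one-hot) sequence matrix.
#' @param geo_rows 3 x n standardized geometric rows of the target (see
#'   [geometry_rows()]).
#' @param L Graph Laplacian of the target.
#' @return List `energy_total`, `stability_total`, `per_residue` (2 x n).
#' @export
predict_design_metrics <- function(model, S, geo_rows, L) {
  UseMethod("predict_design_metrics")
}

#' @export
predict_design_metrics.gnn_surrogate <- function(model, S, geo_rows, L) {
  if (any(S < -1e-9 | S > 1 + 1e-9))
    warning("relaxed sequence matrix has entries outside [0, 1]")
  out <- denormalize_output(surrogate_forward(model, rbind(S, geo_rows), L),
                            model$norm_stats)
  rownames(out) <- c("energy", "deviation")
  list(energy_total = sum(out[1, ]),
       stability_total = sqrt(mean(out[2, ]^2)),
       per_residue = out)
}

#' @export
predict_design_metrics.gnn_ensemble <- function(model, S, geo_rows, L) {
  outs <- lapply(model$members, function(m)
    predict_design_metrics(m, S, geo_rows, L)$per_residue)
  out <- Reduce(`+`, outs) / length(outs)
  list(energy_total = sum(out[1, ]),
       stability_total = sqrt(mean(out[2, ]^2)),
       per_residue = out)
}

#' @export
predict.gnn_ensemble <- function(object, X, L, ...) {
  preds <- lapply(object$members, predict, X, L)
  Reduce(`+`, preds) / length(preds)
}

#' Gradient of the design objective with respect to the sequence
#'
#' Backpropagates the scalar objective `energy_total + lambda * max(0,
#' stability_total - delta_stab)^2` through the network to the one-hot
#' block of the input; the geometric rows are fixed and receive no
#' gradient.
#'
#' @inheritParams predict_design_metrics
#' @param lambda Stability penalty weight (0 disables the penalty).
#' @param delta_stab Acceptable deviation from the target (Angstrom).
#' @return k x n gradient matrix.
#' @export
gradient_wrt_sequence <- function(model, S, geo_rows, L, lambda = 1,
                                  delta_stab = Inf) {
  UseMethod("gradient_wrt_sequence")
}

#' @export
gradient_wrt_sequence.gnn_ensemble <- function(model, S, geo_rows, L,
                                               lambda = 1,
                                               delta_stab = Inf) {
  k <- nrow(S)
  n <- ncol(S)
  m <- length(model$members)
  caches <- lapply(model$members, function(mm)
    surrogate_forward(mm, rbind(S, geo_rows), L, keep = TRUE))
  outs <- lapply(seq_len(m), function(i)
    denormalize_output(caches[[i]]$out, model$members[[i]]$norm_stats))
  avg <- Reduce(`+`, outs) / m
  # cotangent of the objective w.r.t. the averaged de-normalized output
  G_avg <- matrix(0, 2, n)
  G_avg[1, ] <- 1
  R <- sqrt(mean(avg[2, ]^2))
  excess <- max(0, R - delta_stab)
  if (lambda > 0 && excess > 0 && R > 0)
    G_avg[2, ] <- lambda * 2 * excess * avg[2, ] / (n * R)
  dX <- matrix(0, k, n)
  for (i in seq_len(m)) {
    sds <- model$members[[i]]$norm_stats$sd %||% c(1, 1)
    G_out <- G_avg * sds / m
    g <- surrogate_backward(model$members[[i]], caches[[i]], G_out)
    dX <- dX + g$dX[seq_len(k), , drop = FALSE]
  }
  dX
}

#' @export
gradient_wrt_sequence.gnn_surrogate <- function(model, S, geo_rows, L,
                                                lambda = 1,
                                                delta_stab = Inf) {
  k <- nrow(S)
  cache <- surrogate_forward(model, rbind(S, geo_rows), L, keep = TRUE)
  out <- denormalize_output(cache$out, model$norm_stats)
  n <- ncol(out)
  sds <- if (is.null(model$norm_stats)) c(1, 1) else model$norm_stats$sd
  G_out <- matrix(0, 2, n)
  G_out[1, ] <- sds[1]
  R <- sqrt(mean(out[2, ]^2))
  excess <- max(0, R - delta_stab)
  if (lambda > 0 && excess > 0 && R > 0)
    G_out[2, ] <- lambda * 2 * excess * out[2, ] / (n * R) * sds[2]
  grads <- surrogate_backward(model, cache, G_out)
  grads$dX[seq_len(k), , drop = FALSE]
}

#' Write a surrogate checkpoint
#'
#' Single portable JSON file with weights, dimensions, normalization
#' statistics and the training seed.
#'
#' @param model Fitted surrogate.
#' @param path Output file.
#' @export
write_checkpoint <- function(model, path) {
  if (inherits(model, "gnn_ensemble")) {
    obj <- list(ensemble = TRUE,
                members = lapply(model$members, checkpoint_payload),
                seed = if (!is.null(model$config)) model$config$seed else NA)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
    return(invisible(path))
  }
  jsonlite::write_json(checkpoint_payload(model), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

checkpoint_payload <- function(model) {
  list(width = model$width, depth = model$depth,
              input_channels = model$input_channels,
              leaky_slope = model$leaky_slope,
              K0 = model$K0, hidden = model$hidden, Kout = model$Kout,
       norm_stats = model$norm_stats,
       seed = if (!is.null(model$config)) model$config$seed else NA)
}

#' Read a surrogate checkpoint
#'
#' @param path Checkpoint written by [write_checkpoint()].
#' @return A `gnn_surrogate` or `gnn_ensemble`.
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path)  # no simplification: predictable shape
  if (isTRUE(obj$ensemble)) {
    members <- lapply(obj$members, payload_to_model)
    return(structure(list(members = members,
                          norm_stats = members[[1]]$norm_stats,
                          config = NULL),
                     class = "gnn_ensemble"))
  }
  payload_to_model(obj)
}

# rebuild a model from the nested-list form of its JSON payload
# (write_json serializes a matrix as a list of rows)
payload_to_model <- function(obj) {
  as_mat <- function(rows) do.call(rbind, lapply(rows, unlist))
  model <- gnn_surrogate(input_channels = obj$input_channels,
                         width = obj$width, depth = obj$depth,
                         leaky_slope = obj$leaky_slope)
  model$K0 <- as_mat(obj$K0)
  model$hidden <- lapply(obj$hidden, as_mat)
  model$Kout <- as_mat(obj$Kout)
  if (!is.null(obj$norm_stats))
    model$norm_stats <- list(mean = unlist(obj$norm_stats$mean),
                             sd = unlist(obj$norm_stats$sd))
  model
}
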