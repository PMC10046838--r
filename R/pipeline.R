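#' Assemble a pipeline run configuration
#'
#' A fully serializable description of a run: synthetic-world
#' parameters, dataset size, training and design settings, and the
#' master seed. A run is reproducible from its config alone.
#'
#' @param out_dir Output directory.
#' @param n_designs,n_residues,frames,kind Dataset shape (see
#'   [make_dataset()]).
#' @param world_seed Seed of the synthetic world.
#' @param width,depth Surrogate dimensions.
#' @param train A [train_config()].
#' @param design A [design_config()].
#' @param n_starts Number of best starting sequences selected for
#'   design (default 50).
#' @param rounds Active-learning rounds.
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("pinnrun"), n_designs = 300,
                       n_residues = 25, frames = 50,
                       kind = "random_smooth", world_seed = 1,
                       width = 64, depth = 5,
                       train = train_config(), design = design_config(),
                       n_starts = 50, rounds = 1, seed = 1) {
  structure(list(out_dir = out_dir, n_designs = n_designs,
                 n_residues = n_residues, frames = frames, kind = kind,
                 world_seed = world_seed, width = width, depth = depth,
                 train = train, design = design, n_starts = n_starts,
                 rounds = rounds, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; top-level keys mirror [run_config()]
#'   arguments, with `train:` and `design:` sub-maps.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  tc <- do.call(train_config, y$train %||% list())
  dc <- do.call(design_config, y$design %||% list())
  y$train <- NULL; y$design <- NULL
  do.call(run_config, c(y, list(train = tc, design = dc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_manifest <- function(obj, path) {
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Generate data and train the surrogate
#'
#' Builds the synthetic dataset described by the config, fits the
#' surrogate, and writes a checkpoint, a loss-curve CSV and a seed
#' manifest into the output directory.
#'
#' @param config A [run_config()].
#' @return List with `model`, `dataset`, `training_data`, `paths`.
#' @export
run_train <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  world <- synthetic_world(seed = config$world_seed)
  dataset <- make_dataset(config$n_designs, config$n_residues, world,
                          frames = config$frames, kind = config$kind,
                          seed = config$seed)
  td <- as_training_data(dataset)
  pipeline_log("train", "dataset: %d designs x %d residues",
               config$n_designs, config$n_residues)
  model <- fit_surrogate(td, width = config$width, depth = config$depth,
                         config = config$train)
  paths <- list(checkpoint = file.path(config$out_dir, "model.json"),
                history = file.path(config$out_dir, "loss_curve.csv"),
                manifest = file.path(config$out_dir, "train_manifest.json"))
  write_checkpoint(model, paths$checkpoint)
  utils::write.csv(model$history, paths$history, row.names = FALSE)
  write_manifest(list(stage = "train", seed = config$seed,
                      train_seed = config$train$seed,
                      world_seed = config$world_seed,
                      dataset = dataset$manifest,
                      width = config$width, depth = config$depth,
                      wall_seconds = as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs"))),
                 paths$manifest)
  pipeline_log("train", "validation loss %.4g after %d epochs",
               utils::tail(model$history$val_loss, 1),
               nrow(model$history))
  list(model = model, dataset = dataset, training_data = td, paths = paths)
}

#' Select starts and run batch design
#'
#' Ranks the dataset's sequences by predicted total energy, selects the
#' best `n_starts` (lowest energy), runs [batch_design()] with the
#' configured mean-mutation stop, and writes designed sequences (FASTA),
#' per-design traces (CSV) and a run manifest.
#'
#' @param config A [run_config()].
#' @param trained A [run_train()] result (or a list with `model`,
#'   `dataset`, `training_data`).
#' @return The [batch_design()] result, with `starts` attached.
#' @export
run_design <- function(config, trained) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- trained$model
  td <- trained$training_data
  L <- attr(td, "laplacian")
  geo <- attr(td, "geo_rows")
  alphabet <- trained$dataset$world$alphabet
  k <- length(alphabet)
  # candidate pool: every example in the (possibly cumulative) training set
  seqs <- vapply(td, function(ex)
    discretize(ex$features[seq_len(k), , drop = FALSE], alphabet), "")
  pred_energy <- vapply(seq_along(td), function(i)
    sum(predict(model, td[[i]]$features, L)[1, ]), 0)
  m <- config$n_starts
  if (m > length(seqs)) {
    warning(sprintf("requested %d starts but only %d available; using all",
                    m, length(seqs)))
    m <- length(seqs)
  }
  starts <- seqs[order(pred_energy)[seq_len(m)]]
  pipeline_log("design", "selected %d starts (best predicted energy %.2f)",
               m, min(pred_energy))
  batch <- batch_design(as.list(starts), model, geo, L,
                        config = config$design,
                        alphabet = trained$dataset$world$alphabet)
  designed <- vapply(batch$results, `[[`, "", "sequence")
  names(designed) <- sprintf("design_%03d", seq_along(designed))
  write_fasta_sequences(designed, file.path(config$out_dir, "designs.fasta"))
  trace_df <- data.frame(
    design = seq_along(batch$results),
    start = vapply(batch$results, `[[`, "", "start_sequence"),
    sequence = designed,
    mutations = vapply(batch$results, `[[`, 1L, "mutations"),
    energy = vapply(batch$results, `[[`, 1, "energy"),
    stability = vapply(batch$results, `[[`, 1, "stability"),
    termination = vapply(batch$results, `[[`, "", "termination"))
  utils::write.csv(trace_df, file.path(config$out_dir, "design_traces.csv"),
                   row.names = FALSE)
  write_manifest(list(stage = "design", seed = config$design$seed,
                      n_starts = m,
                      batch_stop = config$design$batch_stop,
                      cap = config$design$cap,
                      total_mutations = batch$total_mutations),
                 file.path(config$out_dir, "design_manifest.json"))
  pipeline_log("design", "%d total mutations over %d designs",
               batch$total_mutations, length(batch$results))
  attr(batch, "starts") <- starts
  batch
}

#' Active-learning loop: design, re-simulate, retrain
#'
#' Each round designs sequences with the current surrogate, re-simulates
#' them in the synthetic world (the stand-in for running the simulator
#' on proposed designs), appends the new trajectory summaries to the
#' cumulative dataset, and retrains. Round 0 is plain training.
#'
#' @param config A [run_config()]; `config$rounds` rounds are run.
#' @param rounds Optional override of the round count.
#' @return List with the final `model`, the cumulative `training_data`,
#'   the per-round validation losses `round_val_loss`, and `manifests`.
#' @export
run_active_loop <- function(config, rounds = config$rounds) {
  trained <- run_train(config)
  if (rounds == 0) return(list(model = trained$model,
                               training_data = trained$training_data,
                               round_val_loss = numeric(0),
                               manifests = list()))
  world <- trained$dataset$world
  target <- trained$dataset$target
  td <- trained$training_data
  L <- attr(td, "laplacian"); geo <- attr(td, "geo_rows")
  model <- trained$model
  manifests <- list()
  round_val_loss <- numeric(rounds)
  for (r in seq_len(rounds)) {
    round_cfg <- config
    round_cfg$design$seed <- config$design$seed + r
    round_cfg$out_dir <- file.path(config$out_dir, sprintf("round_%02d", r))
    batch <- tryCatch(
      run_design(round_cfg, list(model = model, dataset = trained$dataset,
                                 training_data = td)),
      error = function(e) {
        pipeline_log("active", "round %d aborted: %s", r, conditionMessage(e))
        NULL
      })
    if (is.null(batch)) break
    new_seqs <- vapply(batch$results, `[[`, "", "sequence")
    new_seeds <- sample.int(.Machine$integer.max %/% 2, length(new_seqs))
    new_examples <- lapply(seq_along(new_seqs), function(i) {
      ens <- simulate_trajectory(new_seqs[i], target, world,
                                 frames = config$frames,
                                 seed = new_seeds[i])
      sm <- summarize_trajectory(ens, target)
      S <- sequence_onehot(new_seqs[i], world$alphabet)
      list(features = rbind(S, geo), laplacian = L,
           targets = rbind(sm$per_residue_energy, sm$per_residue_rmsd))
    })
    td <- c(td, new_examples)
    attr(td, "laplacian") <- L; attr(td, "geo_rows") <- geo
    tc <- config$train
    tc$seed <- config$train$seed + r
    model <- fit_surrogate(td, width = config$width, depth = config$depth,
                           config = tc)
    round_val_loss[r] <- utils::tail(model$history$val_loss, 1)
    manifests[[r]] <- list(round = r, new_designs = length(new_examples),
                           dataset_size = length(td),
                           val_loss = round_val_loss[r])
    pipeline_log("active", "round %d: dataset %d, val loss %.4g",
                 r, length(td), round_val_loss[r])
  }
  list(model = model, training_data = td,
       round_val_loss = round_val_loss, manifests = manifests)
}

#' Mean per-column letter entropy of a set of sequences
#'
#' Diversity measure used to compare designed sets against their
#' starting pools: Shannon entropy (nats) of the letter distribution at
#' each position, averaged over positions.
#'
#' @param sequences Character vector of equal-length sequences.
#' @return Scalar mean column entropy.
#' @export
sequence_entropy <- function(sequences) {
  M <- do.call(rbind, lapply(sequences, split_sequence))
  mean(apply(M, 2, function(col) {
    p <- table(col) / length(col)
    -sum(p * log(p))
  }))
}
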