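# Gain-sweep training protocol.
#
# Every gain level trains on the identical stream of example batches (shared
# sampling seed), with cross-entropy loss and Adam. Checkpoints are taken at
# iteration 0 (before any update) and every `eval_every` iterations: test
# accuracy, the 19 x 19 response matrix, mean per-problem activations (IPS at
# every checkpoint; all four layers at `capture_at` iterations), and a full
# weight/optimizer snapshot so training can be resumed from any checkpoint.

#' Training configuration
#'
#' @param profile `"desk"` (gains 1..5, 600 iterations, for laptop-scale runs)
#'   or `"full"` (the 17-gain grid, 3800 iterations).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Stimuli per iteration (default 100); one iteration is one
#'   optimizer step on one batch.
#' @param eval_every Checkpoint spacing in iterations (default 100).
#' @param max_iterations Training length; defaults to 600 (desk) / 3800 (full).
#' @param gains Gain grid; defaults to `c(1,2,3,4,5)` (desk) or
#'   [gain_grid_full()] (full).
#' @param rng_seed Seed governing batch sampling (shared across gains).
#' @param capture_at Iterations at which all four layers' mean problem
#'   activations are captured (default: the final iteration).
#' @param eval_per_problem Checkpoint evaluations use a fixed, balanced
#'   subset of the test split with this many variants per problem (keeps
#'   evaluation cost flat as the dataset grows; default 5).
#' @return A `train_config` list.
#' @export
train_config <- function(profile = c("desk", "full"), learning_rate = 1e-3,
                         batch_size = 100L, eval_every = 100L,
                         max_iterations = NULL, gains = NULL, rng_seed = 1L,
                         capture_at = NULL, eval_per_problem = 5L) {
  profile <- match.arg(profile)
  if (is.null(max_iterations)) {
    max_iterations <- if (profile == "full") 3800L else 600L
  }
  if (is.null(gains)) {
    gains <- if (profile == "full") gain_grid_full() else c(1, 2, 3, 4, 5)
  }
  if (length(gains) == 0L) stop("`gains` must be non-empty")
  if (is.null(capture_at)) capture_at <- max_iterations
  structure(list(profile = profile, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 eval_every = as.integer(eval_every),
                 max_iterations = as.integer(max_iterations),
                 gains = gains, rng_seed = as.integer(rng_seed),
                 capture_at = as.integer(capture_at),
                 eval_per_problem = as.integer(eval_per_problem)),
            class = "train_config")
}

.ckpt_key <- function(gain, iteration) sprintf("g%.2f_i%d", gain, iteration)

#' Balanced evaluation subset of the test split
#'
#' Returns the indices of the first `k` test variants of every problem:
#' a fixed, result-balanced subset used for checkpoint evaluations.
#'
#' @param dataset A `stimulus_dataset`.
#' @param k Variants per problem.
#' @return Integer image indices.
#' @export
eval_subset <- function(dataset, k) {
  te <- which(dataset$split == "test")
  unlist(lapply(split(te, dataset$problem_idx[te]), utils::head, k),
         use.names = FALSE)
}

#' Evaluate a model on the held-out split
#'
#' @param model A `pdnn_model`.
#' @param dataset A `stimulus_dataset`.
#' @param idx Image indices to evaluate (defaults to the test split).
#' @param batch_size Evaluation batch size.
#' @param capture_layers Layers whose mean per-problem activations to return.
#' @return List with `accuracy`, `response_matrix` (19 x 19 counts of response
#'   r given true result s), and `mean_acts` (named list, problems x units).
#' @export
evaluate_model <- function(model, dataset, idx = NULL, batch_size = 100L,
                           capture_layers = NULL) {
  if (is.null(idx)) idx <- which(dataset$split == "test")
  n_class <- model$config$n_classes
  n_prob <- nrow(dataset$specs)
  resp <- matrix(0L, n_class, n_class,
                 dimnames = list(response = 0:18, result = 0:18))
  sums <- list(); cnt <- NULL
  if (!is.null(capture_layers)) {
    sums <- lapply(stats::setNames(capture_layers, capture_layers), function(l)
      matrix(0, model$n_units[[l]], n_prob))
    cnt <- integer(n_prob)
  }
  for (start in seq(1L, length(idx), by = batch_size)) {
    b <- idx[start:min(start + batch_size - 1L, length(idx))]
    X <- dataset_images(dataset, b)
    fw <- model_forward(model, X, mode = "eval",
                        capture_layers = capture_layers)
    pred <- max.col(t(fw$logits)) - 1L
    truth <- dataset$labels[b]
    for (k in seq_along(b)) {
      resp[pred[k] + 1L, truth[k] + 1L] <- resp[pred[k] + 1L, truth[k] + 1L] + 1L
    }
    if (!is.null(capture_layers)) {
      pid <- dataset$problem_idx[b]
      for (l in capture_layers) {
        # accumulate activation sums per problem
        agg <- rowsum(t(fw$acts[[l]]), group = pid)
        sums[[l]][, as.integer(rownames(agg))] <-
          sums[[l]][, as.integer(rownames(agg))] + t(agg)
      }
      tb <- table(pid)
      cnt[as.integer(names(tb))] <- cnt[as.integer(names(tb))] + as.integer(tb)
    }
  }
  mean_acts <- NULL
  if (!is.null(capture_layers)) {
    if (any(cnt == 0L)) stop("coverage error: some problems have no test variants")
    mean_acts <- lapply(sums, function(s) t(s) / cnt)  # problems x units
  }
  list(accuracy = sum(diag(resp)) / sum(resp), response_matrix = resp,
       mean_acts = mean_acts)
}

#' Train the gain sweep
#'
#' Trains one network per gain level on the identical example stream and
#' records a checkpoint at iteration 0 and every `eval_every` iterations.
#'
#' @param dataset A `stimulus_dataset` with train/test splits.
#' @param cfg A [train_config()].
#' @param model_cfg A [model_config()] template; its `gain` field is
#'   overwritten by each grid value.
#' @param verbose Print per-checkpoint progress.
#' @return A `gain_sweep` object: `trace` (data.frame gain/iteration/accuracy),
#'   `records` (per-checkpoint response matrices, captured activations and
#'   snapshots), and the two configs.
#' @export
train_sweep <- function(dataset, cfg, model_cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), inherits(model_cfg, "model_config"))
  if (length(cfg$gains) == 0L) stop("`gains` must be non-empty")
  train_idx <- which(dataset$split == "train")
  if (length(train_idx) == 0L) stop("dataset has no training split")

  # shared batch stream: identical data order across gains
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(derive_seed(cfg$rng_seed, "batch-stream"))
  batch_idx <- matrix(sample(train_idx, cfg$batch_size * cfg$max_iterations,
                             replace = TRUE),
                      cfg$batch_size, cfg$max_iterations)

  trace <- list(); records <- list()
  # one model/optimizer per gain (identical init seed); gains advance in
  # lockstep through the shared batch stream so the per-batch image render and
  # the weight-independent V1 im2col can be reused across the grid
  models <- list(); adams <- list()
  for (gi in seq_along(cfg$gains)) {
    mc <- model_cfg; mc$gain <- cfg$gains[[gi]]
    models[[gi]] <- build_model(mc)
    adams[[gi]] <- adam_init(models[[gi]]$params)
  }
  ev_idx <- eval_subset(dataset, cfg$eval_per_problem)
  take_ckpt <- function(gi, iter) {
    g <- cfg$gains[[gi]]
    cap <- if (iter %in% cfg$capture_at) names(models[[gi]]$blocks) else "IPS"
    ev <- evaluate_model(models[[gi]], dataset, idx = ev_idx,
                         capture_layers = cap)
    key <- .ckpt_key(g, iter)
    records[[key]] <<- list(gain = g, iteration = iter,
                            accuracy = ev$accuracy,
                            response_matrix = ev$response_matrix,
                            mean_acts = ev$mean_acts,
                            snapshot = model_snapshot(models[[gi]], adams[[gi]]))
    trace[[key]] <<- data.frame(gain = g, iteration = iter,
                                accuracy = ev$accuracy)
    if (verbose) {
      message(sprintf("gain %.2f iter %4d  acc %.3f", g, iter, ev$accuracy))
    }
  }
  for (gi in seq_along(cfg$gains)) take_ckpt(gi, 0L)
  gather_v1 <- models[[1]]$blocks[[1]]$gather_in
  for (it in seq_len(cfg$max_iterations)) {
    b <- batch_idx[, it]
    X <- dataset_images(dataset, b)
    xcol <- conv_im2col(gather_v1, X)
    y <- dataset$labels[b]
    for (gi in seq_along(cfg$gains)) {
      fw <- model_forward(models[[gi]], X, mode = "train", keep_caches = TRUE,
                          v1_xcol = xcol)
      models[[gi]] <- fw$model
      bw <- model_backward(models[[gi]], fw, y)
      st <- adam_step(models[[gi]]$params, bw$grads, adams[[gi]],
                      lr = cfg$learning_rate)
      models[[gi]]$params <- st$params; adams[[gi]] <- st$state
    }
    if (it %% cfg$eval_every == 0L) {
      for (gi in seq_along(cfg$gains)) take_ckpt(gi, it)
    }
  }
  structure(list(trace = do.call(rbind, c(trace, make.row.names = FALSE)),
                 records = records, train_config = cfg,
                 model_config = model_cfg, specs = dataset$specs),
            class = "gain_sweep")
}

#' @export
print.gain_sweep <- function(x, ...) {
  cat(sprintf("<gain_sweep> %d gains x %d checkpoints (max iter %d)\n",
              length(unique(x$trace$gain)),
              length(unique(x$trace$iteration)), max(x$trace$iteration)))
  invisible(x)
}

#' Fetch one sweep checkpoint
#' @param sweep A `gain_sweep`.
#' @param gain,iteration Checkpoint coordinates.
#' @export
sweep_record <- function(sweep, gain, iteration) {
  r <- sweep$records[[.ckpt_key(gain, iteration)]]
  if (is.null(r)) stop(sprintf("missing checkpoint: gain %.2f iteration %d",
                               gain, iteration))
  r
}

#' Iterations needed to reach an accuracy threshold
#'
#' @param trace Data.frame with `iteration` and `accuracy` columns for one
#'   model (e.g. a subset of `sweep$trace`).
#' @param threshold Accuracy threshold in (0, 1].
#' @return The first checkpoint iteration whose accuracy meets the threshold,
#'   or `NA` if it is never reached.
#' @export
iterations_to_threshold <- function(trace, threshold = 0.95) {
  if (nrow(trace) == 0L) stop("empty trace")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  tr <- trace[order(trace$iteration), ]
  hit <- which(tr$accuracy >= threshold)
  if (length(hit) == 0L) NA_integer_ else as.integer(tr$iteration[hit[1]])
}

#' Extended ("catch-up") training from a checkpoint
#'
#' Resumes training from a stored checkpoint with the gain held fixed, until
#' test accuracy reaches `target_accuracy` or a hard cap of
#' `cap_factor * from_iteration` additional iterations (censored, not an
#' error). The percentage convention reports additional iterations relative to
#' the starting iteration.
#'
#' @param dataset The training dataset.
#' @param sweep The `gain_sweep` holding the checkpoint.
#' @param gain,from_iteration Checkpoint to resume from.
#' @param target_accuracy Test accuracy to reach.
#' @param cap_factor Censoring cap as a multiple of `from_iteration`.
#' @param capture_final Capture all-layer mean activations at the final state.
#' @return List with `additional_iterations`, `pct_additional`, `censored`,
#'   `final_accuracy`, `trace`, and `final_record` (response matrix + captured
#'   activations at the stopping point).
#' @export
extended_train <- function(dataset, sweep, gain, from_iteration,
                           target_accuracy, cap_factor = 5,
                           capture_final = TRUE) {
  cfg <- sweep$train_config
  rec <- sweep_record(sweep, gain, from_iteration)
  mc <- sweep$model_config; mc$gain <- gain
  model <- build_model(mc)
  model <- model_restore(model, rec$snapshot)
  adam <- rec$snapshot$adam
  cap <- as.integer(max(cap_factor * from_iteration, cfg$eval_every))
  eval_layers <- if (capture_final) names(model$blocks) else "IPS"
  ev_idx <- eval_subset(dataset, cfg$eval_per_problem)

  done <- function(acc) acc >= target_accuracy
  trace <- data.frame(iteration = from_iteration, accuracy = rec$accuracy)
  pct <- function(add) if (from_iteration > 0L) 100 * add / from_iteration else NA_real_
  if (done(rec$accuracy)) {
    ev <- evaluate_model(model, dataset, idx = ev_idx,
                         capture_layers = eval_layers)
    return(list(additional_iterations = 0L, pct_additional = 0,
                censored = FALSE, final_accuracy = rec$accuracy,
                trace = trace, final_record = ev))
  }
  train_idx <- which(dataset$split == "train")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(derive_seed(cfg$rng_seed, paste0("extended-", from_iteration)))
  add <- 0L; ev <- NULL
  while (add < cap) {
    for (k in seq_len(cfg$eval_every)) {
      b <- sample(train_idx, cfg$batch_size, replace = TRUE)
      X <- dataset_images(dataset, b)
      fw <- model_forward(model, X, mode = "train", keep_caches = TRUE)
      model <- fw$model
      bw <- model_backward(model, fw, dataset$labels[b])
      st <- adam_step(model$params, bw$grads, adam, lr = cfg$learning_rate)
      model$params <- st$params; adam <- st$state
    }
    add <- add + cfg$eval_every
    ev <- evaluate_model(model, dataset, idx = ev_idx,
                         capture_layers = eval_layers)
    trace <- rbind(trace, data.frame(iteration = from_iteration + add,
                                     accuracy = ev$accuracy))
    if (done(ev$accuracy)) break
  }
  censored <- !done(ev$accuracy)
  list(additional_iterations = add,
       pct_additional = pct(add),
       censored = censored, final_accuracy = ev$accuracy,
       trace = trace, final_record = ev)
}
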