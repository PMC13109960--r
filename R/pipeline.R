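# End-to-end experiment orchestration.
#
# run_experiment() chains the stages: stimuli -> gain-sweep training ->
# digital-twin matching -> behavioral metrics -> representational similarity
# -> manifold geometry -> extended-training remediation, and writes the
# primary tables as CSV/JSON under an output directory. Each stage consumes a
# seed derived from the global seed, so a rerun with the same configuration
# is byte-identical. The numbered scripts under analysis/ drive the same
# stage functions one at a time.

#' Experiment configuration
#'
#' @param profile `"desk"` (default; laptop-scale) or `"full"` (the
#'   full-scale protocol: 17 gains, 3800 iterations, 100 variants/problem --
#'   long-running).
#' @param seed Global seed; every random stage derives its own seed from it.
#' @param out_dir Output directory for tables (`NULL` = no files written).
#' @param glyph_style Stimulus style (`"handwritten_synthetic"`, `"printed"`,
#'   `"mixed"`).
#' @param variants_per_problem Variants per problem (default 100; images are
#'   rendered lazily, so this costs render time rather than memory).
#' @param n_glyph_variants Glyph bank size per character.
#' @param cohort A [cohort_config()]; group sizes and calibration.
#' @param do_nrs,do_manifolds,do_overlap,do_remediation Stage toggles.
#' @param nrs_coupling,nrs_noise_sd Coupling/noise for the synthetic observed
#'   similarity used in the prediction stage.
#' @param train_overrides,model_overrides Named lists overriding individual
#'   [train_config()] / [model_config()] fields (e.g. shorter runs).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(profile = c("desk", "full"), seed = 1L,
                              out_dir = NULL,
                              glyph_style = "handwritten_synthetic",
                              variants_per_problem = NULL,
                              n_glyph_variants = 100L,
                              cohort = NULL,
                              do_nrs = TRUE, do_manifolds = TRUE,
                              do_overlap = TRUE, do_remediation = TRUE,
                              nrs_coupling = 0.8, nrs_noise_sd = 0.1,
                              train_overrides = list(),
                              model_overrides = list()) {
  profile <- match.arg(profile)
  if (is.null(variants_per_problem)) variants_per_problem <- 100L
  if (is.null(cohort)) cohort <- cohort_config(rng_seed = derive_seed(seed, "cohort"))
  structure(as.list(environment()), class = "experiment_config")
}

.write_csv <- function(df, dir, name) {
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  invisible(df)
}

#' Run the full experiment
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress.
#' @return A list of artifacts: `dataset` (specs + counts only), `sweep`
#'   trace, `cohort`, `matches`, `best_iteration`, `permutation`,
#'   `group_gain_stats`, `behavior`, `behavior_groups`, `nrs`, `overlap`,
#'   `prediction`, `manifolds`, `remediation` -- also written as CSV/JSON
#'   tables under `config$out_dir` when set.
#' @export
run_experiment <- function(config = experiment_config(), verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- proc.time()[3]
  out <- list(config = config)

  ## stage 1: stimuli -----------------------------------------------------
  say("[stimuli] enumerating problems and rendering variants")
  problems <- enumerate_problems()
  bank <- build_glyph_bank(config$glyph_style, config$n_glyph_variants,
                           rng_seed = derive_seed(config$seed, "glyphs"))
  dataset <- build_dataset(problems, bank, config$variants_per_problem,
                           rng_seed = derive_seed(config$seed, "dataset"),
                           materialize = FALSE)

  ## stage 2: gain-sweep training -----------------------------------------
  say("[sweep] training the gain grid")
  tcfg <- do.call(train_config, c(
    list(profile = config$profile,
         rng_seed = derive_seed(config$seed, "train")),
    config$train_overrides))
  mcfg <- do.call(model_config, c(
    list(profile = config$profile,
         rng_seed = derive_seed(config$seed, "model")),
    config$model_overrides))
  sweep <- train_sweep(dataset, tcfg, mcfg, verbose = verbose)
  out$trace <- .write_csv(sweep$trace, config$out_dir, "sweep_trace.csv")

  ## stage 3: cohort + digital-twin matching -------------------------------
  say("[twins] generating cohort and matching children to gains")
  cohort <- generate_cohort(config$cohort)
  out$cohort <- .write_csv(cohort, config$out_dir, "cohort.csv")
  best <- select_best_iteration(sweep, cohort)
  out$best_iteration <- best$iteration
  matches <- match_children(sweep, cohort, best$iteration)
  perm <- permutation_control(matches, n_perm = 1000L,
                              rng_seed = derive_seed(config$seed, "perm"))
  out$permutation <- perm[c("fitted_mean", "perm_mean", "perm_sd")]
  gg <- split(matches$gain, matches$group)
  out$group_gain_stats <- group_stats(gg$MLD, gg$TD)

  ## stage 4: behavioral metrics -------------------------------------------
  say("[behavior] response-matrix metrics across the sweep")
  behav <- behavioral_metrics(sweep)
  out$behavior <- .write_csv(behav, config$out_dir, "behavioral_metrics.csv")
  bm <- merge(matches, behav,
              by.x = c("gain", "iteration"), by.y = c("gain", "iteration"))
  out$behavior_groups <- lapply(
    c(systematic_error = "systematic_error", imprecision = "imprecision",
      effective_responses = "effective_responses"),
    function(col) {
      v <- split(bm[[col]], bm$group)
      group_stats(v$MLD, v$TD)
    })

  ## stage 5: representational similarity ----------------------------------
  cap_iter <- max(sweep$train_config$capture_at)
  if (config$do_nrs) {
    say("[nrs] block-averaged similarity per layer and gain")
    nrs_rows <- list(); overlap_rows <- list()
    for (g in tcfg$gains) {
      rec <- sweep_record(sweep, g, cap_iter)
      for (layer in names(rec$mean_acts)) {
        nr <- nrs_matrix(rec$mean_acts[[layer]], sweep$specs)
        nrs_rows[[paste(g, layer)]] <- data.frame(
          gain = g, iteration = cap_iter, layer = layer,
          add_sub = block_average(nr, "add_sub"),
          add_add = block_average(nr, "add_add"),
          sub_sub = block_average(nr, "sub_sub"))
        if (config$do_overlap && layer == "IPS") {
          ov <- operand_overlap_average(nr)
          overlap_rows[[paste(g, layer)]] <- data.frame(
            gain = g, iteration = cap_iter, layer = layer,
            both = ov["both"], left = ov["left"], right = ov["right"],
            none = ov["none"])
        }
      }
    }
    out$nrs <- .write_csv(do.call(rbind, c(nrs_rows, make.row.names = FALSE)),
                          config$out_dir, "nrs_block_averages.csv")
    if (config$do_overlap) {
      out$overlap <- .write_csv(
        do.call(rbind, c(overlap_rows, make.row.names = FALSE)),
        config$out_dir, "nrs_operand_overlap.csv")
    }
    # prediction stage: per-child predicted IPS add-sub NRS vs synthetic
    # observed values with known coupling
    say("[nrs] prediction stage against synthetic observed similarity")
    pm <- predicted_nrs_for_matches(sweep, matches)
    obs <- generate_observed_nrs(pm$predicted_nrs, config$nrs_coupling,
                                 config$nrs_noise_sd,
                                 rng_seed = derive_seed(config$seed, "obs-nrs"))
    pv <- predicted_vs_observed(pm$predicted_nrs, obs,
                                rng_seed = derive_seed(config$seed, "pv-perm"))
    out$prediction <- list(r = pv$r, p_perm = pv$p_perm,
                           coupling = config$nrs_coupling,
                           noise_sd = config$nrs_noise_sd)
    pm$observed_nrs <- obs
    matches <- pm
  }
  out$matches <- .write_csv(matches, config$out_dir, "twin_matches.csv")

  ## stage 6: manifold geometry --------------------------------------------
  if (config$do_manifolds) {
    say("[manifolds] mean-field geometry per layer and gain")
    man_rows <- list()
    for (g in tcfg$gains) {
      rec <- sweep_record(sweep, g, cap_iter)
      for (layer in names(rec$mean_acts)) {
        ms <- group_by_result(rec$mean_acts[[layer]], sweep$specs)
        mm <- mft_manifold_metrics(ms, rng_seed = derive_seed(config$seed,
                                                             "mft"))
        man_rows[[paste(g, layer)]] <- data.frame(
          gain = g, iteration = cap_iter, layer = layer,
          capacity = mm$capacity, radius = mm$radius,
          dimension = mm$dimension,
          center_correlation = mm$center_correlation)
      }
    }
    out$manifolds <- .write_csv(
      do.call(rbind, c(man_rows, make.row.names = FALSE)),
      config$out_dir, "manifold_metrics.csv")
  }

  ## stage 7: extended-training remediation --------------------------------
  if (config$do_remediation) {
    say("[remediation] extended training of MLD twins to the TD median")
    td_target <- stats::median(matches$model_accuracy[matches$group == "TD"])
    mld_gains <- sort(unique(matches$gain[matches$group == "MLD"]))
    rem_rows <- lapply(mld_gains, function(g) {
      ex <- extended_train(dataset, sweep, g, best$iteration, td_target,
                           capture_final = FALSE)
      data.frame(gain = g, from_iteration = best$iteration,
                 target_accuracy = td_target,
                 additional_iterations = ex$additional_iterations,
                 pct_additional = ex$pct_additional,
                 censored = ex$censored,
                 final_accuracy = ex$final_accuracy)
    })
    out$remediation <- .write_csv(
      do.call(rbind, c(rem_rows, make.row.names = FALSE)),
      config$out_dir, "remediation.csv")
  }

  if (!is.null(config$out_dir)) {
    jsonlite::write_json(
      list(profile = config$profile, seed = config$seed,
           best_iteration = out$best_iteration,
           permutation = out$permutation,
           prediction = out$prediction,
           elapsed_s = unname(proc.time()[3] - t_start)),
      file.path(config$out_dir, "experiment_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  say("[done] %.1f s elapsed", proc.time()[3] - t_start)
  out$sweep <- sweep
  invisible(out)
}

#' Summarize experiment artifacts as a text report
#'
#' @param artifacts Result of [run_experiment()].
#' @return Character vector of report lines (also printed).
#' @export
make_report <- function(artifacts) {
  if (is.null(artifacts$trace) || nrow(artifacts$trace) == 0L) {
    stop("empty sweep: run the training stage before reporting")
  }
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("== digital-twin experiment report ==")
  add("gains: %s; final iteration %d",
      paste(sort(unique(artifacts$trace$gain)), collapse = ", "),
      max(artifacts$trace$iteration))
  fin <- artifacts$trace[artifacts$trace$iteration ==
                           max(artifacts$trace$iteration), ]
  add("final accuracy by gain: %s",
      paste(sprintf("G=%.2g:%.3f", fin$gain, fin$accuracy), collapse = "  "))
  add("best matching iteration: %d", artifacts$best_iteration)
  add("fitted mean distance %.4f vs permuted %.4f (SD %.4f)",
      artifacts$permutation$fitted_mean, artifacts$permutation$perm_mean,
      artifacts$permutation$perm_sd)
  gs <- artifacts$group_gain_stats
  add("matched gain MLD %.2f (SD %.2f) vs TD %.2f (SD %.2f), t=%.2f d=%.2f",
      gs$mean_x, gs$sd_x, gs$mean_y, gs$sd_y, gs$t, gs$cohens_d)
  if (!is.null(artifacts$prediction)) {
    add("predicted-vs-observed add-sub NRS r = %.3f (perm p = %.3g)",
        artifacts$prediction$r, artifacts$prediction$p_perm)
  }
  if (!is.null(artifacts$remediation)) {
    add("remediation: MLD twins needed %s extra iterations (pct of start: %s)",
        paste(artifacts$remediation$additional_iterations, collapse = "/"),
        paste(round(artifacts$remediation$pct_additional), collapse = "/"))
  }
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}
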