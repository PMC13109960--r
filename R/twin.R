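# Digital-twin matching.
#
# Children and networks are compared on a common [0, 1] scale: achievement
# scores are min-max normalized across the cohort, model accuracies min-max
# normalized across ALL checkpoints of the sweep (all iterations and gains).
# A child's twin at a given iteration is the gain minimizing the L1 distance
# |normalized accuracy - normalized score|; the best matching iteration
# minimizes the mean of these per-child distances.

#' Normalization bounds of a sweep
#'
#' @param sweep A `gain_sweep`.
#' @return List with `Am`, `AM`: minimum and maximum test accuracy across all
#'   iterations and gains.
#' @export
sweep_accuracy_bounds <- function(sweep) {
  list(Am = min(sweep$trace$accuracy), AM = max(sweep$trace$accuracy))
}

#' Min-max normalize a model accuracy
#'
#' @param A Accuracy (vector allowed).
#' @param bounds List with `Am` and `AM` (from [sweep_accuracy_bounds()]).
#' @return `(A - Am) / (AM - Am)`.
#' @export
normalize_accuracy <- function(A, bounds) {
  if (!is.finite(bounds$Am) || !is.finite(bounds$AM) || bounds$AM <= bounds$Am) {
    stop("degenerate bounds: accuracy maximum must exceed minimum")
  }
  (A - bounds$Am) / (bounds$AM - bounds$Am)
}

#' Min-max normalize cohort scores
#'
#' @param scores Raw (standard-scale) achievement scores across the cohort.
#' @return Scores mapped to `[0, 1]` by the cohort-wide minimum and maximum.
#' @export
normalize_scores <- function(scores) {
  lo <- min(scores); hi <- max(scores)
  if (hi <= lo) stop("degenerate bounds: all scores identical")
  (scores - lo) / (hi - lo)
}

#' Match children to gains at one iteration
#'
#' For each child, selects the gain whose normalized accuracy at `iteration`
#' is closest (L1) to the child's normalized score; ties break toward the
#' lowest gain.
#'
#' @param sweep A `gain_sweep`.
#' @param cohort Data.frame with columns `id`, `group`, `normalized_score`.
#' @param iteration Checkpoint iteration at which to match.
#' @param bounds Accuracy bounds; defaults to the whole-sweep bounds.
#' @return Data.frame (one row per child): `id`, `group`, `normalized_score`,
#'   `gain`, `model_accuracy`, `normalized_accuracy`, `distance`, `iteration`.
#' @export
match_children <- function(sweep, cohort, iteration,
                           bounds = sweep_accuracy_bounds(sweep)) {
  tr <- sweep$trace[sweep$trace$iteration == iteration, ]
  if (nrow(tr) == 0L) {
    stop(sprintf("missing checkpoint: no models evaluated at iteration %d",
                 iteration))
  }
  tr <- tr[order(tr$gain), ]
  a_norm <- normalize_accuracy(tr$accuracy, bounds)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    d <- abs(a_norm - cohort$normalized_score[i])
    j <- which.min(d)  # which.min returns the first (lowest-gain) minimum
    data.frame(id = cohort$id[i], group = cohort$group[i],
               normalized_score = cohort$normalized_score[i],
               gain = tr$gain[j], model_accuracy = tr$accuracy[j],
               normalized_accuracy = a_norm[j], distance = d[j],
               iteration = iteration)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Select the best matching iteration
#'
#' @param sweep A `gain_sweep`.
#' @param cohort Cohort data.frame (see [match_children()]).
#' @param iterations Candidate iterations (default: every checkpoint).
#' @return List with `iteration` (argmin of the mean per-child best distance;
#'   earliest on exact ties), `mean_distance` per candidate iteration.
#' @export
select_best_iteration <- function(sweep, cohort,
                                  iterations = sort(unique(sweep$trace$iteration))) {
  if (length(iterations) == 0L) stop("empty iteration grid")
  bounds <- sweep_accuracy_bounds(sweep)
  md <- vapply(iterations, function(it) {
    mean(match_children(sweep, cohort, it, bounds)$distance)
  }, numeric(1))
  list(iteration = iterations[which.min(md)],
       mean_distance = stats::setNames(md, iterations))
}

#' Permutation control for the matching distance
#'
#' Randomly reassigns the children's normalized scores across the fitted
#' models and recomputes the mean distance, giving the null distribution that
#' the fitted matching is compared against.
#'
#' @param matches Output of [match_children()].
#' @param n_perm Number of permutations.
#' @param rng_seed Seed.
#' @return List with `fitted_mean`, `perm_mean`, `perm_sd`, `perm_means`
#'   (per-permutation mean distances).
#' @export
permutation_control <- function(matches, n_perm = 1000L, rng_seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (nrow(matches) < 2L) stop("need at least 2 children")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  pm <- vapply(seq_len(n_perm), function(k) {
    mean(abs(matches$normalized_accuracy -
               sample(matches$normalized_score)))
  }, numeric(1))
  list(fitted_mean = mean(matches$distance),
       perm_mean = mean(pm), perm_sd = stats::sd(pm), perm_means = pm)
}

#' Two-group comparison with effect size
#'
#' Welch's two-sample t-test plus pooled-SD Cohen's d.
#'
#' @param x,y Numeric vectors (>= 2 values each).
#' @return List with `t`, `df`, `p`, `cohens_d`, `mean_x`, `mean_y`, `sd_x`,
#'   `sd_y`. With both groups constant and equal, `t = 0` and `d = 0`; with
#'   zero pooled variance but different means, `d` is `Inf` (flagged via
#'   `degenerate = TRUE`).
#' @export
group_stats <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("insufficient data: need at least 2 values per group")
  }
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  degenerate <- sp2 == 0
  d <- if (degenerate) {
    if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
  } else {
    (mean(x) - mean(y)) / sqrt(sp2)
  }
  if (degenerate) {
    tt <- list(statistic = c(t = if (mean(x) == mean(y)) 0 else
      Inf * sign(mean(x) - mean(y))), parameter = c(df = NA_real_),
      p.value = if (mean(x) == mean(y)) 1 else 0)
  } else {
    tt <- stats::t.test(x, y)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       cohens_d = d, degenerate = degenerate,
       mean_x = mean(x), mean_y = mean(y),
       sd_x = stats::sd(x), sd_y = stats::sd(y))
}

#' Predicted add-sub similarity for matched children
#'
#' For every matched child, computes the IPS add-sub NRS of its twin network
#' at the matching iteration (from the sweep's captured IPS activations).
#'
#' @param sweep A `gain_sweep`.
#' @param matches Output of [match_children()].
#' @param layer Layer to read (default `"IPS"`; must have been captured at the
#'   matching iteration).
#' @return `matches` with an added `predicted_nrs` column.
#' @export
predicted_nrs_for_matches <- function(sweep, matches, layer = "IPS") {
  cache <- new.env(parent = emptyenv())
  get_nrs <- function(g, it) {
    key <- .ckpt_key(g, it)
    if (!is.null(cache[[key]])) return(cache[[key]])
    rec <- sweep_record(sweep, g, it)
    ma <- rec$mean_acts[[layer]]
    if (is.null(ma)) {
      stop(sprintf("layer %s activations not captured at gain %.2f iter %d",
                   layer, g, it))
    }
    nr <- nrs_matrix(ma, sweep$specs)
    val <- block_average(nr, "add_sub")
    cache[[key]] <- val
    val
  }
  matches$predicted_nrs <- vapply(seq_len(nrow(matches)), function(i) {
    get_nrs(matches$gain[i], matches$iteration[i])
  }, numeric(1))
  matches
}
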