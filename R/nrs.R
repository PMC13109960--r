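# Neural representational similarity (NRS).
#
# For one layer, the representation of a problem is the unit-wise mean
# activation over its test variants. The NRS matrix is the 380 x 380 Pearson
# correlation (across units) between these mean patterns, in the canonical
# problem order. Block averages summarize between-operation (add-sub) and
# within-operation (add-add, sub-sub) similarity.

#' Mean per-problem activations
#'
#' @param activations `units x n_images` matrix of layer activations.
#' @param problem_idx Integer problem index per image (column).
#' @param n_problems Total number of problems (defaults to `max(problem_idx)`).
#' @return `n_problems x units` matrix; row p is the unit-wise mean activation
#'   over all images of problem p.
#' @export
mean_problem_activations <- function(activations, problem_idx,
                                     n_problems = max(problem_idx)) {
  if (length(problem_idx) != ncol(activations)) {
    stop("one problem index per activation column is required")
  }
  if (length(unique(problem_idx)) != n_problems) {
    stop("coverage error: every problem needs at least one captured variant")
  }
  sums <- rowsum(t(activations), group = problem_idx)   # problems x units
  cnt <- as.vector(table(factor(problem_idx, levels = seq_len(n_problems))))
  sums / cnt
}

#' Problem-by-problem representational similarity matrix
#'
#' Pearson correlation across units between mean problem activations, sorted
#' into the canonical order (addition before subtraction, then by result, then
#' by first operand). Problems with zero activation variance across units give
#' undefined correlations, returned as `NA` and excluded from block averages.
#'
#' @param mean_acts `problems x units` matrix (rows aligned with `specs`).
#' @param specs Problem data.frame aligned with `mean_acts` rows.
#' @param max_units Layers wider than this are randomly subsampled (seeded)
#'   before correlation, for tractability on full-width models.
#' @param rng_seed Seed for the unit subsample.
#' @return An `nrs_matrix` object: list with `matrix` (problems x problems,
#'   symmetric, unit diagonal), `specs` (canonically sorted), and `order`.
#' @export
nrs_matrix <- function(mean_acts, specs, max_units = 8192L, rng_seed = 1L) {
  stopifnot(nrow(mean_acts) == nrow(specs))
  if (ncol(mean_acts) > max_units) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(rng_seed))
    mean_acts <- mean_acts[, sample.int(ncol(mean_acts), max_units),
                           drop = FALSE]
  }
  ord <- canonical_problem_order(specs)
  A <- mean_acts[ord, , drop = FALSE]
  sd0 <- apply(A, 1, stats::sd) == 0
  M <- suppressWarnings(stats::cor(t(A)))
  M[sd0, ] <- NA_real_
  M[, sd0] <- NA_real_
  diag(M) <- ifelse(sd0, NA_real_, 1)
  structure(list(matrix = M, specs = specs[ord, , drop = FALSE], order = ord),
            class = "nrs_matrix")
}

#' @export
print.nrs_matrix <- function(x, ...) {
  cat(sprintf("<nrs_matrix> %d x %d problems (%d undefined rows)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(is.na(diag(x$matrix)))))
  invisible(x)
}

#' Block-average NRS
#'
#' Average similarity over a problem-pair category: between addition and
#' subtraction problems (`add_sub`), between distinct addition problems
#' (`add_add`), or between distinct subtraction problems (`sub_sub`).
#' Within-operation categories exclude the (trivially 1) diagonal.
#'
#' @param nrs An [nrs_matrix()].
#' @param category One of `"add_sub"`, `"add_add"`, `"sub_sub"`.
#' @return Mean similarity over the category's pairs (`NA` entries excluded).
#' @export
block_average <- function(nrs, category = c("add_sub", "add_add", "sub_sub")) {
  category <- match.arg(category)
  is_add <- nrs$specs$operation == "addition"
  M <- nrs$matrix
  if (category == "add_sub") {
    if (!any(is_add) || all(is_add)) stop("empty category: need both operations")
    return(mean(M[is_add, !is_add], na.rm = TRUE))
  }
  sel <- if (category == "add_add") is_add else !is_add
  if (sum(sel) < 2) stop("empty category: need at least two problems")
  S <- M[sel, sel]
  diag(S) <- NA_real_
  mean(S, na.rm = TRUE)
}

#' NRS by operand overlap
#'
#' Partitions every cross-operation pair (one addition, one subtraction
#' problem) by operand equality -- both operands shared, only the left, only
#' the right, or none -- and returns the mean similarity per category.
#'
#' @param nrs An [nrs_matrix()].
#' @return Named numeric vector with entries `both`, `left`, `right`, `none`,
#'   plus attribute `"counts"` (pairs per category).
#' @export
operand_overlap_average <- function(nrs) {
  sp <- nrs$specs
  ia <- which(sp$operation == "addition")
  is <- which(sp$operation == "subtraction")
  if (!length(ia) || !length(is)) stop("need both operations for overlap analysis")
  M <- nrs$matrix[ia, is, drop = FALSE]
  left_eq <- outer(sp$operand1[ia], sp$operand1[is], "==")
  right_eq <- outer(sp$operand2[ia], sp$operand2[is], "==")
  cat_mat <- ifelse(left_eq & right_eq, "both",
                    ifelse(left_eq, "left",
                           ifelse(right_eq, "right", "none")))
  cats <- c("both", "left", "right", "none")
  out <- vapply(cats, function(cc) mean(M[cat_mat == cc], na.rm = TRUE),
                numeric(1))
  attr(out, "counts") <- vapply(cats, function(cc) sum(cat_mat == cc),
                                numeric(1))
  out
}

#' Inverse Fisher z-transform
#'
#' Maps a Fisher z value back to the correlation scale: `tanh(z)`. Used to put
#' externally supplied (z-transformed) representational similarity values on
#' the same scale as model correlations.
#'
#' @param z Numeric vector of z values.
#' @return `tanh(z)`, in (-1, 1).
#' @export
fisher_unz <- function(z) tanh(z)

#' Predicted-versus-observed similarity correlation
#'
#' Pearson correlation across children between the model-predicted add-sub
#' similarity of each child's matched network and the externally observed
#' value (already on the correlation scale), together with a permutation null
#' obtained by randomly reassigning observed values to children.
#'
#' @param predicted,observed Numeric vectors, one value per child.
#' @param n_perm Number of random permutations for the null distribution.
#' @param rng_seed Seed for the permutations.
#' @return List with `r`, `p_perm` (two-sided permutation p-value), and
#'   `null_r` (permutation distribution).
#' @export
predicted_vs_observed <- function(predicted, observed, n_perm = 1000L,
                                  rng_seed = 1L) {
  stopifnot(length(predicted) == length(observed))
  if (length(predicted) < 3L) stop("insufficient data: need at least 3 children")
  r <- stats::cor(predicted, observed)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  null_r <- vapply(seq_len(n_perm), function(i)
    stats::cor(predicted, sample(observed)), numeric(1))
  list(r = r, p_perm = mean(abs(null_r) >= abs(r)), null_r = null_r)
}
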