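# Behavioral measures computed from the 19 x 19 response matrix
# (counts of response r = 0..18 given true result s = 0..18).
#
# Trueness is measured by the numerical systematic error (how far the average
# response sits from the correct answer), precision by the numerical
# imprecision (within-level response spread), and response granularity by the
# exponential of the Shannon entropy of the pooled response distribution.

.check_response_matrix <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    stop("response matrix must be square (responses x expected results)")
  }
  if (any(counts < 0)) stop("response counts must be non-negative")
  invisible(counts)
}

#' Numerical systematic error (lack of trueness)
#'
#' The absolute difference between the mean response and the expected result,
#' measured at and averaged across each level of expected result.
#'
#' @param counts 19 x 19 matrix of counts: response (row, 0-18) by expected
#'   result (column, 0-18).
#' @return Non-negative scalar; 0 for a perfect responder.
#' @export
systematic_error <- function(counts) {
  .check_response_matrix(counts)
  n <- nrow(counts)
  values <- seq_len(n) - 1
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("undefined level: some expected results received no responses")
  }
  mean_resp <- as.vector(values %*% counts) / tot
  mean(abs(mean_resp - values))
}

#' Numerical imprecision (lack of precision)
#'
#' The population standard deviation of responses, measured at and averaged
#' across each level of expected result.
#'
#' @inheritParams systematic_error
#' @return Non-negative scalar; 0 for a deterministic exact responder.
#' @export
imprecision <- function(counts) {
  .check_response_matrix(counts)
  n <- nrow(counts)
  values <- seq_len(n) - 1
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("undefined level: some expected results received no responses")
  }
  m1 <- as.vector(values %*% counts) / tot
  m2 <- as.vector((values^2) %*% counts) / tot
  mean(sqrt(pmax(m2 - m1^2, 0)))
}

#' Effective number of distinct responses
#'
#' The exponential of the (natural-log) Shannon entropy of the pooled response
#' distribution across all problems: a uniform distribution over all 19
#' answers gives exactly 19, a constant responder gives 1.
#'
#' @inheritParams systematic_error
#' @return Scalar in `[1, nrow(counts)]`.
#' @export
effective_num_responses <- function(counts) {
  .check_response_matrix(counts)
  pooled <- rowSums(counts)
  tot <- sum(pooled)
  if (tot <= 0) stop("response matrix has zero total count")
  p <- pooled / tot
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}

#' Accuracy from a response matrix
#' @inheritParams systematic_error
#' @return Fraction of responses on the diagonal.
#' @export
response_accuracy <- function(counts) {
  .check_response_matrix(counts)
  sum(diag(counts)) / sum(counts)
}

#' Behavioral metric table for a sweep
#'
#' @param sweep A `gain_sweep`.
#' @return Data.frame keyed by (gain, iteration) with accuracy, systematic
#'   error, imprecision and effective number of responses, computed on the
#'   held-out test split.
#' @export
behavioral_metrics <- function(sweep) {
  rows <- lapply(sweep$records, function(r) {
    data.frame(gain = r$gain, iteration = r$iteration,
               accuracy = r$accuracy,
               systematic_error = systematic_error(r$response_matrix),
               imprecision = imprecision(r$response_matrix),
               effective_responses = effective_num_responses(r$response_matrix))
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$gain, out$iteration), ]
}
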