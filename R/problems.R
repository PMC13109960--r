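#' Enumerate single-result addition and subtraction problems
#'
#' Builds the full set of ordered-operand arithmetic problems whose result
#' falls in `[result_min, result_max]`. Operands are non-negative integers and
#' never exceed `result_max`, so the default task (results 0--18) yields 190
#' addition and 190 subtraction problems, exactly 20 per result value.
#'
#' @param result_min,result_max Integer bounds on the result (defaults 0 and 18).
#' @param operations Character vector, subset of `c("addition", "subtraction")`.
#' @return A data.frame with columns `operand1`, `operand2`, `operation`,
#'   `result`, one row per problem, in deterministic order (addition before
#'   subtraction, then by result, then by first operand).
#' @examples
#' nrow(enumerate_problems())            # 380
#' nrow(enumerate_problems(operations = "addition"))  # 190
#' @export
enumerate_problems <- function(result_min = 0L, result_max = 18L,
                               operations = c("addition", "subtraction")) {
  if (length(operations) == 0L) {
    stop("`operations` must contain at least one of 'addition', 'subtraction'")
  }
  operations <- match.arg(operations, c("addition", "subtraction"),
                          several.ok = TRUE)
  stopifnot(result_min >= 0L, result_min <= result_max)
  out <- list()
  if ("addition" %in% operations) {
    rows <- lapply(result_min:result_max, function(s) {
      a <- 0:s  # a + (s - a) = s; both operands bounded by result_max
      data.frame(operand1 = a, operand2 = s - a,
                 operation = "addition", result = s)
    })
    out <- c(out, rows)
  }
  if ("subtraction" %in% operations) {
    rows <- lapply(result_min:result_max, function(s) {
      a <- s:result_max  # a - (a - s) = s; minuend capped at result_max
      data.frame(operand1 = a, operand2 = a - s,
                 operation = "subtraction", result = s)
    })
    out <- c(out, rows)
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$operation, c("addition", "subtraction")),
                   res$result, res$operand1), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Canonical problem ordering
#'
#' Sorting used for all representational analyses: (i) addition before
#' subtraction, (ii) smaller results first, (iii) smaller first operands first.
#'
#' @param specs A problem data.frame as from [enumerate_problems()].
#' @return Integer permutation such that `specs[canonical_problem_order(specs), ]`
#'   is canonically sorted.
#' @export
canonical_problem_order <- function(specs) {
  order(match(specs$operation, c("addition", "subtraction")),
        specs$result, specs$operand1)
}
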