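test_that("mean problem activations average over variants", {
  acts <- matrix(c(1, 2, 3, 4,
                   5, 6, 7, 8), nrow = 2, byrow = TRUE)  # 2 units x 4 images
  pid <- c(1L, 1L, 2L, 2L)
  ma <- mean_problem_activations(acts, pid)
  expect_equal(dim(ma), c(2L, 2L))
  expect_equal(ma[1, ], c(1.5, 5.5), ignore_attr = TRUE)
  # one variant per problem: rows equal raw activations
  one <- mean_problem_activations(acts, 1:4)
  expect_equal(unname(one), unname(t(acts)))
  # duplicating identical variants leaves the mean unchanged
  dup <- mean_problem_activations(cbind(acts, acts), c(pid, pid))
  expect_equal(dup, ma)
  expect_error(mean_problem_activations(acts, c(1L, 1L, 2L, 2L),
                                        n_problems = 3L), "coverage")
})

test_that("similarity matrices are symmetric, bounded and hand-checkable", {
  specs <- enumerate_problems(0L, 1L)  # 3 additions + 2 subtractions...
  specs <- specs[1:4, ]
  ma <- rbind(c(1, 0, 0, 1),
              c(0, 1, 1, 0),
              c(1, 0, 0, 1),
              c(2, 2, 2, 2))  # constant row -> undefined
  nr <- nrs_matrix(ma, specs)
  M <- nr$matrix
  expect_equal(M[1, 2], -1)            # hand Pearson: perfectly anti-correlated
  expect_equal(M[1, 3], 1)
  expect_true(isSymmetric(unname(M)))
  expect_true(all(is.na(M[4, ])))      # constant row flagged undefined
  expect_true(all(abs(M[!is.na(M)]) <= 1 + 1e-12))
  expect_equal(diag(M)[1:3], rep(1, 3), ignore_attr = TRUE)
})

test_that("canonical ordering sorts addition first, then result, then operand", {
  specs <- fix_problems()
  set.seed(4)
  shuffled <- sample(nrow(specs))
  ma <- matrix(rnorm(nrow(specs) * 6), nrow(specs), 6)
  nr <- nrs_matrix(ma[shuffled, ], specs[shuffled, ])
  sp <- nr$specs
  expect_equal(sp$operation, rep(c("addition", "subtraction"), each = 190))
  expect_true(all(diff(sp$result[1:190]) >= 0))
  within <- split(sp$operand1[1:190], sp$result[1:190])
  expect_true(all(vapply(within, function(v) all(diff(v) > 0), logical(1))))
})

test_that("block averages and operand overlap partition the problem pairs", {
  specs <- fix_problems()
  n <- nrow(specs)
  set.seed(8)
  ma <- matrix(rnorm(n * 10), n, 10)
  nr <- nrs_matrix(ma, specs)
  # a constant similarity matrix averages to that constant in every block
  nr_const <- nr; nr_const$matrix[] <- 0.7; diag(nr_const$matrix) <- 1
  for (cat in c("add_sub", "add_add", "sub_sub")) {
    expect_equal(block_average(nr_const, cat), 0.7)
  }
  ov <- operand_overlap_average(nr)
  cnt <- attr(ov, "counts")
  expect_equal(sum(cnt), 190 * 190)          # partition of cross-op pairs
  expect_equal(names(ov), c("both", "left", "right", "none"))
  # "6+2" vs "6-2" falls in category both; "6+2" vs "6-3" in left
  ia <- which(specs$operation == "addition" & specs$operand1 == 6 &
                specs$operand2 == 2)
  expect_length(ia, 1L)
  # category counts: each addition (a,b) pairs with subtraction (a,b) iff
  # that subtraction exists (a >= b)
  n_both <- sum(specs$operand1[specs$operation == "addition"] >=
                  specs$operand2[specs$operation == "addition"])
  expect_equal(unname(cnt["both"]), n_both)
})

test_that("the tanh bridge inverts the Fisher z-transform", {
  expect_equal(fisher_unz(0), 0)
  expect_equal(fisher_unz(atanh(0.5)), 0.5)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisher_unz(atanh(r)), r)
})

test_that("predicted-vs-observed correlation behaves at both extremes", {
  set.seed(12)
  pred <- runif(30, 0.1, 0.8)
  ident <- predicted_vs_observed(pred, pred, n_perm = 200L)
  expect_equal(ident$r, 1)
  indep <- predicted_vs_observed(pred, rnorm(30), n_perm = 500L, rng_seed = 3L)
  expect_lt(abs(mean(indep$null_r)), 0.06)  # null centered on zero
  expect_error(predicted_vs_observed(1:2, 1:2), "insufficient")
})

test_that("coupled synthetic observations recover the generating association", {
  # parameter-recovery: strong coupling with mild noise must give a high
  # prediction correlation, zero coupling must not
  set.seed(31)
  pred <- runif(200, 0.2, 0.7)
  obs_strong <- generate_observed_nrs(pred, coupling = 1, noise_sd = 0.05,
                                      rng_seed = 5L)
  expect_gt(predicted_vs_observed(pred, obs_strong, n_perm = 100L)$r, 0.9)
  obs_null <- generate_observed_nrs(pred, coupling = 0, noise_sd = 0.3,
                                    rng_seed = 6L)
  expect_lt(abs(predicted_vs_observed(pred, obs_null, n_perm = 100L)$r), 0.2)
})
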