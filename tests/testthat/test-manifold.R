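test_that("grouping by result yields 19 manifolds of 20 problems", {
  specs <- fix_problems()
  set.seed(2)
  ma <- matrix(rnorm(nrow(specs) * 30), nrow(specs), 30)
  ms <- group_by_result(ma, specs)
  expect_equal(ms$n_manifolds, 19L)
  expect_true(all(ms$points_per_manifold == 20L))
  # "2+7", "5+4" and "9-0" all live in manifold 9
  m9 <- specs[specs$result == 9, ]
  expect_true(any(m9$operation == "addition" & m9$operand1 == 2 & m9$operand2 == 7))
  expect_true(any(m9$operation == "addition" & m9$operand1 == 5 & m9$operand2 == 4))
  expect_true(any(m9$operation == "subtraction" & m9$operand1 == 9 & m9$operand2 == 0))
  expect_equal(nrow(ms$points[["9"]]), 20L)
})

test_that("point manifolds reproduce Cover's capacity limit", {
  ms <- fix_point_manifolds(P = 20L, N = 100L)
  mm <- mft_manifold_metrics(ms, n_samples = 500L, rng_seed = 2L)
  expect_equal(mm$capacity, 2, tolerance = 0.1)     # classical limit alpha = 2
  ec <- empirical_capacity(ms, n_dichotomies = 40L, rng_seed = 3L)
  expect_equal(ec$capacity, 2, tolerance = 0.1)
  # the two routes agree (mean-field vs separability oracle)
  expect_lt(abs(mm$capacity - ec$capacity) / ec$capacity, 0.15)
})

test_that("estimated dimensionality respects a subspace confinement bound", {
  ms <- fix_subspace_manifolds(d = 4L)
  mm <- mft_manifold_metrics(ms, n_samples = 300L, rng_seed = 2L)
  expect_lte(mm$dimension, 4 + 0.5)
  expect_gt(mm$dimension, 1)
})

test_that("geometry is invariant to rotation and positive rescaling", {
  ms <- fix_subspace_manifolds()
  mm <- mft_manifold_metrics(ms, n_samples = 300L, rng_seed = 2L)
  # both transforms leave the geometry invariant in distribution; numerically
  # the SVD axis basis can flip sign or rotate at near-ties, which reshuffles
  # the Gaussian fields across axes, so allow small Monte-Carlo wiggle
  ms_s <- ms
  ms_s$points <- lapply(ms$points, function(p) p * 3.7)
  mm_s <- mft_manifold_metrics(ms_s, n_samples = 300L, rng_seed = 2L)
  expect_equal(mm_s[c("capacity", "radius", "dimension")],
               mm[c("capacity", "radius", "dimension")], tolerance = 0.02)
  set.seed(9)
  N <- ncol(ms$points[[1]])
  rot <- qr.Q(qr(matrix(rnorm(N * N), N, N)))
  ms2 <- ms
  ms2$points <- lapply(ms$points, function(p) (p %*% rot) * 3.7)
  mm2 <- mft_manifold_metrics(ms2, n_samples = 300L, rng_seed = 2L)
  expect_equal(mm2$capacity, mm$capacity, tolerance = 0.02)
  expect_equal(mm2$dimension, mm$dimension, tolerance = 0.02)
  expect_equal(mm2$radius, mm$radius, tolerance = 0.02)
})

test_that("center correlation measures alignment and ignores labels", {
  # mutually orthogonal zero-mean centers -> ~0
  ortho <- rbind(c(1, -1, 0, 0, 0, 0),
                 c(0, 0, 1, -1, 0, 0),
                 c(0, 0, 0, 0, 1, -1))
  ms_o <- list(points = lapply(1:3, function(i)
    rbind(ortho[i, ], ortho[i, ])))  # two identical points per manifold
  expect_equal(center_correlation(ms_o), 0)
  # identical up to positive scaling -> 1
  v <- c(0.3, 1.2, -0.4, 2.2)
  ms_s <- list(points = lapply(c(1, 2.5, 7), function(s) rbind(s * v, s * v)))
  expect_equal(center_correlation(ms_s), 1)
  # invariance to permuting manifold labels
  ms <- fix_subspace_manifolds()
  cc1 <- center_correlation(ms)
  ms_p <- ms; ms_p$points <- ms_p$points[sample(length(ms_p$points))]
  expect_equal(center_correlation(ms_p), cc1)
})

test_that("the separability oracle is exact on constructed cases", {
  # two linearly separable point clouds (homogeneous): x vs -x offsets
  set.seed(14)
  w_true <- rnorm(10)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- sign(X %*% w_true)
  Z <- X * as.vector(y)           # all rows satisfy <w_true, z> > 0
  expect_true(numtwin:::.separable_gilbert(Z))
  # origin inside the hull: +v and -v both present
  v <- rnorm(10)
  expect_false(numtwin:::.separable_gilbert(rbind(v, -v)))
  # Cover regime: P/N = 0.5 (10 points, 20 dims) -> essentially always separable
  P10 <- matrix(rnorm(10 * 20), 10, 20)
  sgn <- rep(c(1, -1), 5)
  expect_true(numtwin:::.separable_gilbert(P10 * sgn))
  # two manifolds: one dichotomy, a single feasibility test
  ms2 <- list(points = list(matrix(rnorm(5 * 8), 5, 8),
                            matrix(rnorm(5 * 8) + 4, 5, 8)))
  ec <- empirical_capacity(ms2, n_dichotomies = 10L, rng_seed = 1L)
  expect_true(is.finite(ec$capacity) || is.na(ec$capacity))
  expect_error(empirical_capacity(ms2, n_dichotomies = 0L), "n_dichotomies")
})

test_that("degenerate manifold inputs are rejected", {
  same <- list(points = lapply(1:3, function(i) matrix(1, 4, 6)),
               result_values = 1:3)
  expect_error(mft_manifold_metrics(same), "degenerate")
  one <- list(points = list(matrix(rnorm(8), 2, 4)))
  expect_error(mft_manifold_metrics(one), "at least 2")
  expect_error(center_correlation(one), "at least 2")
})
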