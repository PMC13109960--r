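# a hand-built sweep trace is enough for the matching mechanics: matching
# consumes only sweep$trace
fake_sweep <- function(gains = c(1, 2, 3), iterations = c(0, 100, 200),
                       acc_fn = function(g, it) 0.05 + it / 250 / g) {
  tr <- expand.grid(gain = gains, iteration = iterations)
  tr$accuracy <- mapply(acc_fn, tr$gain, tr$iteration)
  structure(list(trace = tr, records = list(),
                 train_config = list(eval_every = 100L)),
            class = "gain_sweep")
}

test_that("accuracy normalization is exact min-max", {
  b <- list(Am = 0.05, AM = 0.85)
  expect_equal(normalize_accuracy(0.05, b), 0)
  expect_equal(normalize_accuracy(0.85, b), 1)
  expect_equal(normalize_accuracy(0.45, b), 0.5)
  expect_error(normalize_accuracy(0.5, list(Am = 0.3, AM = 0.3)), "degenerate")
})

test_that("children match to the closest gain; ties break low", {
  sw <- fake_sweep()
  b <- sweep_accuracy_bounds(sw)
  tr200 <- sw$trace[sw$trace$iteration == 200, ]
  a_norm <- normalize_accuracy(tr200$accuracy[order(tr200$gain)], b)
  cohort <- data.frame(id = c("c1", "c2"), group = c("TD", "MLD"),
                       normalized_score = c(a_norm[1], a_norm[3]))
  m <- match_children(sw, cohort, 200L)
  expect_equal(m$gain, c(1, 3))
  expect_equal(m$distance, c(0, 0))
  # exact tie between two gains -> the lower one is returned
  sw2 <- fake_sweep(acc_fn = function(g, it) {
    if (it == 0) 0.05 else if (g == 2) 0.50 else if (g == 1) 0.60 else 0.40
  })
  b2 <- sweep_accuracy_bounds(sw2)
  mid <- normalize_accuracy(0.55, b2)  # equidistant from gains 1 and 2
  tie <- match_children(sw2, data.frame(id = "t", group = "TD",
                                        normalized_score = mid), 100L)
  expect_equal(tie$gain, 1)
  expect_error(match_children(sw, cohort, 999L), "missing checkpoint")
})

test_that("closed-loop recovery returns the generating gain and iteration", {
  sw <- fake_sweep(gains = c(1, 2, 3, 4, 5),
                   iterations = seq(0, 500, by = 100))
  b <- sweep_accuracy_bounds(sw)
  t_star <- 300L
  tr <- sw$trace[sw$trace$iteration == t_star, ]
  tr <- tr[order(tr$gain), ]
  cohort <- data.frame(id = sprintf("p%d", seq_len(nrow(tr))),
                       group = "TD",
                       normalized_score = normalize_accuracy(tr$accuracy, b))
  m <- match_children(sw, cohort, t_star)
  expect_equal(m$gain, tr$gain)
  expect_equal(max(m$distance), 0)
  best <- select_best_iteration(sw, cohort)
  expect_equal(best$iteration, t_star)
  expect_equal(unname(best$mean_distance[as.character(t_star)]), 0)
  expect_error(select_best_iteration(sw, cohort, integer(0)), "empty")
})

test_that("fitted distances never exceed permuted distances", {
  sw <- fake_sweep(gains = 1:5, iterations = c(0, 100))
  b <- sweep_accuracy_bounds(sw)
  set.seed(3)
  cohort <- data.frame(id = sprintf("c%d", 1:12),
                       group = rep(c("TD", "MLD"), 6),
                       normalized_score = runif(12))
  m <- match_children(sw, cohort, 100L)
  pc <- permutation_control(m, n_perm = 300L, rng_seed = 2L)
  expect_gte(pc$perm_mean + 1e-12, pc$fitted_mean)
  # argmin optimality holds for every single permutation draw
  expect_true(all(pc$perm_means >= pc$fitted_mean - 1e-12))
  # the identity assignment reproduces the fitted distance exactly
  expect_equal(mean(abs(m$normalized_accuracy - m$normalized_score)),
               pc$fitted_mean)
  expect_error(permutation_control(m, n_perm = 0L), "n_perm")
})

test_that("group statistics match hand computations", {
  gs <- group_stats(c(1, 2, 3), c(4, 5, 6))
  expect_equal(gs$cohens_d, -3)        # pooled SD 1, mean difference -3
  expect_equal(gs$t, -3.674, tolerance = 1e-3)
  same <- group_stats(c(2, 2, 3), c(2, 2, 3))
  expect_equal(same$cohens_d, 0)
  degen <- group_stats(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(degen$degenerate)
  expect_true(is.infinite(degen$cohens_d))
  expect_error(group_stats(1, c(1, 2)), "insufficient")
})
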