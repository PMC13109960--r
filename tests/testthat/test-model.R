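test_that("gain-ReLU matches its definition and is positively homogeneous", {
  expect_equal(gain_relu(2, 1), 2)
  expect_equal(gain_relu(-3, 4), 0)
  expect_equal(gain_relu(1, 2.5), 2.5)
  x <- seq(-5, 5, length.out = 101)
  for (G in c(0.5, 1, 2.5, 5)) {
    expect_identical(gain_relu(x, G), G * gain_relu(x, 1))
  }
  expect_error(gain_relu(1, 0), "positive")
  expect_error(gain_relu(1, -2), "positive")
})

test_that("model construction is seeded, 19-way, and gain-independent at init", {
  cfg <- model_config("desk", gain = 1 + 0.25 * 16, rng_seed = 5L)
  expect_equal(cfg$gain, 5)
  m1 <- build_model(cfg)
  m2 <- build_model(model_config("desk", gain = 2.0, rng_seed = 5L))
  expect_identical(m1$params, m2$params)  # gain does not enter initialization
  expect_equal(nrow(m1$params$W_out), 19L)
  m3 <- build_model(model_config("desk", gain = 1, rng_seed = 6L))
  expect_false(identical(m1$params$V1.W_in, m3$params$V1.W_in))
  expect_error(build_model(model_config("desk", n_classes = 10L)), "19-way")
  expect_error(model_config("desk", gain = -1), "positive")
})

test_that("forward pass returns non-negative last-timestep activations", {
  m <- build_model(model_config("desk", gain = 2, rng_seed = 1L,
                                channels = c(V1 = 4L, V2 = 6L, V3 = 6L,
                                             IPS = 6L)))
  set.seed(3)
  X <- matrix(runif(11760 * 8), 11760, 8)
  out <- forward_with_activations(m, X)
  expect_equal(dim(out$scores), c(19L, 8L))
  expect_true(all(out$response %in% 0:18))
  expect_equal(names(out$activations), c("V1", "V2", "V3", "IPS"))
  for (a in out$activations) {
    expect_true(all(a >= 0))
    expect_equal(ncol(a), 8L)
  }
  # single 3 x 28 x 140 array input
  one <- forward_with_activations(m, array(runif(11760), c(3, 28, 140)))
  expect_equal(ncol(one$scores), 1L)
  expect_error(forward_with_activations(m, matrix(0, 100, 2)), "11760")
})

test_that("with batch statistics, gain rescales every layer by exactly G", {
  # the frozen batch norm standardizes each channel, so in training mode the
  # whole hidden stack is positively homogeneous in the gain: h_l(G) = G h_l(1)
  ch <- c(V1 = 4L, V2 = 6L, V3 = 6L, IPS = 6L)
  m1 <- build_model(model_config("desk", gain = 1, rng_seed = 2L, channels = ch))
  m3 <- build_model(model_config("desk", gain = 3, rng_seed = 2L, channels = ch))
  set.seed(9)
  X <- matrix(runif(11760 * 16), 11760, 16)
  f1 <- model_forward(m1, X, mode = "train", capture_layers = c("V1", "IPS"))
  f3 <- model_forward(m3, X, mode = "train", capture_layers = c("V1", "IPS"))
  # exact up to the batch-norm epsilon (sqrt(G^2 v + eps) != G sqrt(v + eps)),
  # a relative perturbation of order eps/var ~ 1e-5 per layer
  expect_equal(f3$acts$V1, 3 * f1$acts$V1, tolerance = 1e-4)
  expect_equal(f3$acts$IPS, 3 * f1$acts$IPS, tolerance = 1e-3)
  # hence the logits are temperature-scaled by G (up to the shared bias)
  expect_equal(f3$logits, 3 * f1$logits, tolerance = 1e-3)
})

test_that("backpropagation matches finite differences", {
  set.seed(1)
  m <- build_model(model_config("desk", gain = 2.5, rng_seed = 3L,
                                channels = c(V1 = 2L, V2 = 3L, V3 = 3L,
                                             IPS = 3L)))
  B <- 4L
  X <- matrix(runif(11760 * B), 11760, B)
  y <- sample(0:18, B, replace = TRUE)
  fw <- model_forward(m, X, "train", keep_caches = TRUE)
  bw <- model_backward(m, fw, y)
  eps <- 1e-5
  for (nm in c("V1.W_in", "V3.W_lat", "W_out", "b_out")) {
    ii <- sample(length(m$params[[nm]]), 3L)
    for (i in ii) {
      m2 <- m
      m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      l1 <- model_backward(m2, model_forward(m2, X, "train", TRUE), y)$loss
      m2$params[[nm]][i] <- m2$params[[nm]][i] - 2 * eps
      l0 <- model_backward(m2, model_forward(m2, X, "train", TRUE), y)$loss
      expect_equal(bw$grads[[nm]][i], (l1 - l0) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("batch statistics standardize pre-activations during training", {
  # spot-check through the public surface: a one-channel batch-norm pass
  z <- matrix(rnorm(5 * 200, mean = 3, sd = 7), 5, 200)
  out <- numtwin:::bn_forward(z, C = 5L,
                              state = list(rm = numeric(5), rv = rep(1, 5)),
                              mode = "train")
  zn <- out$Zn; dim(zn) <- c(5, 200)
  expect_equal(rowMeans(zn), rep(0, 5), tolerance = 1e-10)
  expect_equal(apply(zn, 1, sd) * sqrt(199 / 200), rep(1, 5), tolerance = 1e-3)
})
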