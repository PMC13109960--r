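# Shared fixtures, memoized per test session. The desk sweep (5 gains x 600
# iterations) is the expensive one; it is built once on first use and shared
# by the training, matching and acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# small glyph bank for fast structural tests
fix_bank <- function() memo("bank_small", build_glyph_bank(
  "handwritten_synthetic", n_variants = 12L, rng_seed = 42L))

fix_problems <- function() memo("problems", enumerate_problems())

# small materialized dataset (4 variants/problem)
fix_dataset_small <- function() memo("ds_small", build_dataset(
  fix_problems(), fix_bank(), variants_per_problem = 4L, rng_seed = 7L))

# study-condition desk dataset: full glyph bank, 100 variants per problem,
# rendered lazily
fix_dataset_desk <- function() memo("ds_desk", build_dataset(
  fix_problems(),
  memo("bank_full", build_glyph_bank("handwritten_synthetic",
                                     n_variants = 100L, rng_seed = 42L)),
  variants_per_problem = 100L, rng_seed = 7L, materialize = FALSE))

# the desk gain sweep (shared across test files; several minutes of CPU)
fix_desk_sweep <- function() memo("desk_sweep", {
  cfg <- train_config("desk", rng_seed = 11L)
  mcfg <- model_config("desk", rng_seed = 3L)
  train_sweep(fix_dataset_desk(), cfg, mcfg)
})

# tiny sweep for fast mechanics tests: 2 gains, 30 iterations
fix_tiny_sweep <- function() memo("tiny_sweep", {
  cfg <- train_config("desk", gains = c(1, 5), max_iterations = 30L,
                      eval_every = 10L, eval_per_problem = 2L,
                      rng_seed = 11L)
  mcfg <- model_config("desk", rng_seed = 3L)
  train_sweep(fix_dataset_small(), cfg, mcfg)
})

# synthetic manifold sets
fix_point_manifolds <- function(P = 20L, N = 100L, seed = 5L) {
  set.seed(seed)
  pts <- lapply(seq_len(P), function(i) matrix(rnorm(N), 1, N))
  structure(list(points = pts, result_values = seq_len(P), n_manifolds = P,
                 points_per_manifold = rep(1L, P)),
            class = "manifold_set")
}

fix_subspace_manifolds <- function(P = 10L, N = 60L, d = 4L, m = 15L,
                                   seed = 6L) {
  set.seed(seed)
  pts <- lapply(seq_len(P), function(i) {
    ctr <- rnorm(N) * 3
    sub <- matrix(rnorm(N * d), N, d)
    t(ctr + sub %*% matrix(rnorm(d * m), d, m))
  })
  structure(list(points = pts, result_values = seq_len(P), n_manifolds = P,
                 points_per_manifold = rep(as.integer(m), P)),
            class = "manifold_set")
}
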