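test_that("problem enumeration reproduces the task combinatorics", {
  p <- fix_problems()
  expect_equal(nrow(p), 380L)
  expect_equal(sum(p$operation == "addition"), 190L)
  expect_equal(sum(p$operation == "subtraction"), 190L)
  expect_true(all(table(p$result) == 20L))
  expect_true(all(p$result == ifelse(p$operation == "addition",
                                     p$operand1 + p$operand2,
                                     p$operand1 - p$operand2)))
  expect_true(all(p$operand1 >= 0 & p$operand1 <= 18))
  expect_true(all(p$operand2 >= 0 & p$operand2 <= 18))
  expect_false(anyDuplicated(p[c("operand1", "operand2", "operation")]) > 0)

  # closed form |additions| = (R+1)(R+2)/2 against brute-force enumeration
  for (R in c(1L, 3L, 18L)) {
    grid <- expand.grid(a = 0:R, b = 0:R)
    brute <- sum(grid$a + grid$b <= R)
    expect_equal(nrow(enumerate_problems(0L, R, "addition")), brute)
    expect_equal(brute, (R + 1) * (R + 2) / 2)
  }
  tiny <- enumerate_problems(0L, 1L, "addition")
  expect_equal(nrow(tiny), 3L)

  expect_error(enumerate_problems(operations = character(0)), "at least one")
})

test_that("glyph banks are reproducible, bounded and varied", {
  bank <- fix_bank()
  expect_true(all(bank$glyphs$blank == 0))
  rng <- range(unlist(lapply(bank$glyphs, range)))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  # bit-identical rebuild under the same seed
  again <- build_glyph_bank("handwritten_synthetic", 12L, 42L)
  expect_identical(bank$glyphs, again$glyphs)
  # distinct variants per character under the handwritten style
  for (ch in c("0", "7", "plus")) {
    g <- bank$glyphs[[ch]]
    expect_equal(ncol(g), 12L)
    expect_false(any(duplicated(t(g))))
  }
  # printed style renders a fixed shape, moved by whole pixels: every variant
  # has identical ink mass
  pb <- build_glyph_bank("printed", 6L, 1L)
  ink <- colSums(pb$glyphs[["5"]])
  expect_true(all(abs(ink - ink[1]) < 1e-9))
  expect_error(build_glyph_bank("cursive"), "arg")
})

test_that("problem rendering follows the five-slot layout", {
  bank <- fix_bank()
  spec <- data.frame(operand1 = 10L, operand2 = 2L, operation = "subtraction")
  img <- render_problem(spec, bank, variant_idx = c(1, 1, 1, 1, 1))
  expect_equal(dim(img), c(3L, 28L, 140L))
  slot <- function(k) img[, , ((k - 1) * 28 + 1):(k * 28)]
  expect_equal(as.vector(slot(1)),
               as.vector(bank$glyphs[["1"]][, 1]))  # tens of 10
  expect_equal(as.vector(slot(2)), as.vector(bank$glyphs[["0"]][, 1]))
  expect_equal(as.vector(slot(3)), as.vector(bank$glyphs[["minus"]][, 1]))
  expect_true(all(slot(4) == 0))                    # blank tens of 2
  expect_equal(as.vector(slot(5)), as.vector(bank$glyphs[["2"]][, 1]))

  both0 <- render_problem(
    data.frame(operand1 = 0L, operand2 = 0L, operation = "addition"), bank,
    variant_idx = rep(1, 5))
  expect_true(all(both0[, , 1:28] == 0) && all(both0[, , 85:112] == 0))

  expect_error(render_problem(
    data.frame(operand1 = 100L, operand2 = 2L, operation = "addition"), bank),
    "unsupported operand")
})

test_that("datasets are balanced, split-disjoint and seed-deterministic", {
  ds <- fix_dataset_small()
  expect_equal(length(ds$labels), 380L * 4L)
  expect_equal(sum(ds$split == "train"), 380L * 2L)
  # per-split per-result balance: 20 problems x 2 variants
  for (sp in c("train", "test")) {
    expect_true(all(table(ds$labels[ds$split == sp]) == 40L))
  }
  # train/test variant tuples are disjoint within every problem
  key <- apply(ds$plan, 1, paste, collapse = ",")
  for (i in sample(380L, 20L)) {
    rows <- which(ds$problem_idx == i)
    expect_false(any(key[rows][ds$split[rows] == "train"] %in%
                       key[rows][ds$split[rows] == "test"]))
  }
  # pure function of (inputs, seed)
  ds2 <- build_dataset(fix_problems(), fix_bank(), 4L, rng_seed = 7L)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$split, ds2$split)
  # lazy rendering agrees with materialized images
  lazy <- build_dataset(fix_problems(), fix_bank(), 4L, rng_seed = 7L,
                        materialize = FALSE)
  idx <- sample(length(ds$labels), 25L)
  expect_equal(dataset_images(lazy, idx), ds$images[, idx])
  expect_equal(dim(dataset_image(ds, 17L)), c(3L, 28L, 140L))

  expect_error(build_dataset(fix_problems(), fix_bank(), 5L), "even")
})
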