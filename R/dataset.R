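#' Build a balanced stimulus dataset
#'
#' Renders `variants_per_problem` image variants for every problem, assigning
#' half of each problem's variants to the training split and half to the test
#' split (seeded random assignment, disjoint variant tuples). Because the task
#' has exactly 20 problems per result value, both splits are balanced over the
#' 19 result classes by construction.
#'
#' @param problems Problem data.frame from [enumerate_problems()].
#' @param bank Glyph bank from [build_glyph_bank()].
#' @param variants_per_problem Even integer; number of rendered variants per
#'   problem (half train, half test).
#' @param rng_seed Integer seed; the dataset is a pure function of
#'   (problems, bank, variants_per_problem, rng_seed).
#' @param materialize If `TRUE` (default) all images are rendered into one
#'   `11760 x N` matrix (channel-first `3 x 28 x 140` per column). If `FALSE`
#'   only the render plan is stored and [dataset_images()] renders on demand.
#' @return An object of class `stimulus_dataset` with fields `images` (matrix
#'   or `NULL`), `labels` (result per image), `problem_idx`, `split`
#'   (`"train"`/`"test"`), `specs`, `plan` (glyph variant indices per slot),
#'   `dims = c(3, 28, 140)`.
#' @export
build_dataset <- function(problems, bank, variants_per_problem = 100L,
                          rng_seed = 1L, materialize = TRUE) {
  stopifnot(inherits(bank, "glyph_bank"))
  variants_per_problem <- as.integer(variants_per_problem)
  if (variants_per_problem < 2L || variants_per_problem %% 2L != 0L) {
    stop("`variants_per_problem` must be a positive even integer")
  }
  n_prob <- nrow(problems)
  n_img <- n_prob * variants_per_problem

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))

  # per-image slot characters
  slot_mat <- t(vapply(seq_len(n_prob), function(i) {
    .slot_chars(problems$operand1[i], problems$operand2[i], problems$operation[i])
  }, character(5)))

  # sample distinct glyph-variant tuples per problem so train/test variants
  # can never coincide
  plan <- matrix(1L, n_img, 5L)
  problem_idx <- rep(seq_len(n_prob), each = variants_per_problem)
  for (i in seq_len(n_prob)) {
    rows <- ((i - 1L) * variants_per_problem + 1L):(i * variants_per_problem)
    free <- which(slot_mat[i, ] != "blank")
    repeat {
      draw <- matrix(sample.int(bank$n_variants,
                                variants_per_problem * length(free),
                                replace = TRUE),
                     variants_per_problem, length(free))
      key <- apply(draw, 1, paste, collapse = ",")
      if (!anyDuplicated(key)) break
    }
    plan[rows, free] <- draw
  }

  # seeded random half/half split within each problem's variants
  split <- character(n_img)
  half <- variants_per_problem %/% 2L
  for (i in seq_len(n_prob)) {
    rows <- ((i - 1L) * variants_per_problem + 1L):(i * variants_per_problem)
    tr <- sample(rows, half)
    split[rows] <- "test"
    split[tr] <- "train"
  }

  ds <- structure(list(
    images = NULL,
    labels = problems$result[problem_idx],
    problem_idx = problem_idx,
    split = split,
    specs = problems,
    plan = plan,
    slot_mat = slot_mat,
    variants_per_problem = variants_per_problem,
    rng_seed = as.integer(rng_seed),
    bank = bank,
    dims = c(GLYPH_CHANNELS, GLYPH_SIDE, 5L * GLYPH_SIDE)
  ), class = "stimulus_dataset")

  if (materialize) {
    ds$images <- dataset_images(ds, seq_len(n_img))
  }
  ds
}

#' Render (or fetch) dataset images
#'
#' @param ds A `stimulus_dataset`.
#' @param idx Image indices.
#' @return `11760 x length(idx)` matrix; each column is a channel-first
#'   `3 x 28 x 140` image.
#' @export
dataset_images <- function(ds, idx) {
  if (!is.null(ds$images)) return(ds$images[, idx, drop = FALSE])
  n <- length(idx)
  M <- matrix(0, 5L * GLYPH_LEN, n)
  chars <- ds$slot_mat[ds$problem_idx[idx], , drop = FALSE]
  for (s in 1:5) {
    rows <- ((s - 1L) * GLYPH_LEN + 1L):(s * GLYPH_LEN)
    cs <- chars[, s]
    for (ch in unique(cs)) {
      if (ch == "blank") next
      cols <- which(cs == ch)
      M[rows, cols] <- ds$bank$glyphs[[ch]][, ds$plan[idx[cols], s]]
    }
  }
  M
}

#' Extract one image as a 3 x 28 x 140 array
#' @param ds A `stimulus_dataset`.
#' @param i Image index.
#' @export
dataset_image <- function(ds, i) {
  array(dataset_images(ds, i), ds$dims)
}

#' @export
print.stimulus_dataset <- function(x, ...) {
  cat(sprintf(
    "<stimulus_dataset> %d problems x %d variants = %d images (%d train / %d test)%s\n",
    nrow(x$specs), x$variants_per_problem, length(x$labels),
    sum(x$split == "train"), sum(x$split == "test"),
    if (is.null(x$images)) " [lazy]" else ""))
  invisible(x)
}
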