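# Procedural digit/operator glyph synthesis.
#
# Glyphs are drawn as stroke paths (polylines and sampled arcs) rasterized on a
# 28 x 28 grid with an anti-aliased pen, then replicated over 3 channels.
# The handwritten style jitters control points, pen thickness and pose per
# variant; the printed style renders one fixed glyph shape per character and
# only translates it by whole pixels. Intensities live in [0, 1], background 0.

GLYPH_SIDE <- 28L
GLYPH_CHANNELS <- 3L
GLYPH_LEN <- GLYPH_CHANNELS * GLYPH_SIDE * GLYPH_SIDE
GLYPH_CHARS <- c(as.character(0:9), "plus", "minus", "blank")

# sampled elliptical arc in the unit box (y grows downward)
.arc <- function(cx, cy, rx, ry, deg0, deg1, n = 14) {
  th <- seq(deg0, deg1, length.out = n) * pi / 180
  cbind(cx + rx * cos(th), cy - ry * sin(th))
}

# each character: list of strokes; a stroke is an n x 2 matrix of unit coords.
# plus/minus are assembled from the same stroke primitives as "1": a vertical
# bar, and its 90-degree rotation as the horizontal bar.
.glyph_skeleton <- function(ch) {
  v_bar <- cbind(c(0.5, 0.5), c(0.21, 0.79))        # the "1" primitive
  h_bar <- v_bar[, 2:1]                             # rotated copy
  switch(ch,
    "0" = list(.arc(0.5, 0.5, 0.30, 0.42, 90, 450, 22)),
    "1" = list(cbind(c(0.5, 0.5), c(0.10, 0.90))),
    "2" = list(rbind(.arc(0.5, 0.30, 0.28, 0.22, 160, -20, 12),
                     cbind(c(0.74, 0.24, 0.78), c(0.42, 0.90, 0.90)))),
    "3" = list(rbind(.arc(0.48, 0.29, 0.26, 0.20, 150, -80, 12),
                     .arc(0.48, 0.71, 0.29, 0.22, 80, -150, 12))),
    "4" = list(cbind(c(0.62, 0.22, 0.82), c(0.10, 0.60, 0.60)),
               cbind(c(0.66, 0.66), c(0.35, 0.90))),
    "5" = list(cbind(c(0.76, 0.30, 0.28), c(0.10, 0.10, 0.44)),
               .arc(0.48, 0.66, 0.28, 0.24, 130, -130, 14)),
    "6" = list(rbind(.arc(0.52, 0.40, 0.28, 0.34, 70, 180, 10),
                     .arc(0.50, 0.68, 0.24, 0.22, 180, -180, 18))),
    "7" = list(cbind(c(0.22, 0.80, 0.46), c(0.12, 0.12, 0.90))),
    "8" = list(.arc(0.5, 0.30, 0.21, 0.19, 90, 450, 16),
               .arc(0.5, 0.69, 0.25, 0.22, 90, 450, 16)),
    "9" = list(.arc(0.52, 0.33, 0.24, 0.23, 0, 360, 16),
               cbind(c(0.76, 0.62), c(0.33, 0.90))),
    "plus"  = list(v_bar, h_bar),
    "minus" = list(h_bar),
    "blank" = list(),
    stop("unknown glyph character: ", ch)
  )
}

# rasterize strokes (pixel coords) with a round pen; returns 28 x 28 matrix
.rasterize_strokes <- function(strokes, thickness, soft = 0.7) {
  g <- matrix(0, GLYPH_SIDE, GLYPH_SIDE)
  if (length(strokes) == 0L) return(g)
  px <- rep(seq_len(GLYPH_SIDE), each = GLYPH_SIDE)  # x (column)
  py <- rep(seq_len(GLYPH_SIDE), times = GLYPH_SIDE) # y (row)
  half <- thickness / 2
  for (s in strokes) {
    n <- nrow(s)
    if (n < 2L) next
    for (k in seq_len(n - 1L)) {
      x1 <- s[k, 1]; y1 <- s[k, 2]; x2 <- s[k + 1L, 1]; y2 <- s[k + 1L, 2]
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      if (len2 < 1e-12) {
        d <- sqrt((px - x1)^2 + (py - y1)^2)
      } else {
        t <- ((px - x1) * dx + (py - y1) * dy) / len2
        t <- pmin(pmax(t, 0), 1)
        d <- sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
      }
      val <- pmin(pmax((half + soft - d) / soft, 0), 1)
      idx <- val > 0
      gv <- pmax(g[cbind(py[idx], px[idx])], val[idx])
      g[cbind(py[idx], px[idx])] <- gv
    }
  }
  g
}

# map unit-box strokes into pixel coordinates with pose parameters
.pose_strokes <- function(strokes, scale, rot, shear, tx, ty, jitter_sd = 0) {
  ctr <- 0.5
  cs <- cos(rot); sn <- sin(rot)
  size <- 18 * scale  # nominal glyph body ~18 px inside the 28 px slot
  lapply(strokes, function(s) {
    if (jitter_sd > 0) s <- s + matrix(stats::rnorm(length(s), 0, jitter_sd), nrow(s), 2)
    x <- s[, 1] - ctr; y <- s[, 2] - ctr
    x <- x + shear * y
    xr <- cs * x - sn * y
    yr <- sn * x + cs * y
    cbind(14.5 + size * xr + tx, 14.5 + size * yr + ty)
  })
}

.render_glyph_variant <- function(ch, style) {
  strokes <- .glyph_skeleton(ch)
  if (ch == "blank") return(matrix(0, GLYPH_SIDE, GLYPH_SIDE))
  if (style == "handwritten_synthetic") {
    posed <- .pose_strokes(strokes,
                           scale = stats::runif(1, 0.86, 1.12),
                           rot = stats::runif(1, -8, 8) * pi / 180,
                           shear = stats::runif(1, -0.12, 0.12),
                           tx = stats::runif(1, -2, 2),
                           ty = stats::runif(1, -2, 2),
                           jitter_sd = 0.02)
    thick <- stats::runif(1, 1.2, 3.0)  # pen 2 +/- 1 px
  } else {  # printed: fixed shape, whole-pixel translation only
    posed <- .pose_strokes(strokes, scale = 1, rot = 0, shear = 0,
                           tx = sample(-2:2, 1), ty = sample(-2:2, 1))
    thick <- 2
  }
  .rasterize_strokes(posed, thickness = thick)
}

# grayscale 28x28 -> channel-first (3, 28, 28) vector
.gray_to_vec <- function(g) {
  arr <- array(0, c(GLYPH_CHANNELS, GLYPH_SIDE, GLYPH_SIDE))
  for (ch in seq_len(GLYPH_CHANNELS)) arr[ch, , ] <- g
  as.vector(arr)
}

#' Build a procedural glyph bank
#'
#' Synthesizes per-character banks of 28 x 28 digit and operator glyphs used to
#' assemble arithmetic stimuli. Characters `0..9`, `plus`, `minus` are drawn
#' from stroke skeletons; the operator glyphs reuse the vertical-bar primitive
#' of the character "1" (the minus sign is its 90-degree rotation). The `blank`
#' character is an all-zero (black) image.
#'
#' @param style One of `"handwritten_synthetic"` (stroke jitter, variable pen,
#'   random pose), `"printed"` (fixed shapes, whole-pixel translations), or
#'   `"mixed"` (half of the variants from each style).
#' @param n_variants Number of variants per character (>= 1).
#' @param rng_seed Integer seed; banks are bit-reproducible given the seed.
#' @return An object of class `glyph_bank`: a list with `style`, `n_variants`,
#'   `rng_seed` and `glyphs`, a named list mapping each character to a
#'   `2352 x n_variants` matrix of channel-first image vectors in `[0, 1]`
#'   (`blank` holds a single zero column).
#' @export
build_glyph_bank <- function(style = c("handwritten_synthetic", "printed", "mixed"),
                             n_variants = 100L, rng_seed = 1L) {
  style <- match.arg(style)
  stopifnot(n_variants >= 1L)
  glyphs <- vector("list", length(GLYPH_CHARS))
  names(glyphs) <- GLYPH_CHARS
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  for (ch in GLYPH_CHARS) {
    if (ch == "blank") {
      glyphs[[ch]] <- matrix(0, GLYPH_LEN, 1L)
      next
    }
    m <- matrix(0, GLYPH_LEN, n_variants)
    for (v in seq_len(n_variants)) {
      st <- switch(style,
                   handwritten_synthetic = "handwritten_synthetic",
                   printed = "printed",
                   mixed = if (v %% 2L == 1L) "handwritten_synthetic" else "printed")
      m[, v] <- .gray_to_vec(.render_glyph_variant(ch, st))
    }
    glyphs[[ch]] <- m
  }
  structure(list(style = style, n_variants = as.integer(n_variants),
                 rng_seed = as.integer(rng_seed), glyphs = glyphs),
            class = "glyph_bank")
}

#' @export
print.glyph_bank <- function(x, ...) {
  cat(sprintf("<glyph_bank> style=%s, %d variants/character, seed=%d\n",
              x$style, x$n_variants, x$rng_seed))
  invisible(x)
}

# characters occupying the five 28-px slots T1 U1 S T2 U2
.slot_chars <- function(operand1, operand2, operation) {
  if (operand1 >= 100 || operand2 >= 100) {
    stop("unsupported operand: operands above 99 cannot be rendered")
  }
  tens <- function(a) if (a >= 10) as.character(a %/% 10) else "blank"
  units <- function(a) as.character(a %% 10)
  op <- if (operation == "addition") "plus" else "minus"
  c(tens(operand1), units(operand1), op, tens(operand2), units(operand2))
}

#' Render a single arithmetic problem image
#'
#' Concatenates five glyph slots (tens1, units1, operator, tens2, units2) into
#' a channel-first `3 x 28 x 140` stimulus. Single-digit operands receive the
#' blank (black) glyph in their tens slot.
#'
#' @param spec A one-row problem data.frame (`operand1`, `operand2`,
#'   `operation`) as from [enumerate_problems()].
#' @param bank A [build_glyph_bank()] object.
#' @param variant_idx Optional integer vector of length 5 choosing the glyph
#'   variant per slot; sampled from the bank otherwise (uses the current RNG).
#' @return A `3 x 28 x 140` array.
#' @export
render_problem <- function(spec, bank, variant_idx = NULL) {
  stopifnot(inherits(bank, "glyph_bank"))
  chars <- .slot_chars(spec$operand1[1], spec$operand2[1], spec$operation[1])
  if (is.null(variant_idx)) {
    variant_idx <- vapply(chars, function(ch) {
      if (ch == "blank") 1L else sample.int(bank$n_variants, 1L)
    }, integer(1))
  }
  img <- numeric(5L * GLYPH_LEN)
  for (s in 1:5) {
    img[((s - 1L) * GLYPH_LEN + 1L):(s * GLYPH_LEN)] <-
      bank$glyphs[[chars[s]]][, variant_idx[s]]
  }
  array(img, c(GLYPH_CHANNELS, GLYPH_SIDE, 5L * GLYPH_SIDE))
}
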