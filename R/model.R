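# Gain-modulated recurrent convolutional network ("pDNN").
#
# Four convolutional blocks named after the dorsal visual stream (V1, V2, V3,
# IPS), each with within-block recurrence: the block input is convolved once,
# and on every recurrent timestep a lateral 3x3 convolution of the previous
# hidden state is added before frozen batch normalization and the gain-ReLU.
# Representational analyses read the last timestep of each block. A global
# average pool and a 19-way linear readout (one unit per possible answer 0-18)
# produce the class scores; the readout is linear and carries no gain.

#' Model configuration
#'
#' @param profile `"desk"` (reduced channel widths for laptop-scale sweeps) or
#'   `"full"` (the full-scale architecture).
#' @param gain Neural gain `G` applied at every nonlinearity (excitability).
#' @param rng_seed Seed for weight initialization.
#' @param n_classes Number of possible answers; the default task has 19 (0-18).
#' @param channels Named per-block channel widths; defaults depend on profile
#'   (desk = full widths divided by 4).
#' @param recurrence Named per-block recurrent timestep counts
#'   (default V1:1, V2:2, V3:4, IPS:2).
#' @return A `model_config` list.
#' @export
model_config <- function(profile = c("desk", "full"), gain = 1,
                         rng_seed = 1L, n_classes = 19L,
                         channels = NULL, recurrence = NULL) {
  profile <- match.arg(profile)
  if (gain <= 0) stop("gain must be positive")
  if (is.null(channels)) {
    channels <- if (profile == "full") {
      c(V1 = 64L, V2 = 128L, V3 = 256L, IPS = 512L)
    } else {
      c(V1 = 8L, V2 = 16L, V3 = 16L, IPS = 16L)
    }
  }
  if (is.null(recurrence)) recurrence <- c(V1 = 1L, V2 = 2L, V3 = 4L, IPS = 2L)
  structure(list(profile = profile, gain = gain,
                 rng_seed = as.integer(rng_seed),
                 n_classes = as.integer(n_classes),
                 channels = channels, recurrence = recurrence),
            class = "model_config")
}

#' The full-scale gain grid
#'
#' The 17-value excitability grid `G = 1 + 0.25 k`, `k = 0..16`.
#' @return Numeric vector of 17 gains from 1 to 5.
#' @export
gain_grid_full <- function() 1 + 0.25 * (0:16)

#' Build a gain-modulated recurrent network
#'
#' @param config A [model_config()].
#' @return A `pdnn_model` list holding per-block convolution gathers, weights,
#'   frozen-batch-norm running statistics, and the linear readout. Two builds
#'   with equal seeds have identical initial weights (the gain does not enter
#'   initialization).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  if (config$n_classes != 19L) {
    stop("the default arithmetic task requires a 19-way readout (answers 0-18)")
  }
  ch <- config$channels
  rec <- config$recurrence
  # V1 uses a 7x7 window with effective stride 4 (conv + pool fused), as in
  # CORnet-S; total downsampling 16x leaves a 2 x 9 IPS grid on 28 x 140 input.
  arch <- list(
    V1  = list(K = 5L, stride = 4L, pad = 2L),
    V2  = list(K = 3L, stride = 2L, pad = 1L),
    V3  = list(K = 3L, stride = 2L, pad = 1L),
    IPS = list(K = 3L, stride = 1L, pad = 1L)
  )
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$rng_seed)

  Cin <- 3L; H <- 28L; W <- 140L
  blocks <- list()
  params <- list()
  for (nm in names(arch)) {
    a <- arch[[nm]]
    Cout <- ch[[nm]]; T_rec <- rec[[nm]]
    g_in <- make_conv_gather(Cin, H, W, a$K, a$stride, a$pad)
    g_lat <- if (T_rec > 1L) {
      make_conv_gather(Cout, g_in$Ho, g_in$Wo, 3L, 1L, 1L)
    } else NULL
    W_in <- matrix(stats::rnorm(Cout * g_in$CKK, 0, sqrt(2 / g_in$CKK)),
                   Cout, g_in$CKK)
    params[[paste0(nm, ".W_in")]] <- W_in
    if (T_rec > 1L) {
      W_lat <- matrix(stats::rnorm(Cout * g_lat$CKK, 0, sqrt(2 / g_lat$CKK)),
                      Cout, g_lat$CKK)
      params[[paste0(nm, ".W_lat")]] <- W_lat
    }
    bn <- lapply(seq_len(T_rec), function(t) {
      list(rm = numeric(Cout), rv = rep(1, Cout))
    })
    blocks[[nm]] <- list(name = nm, Cin = Cin, Cout = Cout, T_rec = T_rec,
                         gather_in = g_in, gather_lat = g_lat, bn = bn,
                         P = g_in$P)
    Cin <- Cout; H <- g_in$Ho; W <- g_in$Wo
  }
  # readout pools IPS over the height dimension only: the stimulus is a wide
  # 1:5 equation strip, so horizontal (slot) structure is preserved for the
  # linear readout while vertical detail is averaged out
  C_top <- Cin; Ho_top <- blocks$IPS$gather_in$Ho; Wo_top <- blocks$IPS$gather_in$Wo
  jj <- seq_len(C_top * Ho_top * Wo_top)
  cc <- (jj - 1L) %% C_top + 1L
  wo <- (jj - 1L) %/% (C_top * Ho_top) + 1L
  n_read <- C_top * Wo_top
  pool <- Matrix::sparseMatrix(
    i = cc + C_top * (wo - 1L), j = jj,
    x = 1 / Ho_top, dims = c(n_read, C_top * Ho_top * Wo_top))
  params[["W_out"]] <- matrix(stats::rnorm(config$n_classes * n_read, 0,
                                           sqrt(1 / n_read)),
                              config$n_classes, n_read)
  params[["b_out"]] <- matrix(0, config$n_classes, 1L)

  structure(list(config = config, blocks = blocks, params = params,
                 pool = pool, n_units = vapply(blocks, function(b)
                   b$Cout * b$P, numeric(1))),
            class = "pdnn_model")
}

#' @export
print.pdnn_model <- function(x, ...) {
  cat(sprintf("<pdnn_model> profile=%s gain=%.2f | %s | %d params\n",
              x$config$profile, x$config$gain,
              paste(sprintf("%s:%d", names(x$blocks),
                            vapply(x$blocks, `[[`, integer(1), "Cout")),
                    collapse = " "),
              sum(vapply(x$params, length, numeric(1)))))
  invisible(x)
}

# Forward pass. X: 11760 x B matrix. mode "train" uses batch statistics and
# updates running stats (returned in `model`); "eval" uses running stats.
# keep_caches enables a subsequent model_backward.
model_forward <- function(model, X, mode = c("eval", "train"),
                          keep_caches = FALSE, capture_layers = NULL,
                          v1_xcol = NULL) {
  mode <- match.arg(mode)
  gain <- model$config$gain
  h <- X
  caches <- list()
  acts <- list()
  first <- TRUE
  for (nm in names(model$blocks)) {
    blk <- model$blocks[[nm]]
    cin <- conv_forward(model$params[[paste0(nm, ".W_in")]], blk$gather_in, h,
                        Xcol = if (first) v1_xcol else NULL)
    first <- FALSE
    zin <- cin$Y
    bc <- list(Xcol_in = if (keep_caches) cin$Xcol else NULL,
               X_in = if (keep_caches) h else NULL,
               t = vector("list", blk$T_rec))
    hh <- NULL
    for (t in seq_len(blk$T_rec)) {
      if (t == 1L) {
        z <- zin
        Hcol <- NULL
      } else {
        cl <- conv_forward(model$params[[paste0(nm, ".W_lat")]],
                           blk$gather_lat, hh)
        z <- zin + cl$Y
        Hcol <- if (keep_caches) cl$Xcol else NULL
      }
      bf <- bn_forward(z, blk$Cout, blk$bn[[t]], mode)
      if (mode == "train") model$blocks[[nm]]$bn[[t]] <- bf$state
      hh <- gain * pmax(bf$Zn, 0)
      if (keep_caches) {
        bc$t[[t]] <- list(Zn = bf$Zn, sd = bf$sd, Hcol = Hcol)
      }
    }
    if (keep_caches) caches[[nm]] <- bc
    if (nm %in% capture_layers) acts[[nm]] <- hh
    h <- hh
  }
  pooled <- as.matrix(model$pool %*% h)
  logits <- model$params$W_out %*% pooled + as.vector(model$params$b_out)
  list(model = model, logits = logits, pooled = pooled, h_top = h,
       caches = caches, acts = acts)
}

# Backward pass for softmax cross-entropy. `fw` is the result of
# model_forward(..., mode = "train", keep_caches = TRUE); labels in 0..18.
model_backward <- function(model, fw, labels) {
  B <- ncol(fw$logits)
  gain <- model$config$gain
  # softmax + cross entropy
  lg <- fw$logits
  lg <- lg - rep(apply(lg, 2, max), each = nrow(lg))
  el <- exp(lg)
  probs <- el / rep(colSums(el), each = nrow(el))
  y1 <- labels + 1L
  loss <- -mean(log(pmax(probs[cbind(y1, seq_len(B))], 1e-12)))
  dlogits <- probs
  dlogits[cbind(y1, seq_len(B))] <- dlogits[cbind(y1, seq_len(B))] - 1
  dlogits <- dlogits / B

  grads <- list(
    W_out = tcrossprod(dlogits, fw$pooled),
    b_out = matrix(rowSums(dlogits), ncol = 1L)
  )
  dpooled <- crossprod(model$params$W_out, dlogits)
  dh <- as.matrix(Matrix::crossprod(model$pool, dpooled))

  for (nm in rev(names(model$blocks))) {
    blk <- model$blocks[[nm]]
    bc <- fw$caches[[nm]]
    W_lat_nm <- paste0(nm, ".W_lat")
    dzin <- NULL
    dh_t <- dh  # gradient wrt h_T of this block
    for (t in rev(seq_len(blk$T_rec))) {
      ct <- bc$t[[t]]
      mask <- ct$Zn > 0
      dZn <- gain * dh_t * mask
      dz <- bn_backward(dZn, ct$Zn, ct$sd, blk$Cout)
      dzin <- if (is.null(dzin)) dz else dzin + dz
      if (t > 1L) {
        cb <- conv_backward(model$params[[W_lat_nm]], blk$gather_lat,
                            ct$Hcol, dz)
        grads[[W_lat_nm]] <- if (is.null(grads[[W_lat_nm]])) cb$dW else
          grads[[W_lat_nm]] + cb$dW
        dh_t <- cb$dX
      }
    }
    cbi <- conv_backward(model$params[[paste0(nm, ".W_in")]], blk$gather_in,
                         bc$Xcol_in, dzin)
    grads[[paste0(nm, ".W_in")]] <- cbi$dW
    dh <- cbi$dX
  }
  list(loss = loss, grads = grads)
}

#' Forward pass with per-layer activations
#'
#' Runs the network in evaluation mode and returns the 19-way class scores
#' together with the last-timestep activations of every block. The argmax of
#' the scores (minus 1) is the model's numeric response.
#'
#' @param model A [build_model()] network.
#' @param images Either an `11760 x B` matrix (channel-first `3 x 28 x 140`
#'   columns) or a single `3 x 28 x 140` array.
#' @return A list with `scores` (`19 x B`), `response` (integer vector, 0-18),
#'   and `activations` (named list of `units x B` non-negative matrices for
#'   V1, V2, V3, IPS).
#' @export
forward_with_activations <- function(model, images) {
  stopifnot(inherits(model, "pdnn_model"))
  if (is.array(images) && length(dim(images)) == 3L) {
    if (!identical(dim(images), c(3L, 28L, 140L))) {
      stop("images must be 3 x 28 x 140")
    }
    images <- matrix(as.vector(images), ncol = 1L)
  }
  if (nrow(images) != 3L * 28L * 140L) {
    stop("images must have 3*28*140 = 11760 rows (channel-first layout)")
  }
  fw <- model_forward(model, images, mode = "eval",
                      capture_layers = names(model$blocks))
  list(scores = fw$logits,
       response = apply(fw$logits, 2, which.max) - 1L,
       activations = fw$acts)
}

# snapshot / restore of the mutable model state (weights + bn running stats)
model_snapshot <- function(model, adam_state = NULL) {
  list(params = model$params,
       bn = lapply(model$blocks, `[[`, "bn"),
       adam = adam_state)
}

model_restore <- function(model, snap) {
  model$params <- snap$params
  for (nm in names(model$blocks)) model$blocks[[nm]]$bn <- snap$bn[[nm]]
  model
}
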