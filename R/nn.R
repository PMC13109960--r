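# Convolution / batch-norm primitives.
#
# Feature maps are stored channel-first as (C*H*W) x batch matrices (C fastest,
# then H, then W), so a column is one image and reshaping to (C, H*W*batch)
# groups entries by channel. Convolutions are computed by an im2col gather
# followed by a dense GEMM; the gather is a precomputed index map (forward) and
# its transpose as a sparse matrix (backward scatter-add).

# Build the gather for a K x K convolution with given stride and zero padding.
make_conv_gather <- function(C, H, W, K, stride, pad) {
  Ho <- (H + 2L * pad - K) %/% stride + 1L
  Wo <- (W + 2L * pad - K) %/% stride + 1L
  CKK <- C * K * K
  P <- Ho * Wo
  g <- expand.grid(c = seq_len(C), kh = seq_len(K), kw = seq_len(K),
                   ho = seq_len(Ho), wo = seq_len(Wo))
  h_in <- (g$ho - 1L) * stride + g$kh - pad
  w_in <- (g$wo - 1L) * stride + g$kw - pad
  q <- g$c + C * (g$kh - 1L) + C * K * (g$kw - 1L)
  p <- g$ho + Ho * (g$wo - 1L)
  row <- q + CKK * (p - 1L)
  valid <- h_in >= 1L & h_in <= H & w_in >= 1L & w_in <= W
  col <- g$c + C * (h_in - 1L) + C * H * (w_in - 1L)
  n_in <- C * H * W
  # forward map: padded taps are zeroed after the gather
  map <- rep.int(n_in + 1L, CKK * P)
  map[row[valid]] <- col[valid]
  map_safe <- pmin(map, n_in)
  pad_rows <- which(map > n_in)
  list(map = map, map_safe = map_safe, pad_rows = pad_rows,
       C = C, H = H, W = W, K = K,
       Ho = Ho, Wo = Wo, CKK = CKK, P = P, n_in = n_in)
}

# im2col gather only: X (C*H*W) x B -> CKK x (P*B)
conv_im2col <- function(gth, X) {
  B <- ncol(X)
  Xcol <- X[gth$map_safe, , drop = FALSE]        # (CKK*P) x B
  if (length(gth$pad_rows)) Xcol[gth$pad_rows, ] <- 0
  dim(Xcol) <- c(gth$CKK, gth$P * B)
  Xcol
}

# X: (C*H*W) x B -> list(Y = (Cout*P) x B, Xcol = CKK x (P*B)).
# A precomputed Xcol (weight-independent) may be supplied.
conv_forward <- function(Wmat, gth, X, Xcol = NULL) {
  B <- if (is.null(Xcol)) ncol(X) else ncol(Xcol) %/% gth$P
  if (is.null(Xcol)) Xcol <- conv_im2col(gth, X)
  Y <- Wmat %*% Xcol
  dim(Y) <- c(nrow(Wmat) * gth$P, B)
  list(Y = Y, Xcol = Xcol)
}

# dY: (Cout*P) x B. Returns gradient wrt input and weights.
conv_backward <- function(Wmat, gth, Xcol, dY) {
  B <- ncol(dY)
  Cout <- nrow(Wmat)
  dim(dY) <- c(Cout, gth$P * B)
  dW <- tcrossprod(dY, Xcol)                     # Cout x CKK
  dXcol <- crossprod(Wmat, dY)                   # CKK x (P*B)
  dim(dXcol) <- c(gth$CKK * gth$P, B)
  # scatter-add back to the input layout (padding taps drop out)
  rs <- rowsum(dXcol, gth$map, reorder = TRUE)
  grp <- as.integer(rownames(rs))
  keep <- grp <= gth$n_in
  dX <- matrix(0, gth$n_in, B)
  dX[grp[keep], ] <- rs[keep, , drop = FALSE]
  list(dX = dX, dW = dW)
}

# Frozen (normalization-only) batch norm over channels: affine scale/shift are
# never trained; batch statistics are used in training mode and exponential
# running statistics at evaluation.
bn_forward <- function(Z, C, state, mode, momentum = 0.1, eps = 1e-5) {
  d <- dim(Z); n <- length(Z) %/% C
  dim(Z) <- c(C, n)
  if (mode == "train") {
    mu <- rowMeans(Z)
    v <- rowMeans(Z * Z) - mu * mu
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * v
  } else {
    mu <- state$rm
    v <- state$rv
  }
  sd <- sqrt(pmax(v, 0) + eps)
  Zn <- (Z - mu) / sd
  dim(Zn) <- d
  list(Zn = Zn, sd = sd, state = state)
}

bn_backward <- function(dZn, Zn, sd, C) {
  d <- dim(dZn); n <- length(dZn) %/% C
  dim(dZn) <- c(C, n); dim(Zn) <- c(C, n)
  g1 <- rowMeans(dZn)
  g2 <- rowMeans(dZn * Zn)
  dZ <- (dZn - g1 - Zn * g2) / sd
  dim(dZ) <- d
  dZ
}

#' Gain-modulated rectified linear unit
#'
#' The excitability-scaled nonlinearity `y = G * max(0, x)` applied at every
#' neuron of the network. The gain `G` operationalizes neural excitability:
#' `G = 1` is the canonical ReLU, larger `G` amplifies all supra-threshold
#' responses. Positively homogeneous: `gain_relu(x, G) = G * gain_relu(x, 1)`.
#'
#' @param x Numeric input (any shape).
#' @param G Positive gain factor.
#' @return `G * pmax(x, 0)`, same shape as `x`.
#' @examples
#' gain_relu(c(-3, 1, 2), G = 2.5)
#' @export
gain_relu <- function(x, G) {
  if (!is.numeric(G) || length(G) != 1L || G <= 0) {
    stop("gain `G` must be a positive scalar")
  }
  G * pmax(x, 0)
}

# Adam optimizer step over a flat named list of parameter matrices.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
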