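# Geometry of result manifolds.
#
# A "result manifold" is the set of unit-space mean activations of all
# problems sharing one numeric result (19 manifolds x 20 problems on the
# default task). Capacity, radius and dimensionality follow the replica
# mean-field theory of perceptual manifolds: each manifold is described in a
# center-plus-axes frame (coordinates scaled by the center norm, with a unit
# center coordinate appended), and for Gaussian fields t the convex program
#
#   F(t) = min ||v - t||^2  s.t.  <v, s> >= kappa for every manifold point s
#
# is solved through its non-negative dual. The inverse capacity is the mean
# of F over fields, the anchor point s*(t) = (t - v)/sum(alpha) yields the
# radius (mean squared anchor norm) and dimensionality (mean squared
# alignment of the field with the anchor direction). For point manifolds at
# kappa = 0 this reduces to Cover's classical limit alpha = 2.

#' Group mean problem activations into result manifolds
#'
#' @param mean_acts `problems x units` matrix (aligned with `specs` rows).
#' @param specs Problem data.frame with a `result` column.
#' @return A `manifold_set`: list of `points` (one `m x units` matrix per
#'   result value, named by result) plus bookkeeping fields.
#' @export
group_by_result <- function(mean_acts, specs) {
  stopifnot(nrow(mean_acts) == nrow(specs))
  values <- sort(unique(specs$result))
  pts <- lapply(values, function(s) {
    mean_acts[specs$result == s, , drop = FALSE]
  })
  names(pts) <- values
  structure(list(points = pts, result_values = values,
                 n_manifolds = length(values),
                 points_per_manifold = vapply(pts, nrow, integer(1))),
            class = "manifold_set")
}

#' @export
print.manifold_set <- function(x, ...) {
  cat(sprintf("<manifold_set> %d manifolds, %s points each, %d units\n",
              x$n_manifolds,
              paste(range(x$points_per_manifold), collapse = "-"),
              ncol(x$points[[1]])))
  invisible(x)
}

# Solve the batched non-negative dual QP min .5 a'Ka + a'q, a >= 0 by cyclic
# coordinate descent, one column per Gaussian field. K: m x m PSD, Q: m x n_t.
.nnqp_batch <- function(K, Q, max_sweeps = 500L, tol = 1e-9) {
  m <- nrow(K); n <- ncol(Q)
  A <- matrix(0, m, n)
  KA <- matrix(0, m, n)
  dK <- diag(K)
  for (sweep in seq_len(max_sweeps)) {
    delta_max <- 0
    for (j in seq_len(m)) {
      aj_new <- pmax(0, A[j, ] - (KA[j, ] + Q[j, ]) / dK[j])
      d <- aj_new - A[j, ]
      if (any(d != 0)) {
        KA <- KA + tcrossprod(K[, j], d)
        A[j, ] <- aj_new
        delta_max <- max(delta_max, max(abs(d)))
      }
    }
    if (delta_max < tol) break
  }
  list(A = A, KA = KA)
}

# Analyze one manifold given its (D+1) x m lifted representation sD1
# (axes coordinates over center norm; last row = 1) under n_t Gaussian fields.
.analyze_manifold_D1 <- function(sD1, kappa, n_t) {
  D1 <- nrow(sD1); m <- ncol(sD1)
  Tm <- matrix(stats::rnorm(D1 * n_t), D1, n_t)
  K <- crossprod(sD1, sD1)
  Q <- crossprod(sD1, Tm) - kappa        # m x n_t: <s_j, t> - kappa
  # constraint <v,s> >= kappa with v = t + S'alpha gives the dual
  # min .5 a'Ka + a'(St - kappa.1) over a >= 0; fields with Q >= 0 are
  # interior (alpha = 0, F = 0)
  sol <- .nnqp_batch(K, Q)
  A <- sol$A
  Fv <- colSums(A * sol$KA)              # ||S'alpha||^2 = F(t)
  lam <- sD1 %*% A                       # (D+1) x n_t
  alpha_sum <- colSums(A)
  contrib <- which(Fv > 1e-12 & alpha_sum > 1e-12)
  R2 <- NA_real_; Dm <- NA_real_
  if (D1 > 1L && length(contrib)) {
    s_star <- lam[-D1, contrib, drop = FALSE] /
      rep(alpha_sum[contrib], each = D1 - 1L)
    ns <- sqrt(colSums(s_star^2))
    ok <- ns > 1e-12
    R2 <- mean(colSums(s_star^2))
    if (any(ok)) {
      s_hat <- s_star[, ok, drop = FALSE] / rep(ns[ok], each = D1 - 1L)
      t_ax <- Tm[-D1, contrib, drop = FALSE][, ok, drop = FALSE]
      Dm <- mean(colSums(t_ax * s_hat)^2)
    }
  } else if (D1 == 1L) {
    R2 <- 0; Dm <- 0
  }
  list(inv_capacity = mean(Fv), R2 = R2, D = Dm)
}

#' Mean-field manifold capacity, radius and dimensionality
#'
#' Replica mean-field analysis of a set of manifolds: per-manifold inverse
#' capacities are averaged (the set capacity is their harmonic-style
#' combination), and radius/dimensionality are anchor-point statistics.
#' Deterministic given `rng_seed`.
#'
#' @param ms A [group_by_result()] manifold set (or compatible list of point
#'   matrices in `$points`).
#' @param kappa Classification margin (default 0).
#' @param n_samples Gaussian field draws per manifold (default 200).
#' @param rng_seed Seed for field draws and the unit projection.
#' @param max_units If the unit space is larger, project to this many random
#'   Gaussian dimensions first (default 500).
#' @return List with scalars `capacity`, `radius`, `dimension`,
#'   `center_correlation`, and per-manifold vectors in `per_manifold`.
#' @export
mft_manifold_metrics <- function(ms, kappa = 0, n_samples = 200L,
                                 rng_seed = 1L, max_units = 500L) {
  pts <- ms$points
  if (length(pts) < 2L) stop("need at least 2 manifolds")
  X <- do.call(rbind, pts)
  if (!all(is.finite(X))) stop("manifold points must be finite")
  if (max(apply(X, 2, stats::var)) < 1e-24) {
    stop("degenerate geometry: all manifold points are identical")
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  N <- ncol(X)
  if (N > max_units) {
    proj <- matrix(stats::rnorm(N * max_units, 0, 1 / sqrt(max_units)),
                   N, max_units)
    pts <- lapply(pts, function(p) p %*% proj)
    X <- do.call(rbind, pts)
  }
  mu <- colMeans(X)                       # grand mean over all problems
  res <- lapply(pts, function(P) {
    Pc <- sweep(P, 2, mu)
    ctr <- colMeans(Pc)
    norm_c <- sqrt(sum(ctr^2))
    if (norm_c < 1e-12) {
      stop("degenerate geometry: a manifold center coincides with the grand mean")
    }
    M <- sweep(Pc, 2, ctr)                # centered points
    sv <- svd(M)
    keep <- sv$d > max(sv$d[1], 1e-12) * 1e-8
    Acoord <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
    sD1 <- rbind(t(Acoord) / norm_c, rep(1, nrow(P)))
    .analyze_manifold_D1(sD1, kappa, n_samples)
  })
  inv_cap <- vapply(res, `[[`, numeric(1), "inv_capacity")
  r2 <- vapply(res, `[[`, numeric(1), "R2")
  dd <- vapply(res, `[[`, numeric(1), "D")
  list(capacity = 1 / mean(inv_cap),
       radius = sqrt(mean(r2, na.rm = TRUE)),
       dimension = mean(dd, na.rm = TRUE),
       center_correlation = center_correlation(ms),
       per_manifold = list(capacity = 1 / inv_cap,
                           radius = sqrt(r2), dimension = dd))
}

#' Mean absolute correlation between manifold centers
#'
#' Alignment of the manifolds: the mean absolute pairwise Pearson correlation
#' between center (mean-activation) vectors, self-pairs excluded. High values
#' mean the centers point in similar directions in unit space.
#'
#' @param ms A manifold set.
#' @return Scalar in `[0, 1]` (`NA` if a center is constant across units).
#' @export
center_correlation <- function(ms) {
  centers <- t(vapply(ms$points, colMeans, numeric(ncol(ms$points[[1]]))))
  if (nrow(centers) < 2L) stop("need at least 2 manifolds")
  if (any(apply(centers, 1, stats::sd) == 0)) return(NA_real_)
  cc <- stats::cor(t(centers))
  mean(abs(cc[upper.tri(cc)]))
}

# Is the homogeneous dichotomy separable? By Gordan's theorem, some w with
# <w, y_i x_i> > 0 for all i exists iff 0 is not in the convex hull of the
# signed points. Gilbert's minimum-norm-point iteration either produces a
# separating certificate or drives the hull point to the origin.
.separable_gilbert <- function(Z, max_iter = 500L, tol = 1e-7) {
  nr <- sqrt(rowSums(Z^2))
  nr[nr == 0] <- 1
  Z <- Z / nr                             # scale-invariant problem
  w <- Z[1, ]
  for (it in seq_len(max_iter)) {
    d <- as.vector(Z %*% w)
    i <- which.min(d)
    if (d[i] > 0) return(TRUE)            # w itself separates
    z <- Z[i, ]
    dif <- w - z
    den <- sum(dif^2)
    theta <- if (den < 1e-18) 1 else min(max(sum(w * dif) / den, 0), 1)
    w <- (1 - theta) * w + theta * z
    if (sum(w^2) < tol^2) return(FALSE)   # hull reaches the origin
  }
  FALSE
}

#' Empirical manifold capacity by random dichotomies
#'
#' Monte-Carlo estimate of the classification capacity: for random balanced
#' dichotomies of the manifolds, all member points are tested for homogeneous
#' linear separability after random Gaussian projection to `n_dim` dimensions;
#' bisection over `n_dim` locates the 50% separability transition, and
#' capacity is (number of manifolds) / (transition dimension).
#'
#' @param ms A manifold set.
#' @param n_dichotomies Random balanced dichotomies per probed dimension.
#' @param rng_seed Seed for dichotomies and projections.
#' @param max_dim Largest projected dimension probed (default: ambient).
#' @return List with `capacity`, `n_star` (transition dimension), and `probed`
#'   (data.frame of dimension / separable fraction pairs).
#' @export
empirical_capacity <- function(ms, n_dichotomies = 30L, rng_seed = 1L,
                               max_dim = NULL) {
  if (n_dichotomies < 1L) stop("n_dichotomies must be >= 1")
  P <- length(ms$points)
  if (P < 2L) stop("need at least 2 manifolds")
  X <- do.call(rbind, ms$points)
  grp <- rep(seq_len(P), vapply(ms$points, nrow, integer(1)))
  N <- ncol(X)
  if (is.null(max_dim)) max_dim <- N
  max_dim <- min(max_dim, N)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))

  frac_at <- function(nd) {
    ok <- 0L
    reps <- if (P == 2L) 1L else n_dichotomies
    for (k in seq_len(reps)) {
      y <- rep(-1L, P)
      y[sample.int(P, P %/% 2L)] <- 1L
      pr <- matrix(stats::rnorm(N * nd), N, nd)
      Z <- (X %*% pr) * y[grp]
      if (.separable_gilbert(Z)) ok <- ok + 1L
    }
    ok / reps
  }
  probed <- data.frame(dim = integer(0), frac = numeric(0))
  note <- function(nd, f) probed <<- rbind(probed, data.frame(dim = nd, frac = f))
  lo <- 1L; f_lo <- frac_at(lo); note(lo, f_lo)
  hi <- max_dim; f_hi <- frac_at(hi); note(hi, f_hi)
  if (f_lo >= 0.5) {
    n_star <- lo
  } else if (f_hi < 0.5) {
    n_star <- NA_integer_                 # not separable within ambient space
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      fm <- frac_at(mid); note(mid, fm)
      if (fm >= 0.5) hi <- mid else lo <- mid
    }
    n_star <- hi
  }
  list(capacity = if (is.na(n_star)) NA_real_ else P / n_star,
       n_star = n_star, probed = probed[order(probed$dim), ])
}
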