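# Synthetic cohort of children.
#
# Stand-in for the study's behavioral data: 45 children (24 typically
# developing, 21 with a math learning disability defined by a standard score
# below 90). Raw scores are drawn on the standard-score scale and calibrated
# so that cohort-wide min-max normalization yields group means/SDs near the
# published normalized summaries (TD ~ 0.70 +/- 0.13, MLD ~ 0.35 +/- 0.06) in
# the large-sample limit. The MLD distribution is a mixture of a dominant
# just-below-cutoff component and a small uniform low tail (a few far-below
# scorers), which is what makes a small-sample min-max normalization with a
# mean 5-6 group SDs above the cohort minimum attainable at all.

#' Cohort configuration
#'
#' @param n_td,n_mld Group sizes (defaults 24 and 21).
#' @param td_norm_mean,td_norm_sd Target normalized TD moments (0.70, 0.13).
#' @param mld_norm_mean,mld_norm_sd Target normalized MLD moments (0.35, 0.06).
#' @param mld_cutoff MLD classification cutoff on the standard-score scale (90).
#' @param score_floor,score_ceiling Attainable score range anchoring the
#'   normalization in the large-sample limit (55, 145).
#' @param low_tail_weight,low_tail_upper Mixture weight and upper bound of the
#'   uniform low tail of the MLD distribution.
#' @param rng_seed Seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_td = 24L, n_mld = 21L,
                          td_norm_mean = 0.70, td_norm_sd = 0.13,
                          mld_norm_mean = 0.35, mld_norm_sd = 0.06,
                          mld_cutoff = 90, score_floor = 55,
                          score_ceiling = 145,
                          low_tail_weight = 0.03, low_tail_upper = 70,
                          rng_seed = 1L) {
  if (n_td < 1L || n_mld < 1L) stop("group sizes must be >= 1")
  structure(as.list(environment()), class = "cohort_config")
}

# truncated-normal helpers (inverse-CDF sampling and closed-form moments)
.tnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# find (mu, sigma) of a normal truncated to [lo, hi] with given moments
.tnorm_calibrate <- function(target_mean, target_sd, lo, hi) {
  obj <- function(p) {
    mo <- .tnorm_moments(p[1], exp(p[2]), lo, hi)
    (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  mo <- .tnorm_moments(fit$par[1], exp(fit$par[2]), lo, hi)
  if (abs(mo["mean"] - target_mean) > 0.02 * (hi - lo) ||
      abs(mo["sd"] - target_sd) > 0.02 * (hi - lo)) {
    stop("calibration error: truncated-normal moments not attainable")
  }
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

.tnorm_draw <- function(n, mu, sigma, lo, hi) {
  plo <- stats::pnorm(lo, mu, sigma); phi <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(stats::runif(n, plo, phi), mu, sigma)
}

#' Generate a synthetic cohort
#'
#' Draws raw achievement scores per group (MLD strictly below the cutoff, TD
#' at or above), calibrated so cohort-wide min-max normalization approaches
#' the configured group means/SDs as the cohort grows.
#'
#' @param config A [cohort_config()].
#' @return Data.frame with columns `id`, `group` (`"TD"`/`"MLD"`),
#'   `raw_score`, `normalized_score` (cohort min-max).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  L <- config$score_floor; U <- config$score_ceiling
  R <- U - L
  cut <- config$mld_cutoff
  if (!(L < config$low_tail_upper && config$low_tail_upper < cut && cut < U)) {
    stop("calibration error: need floor < low_tail_upper < cutoff < ceiling")
  }
  # raw-scale targets implied by the normalized targets in the large-n limit
  m_mld <- L + config$mld_norm_mean * R; s_mld <- config$mld_norm_sd * R
  m_td <- L + config$td_norm_mean * R; s_td <- config$td_norm_sd * R
  if (!(m_mld < cut && m_td > cut)) {
    stop("calibration error: group means must straddle the cutoff")
  }
  # MLD mixture: weight w uniform on [L, low_tail_upper), rest truncated
  # normal on [low_tail_upper, cutoff) with moments solved from the targets
  w <- config$low_tail_weight
  mean_u <- (L + config$low_tail_upper) / 2
  var_u <- (config$low_tail_upper - L)^2 / 12
  m_core <- (m_mld - w * mean_u) / (1 - w)
  var_between <- w * (mean_u - m_mld)^2 + (1 - w) * (m_core - m_mld)^2
  var_core <- (s_mld^2 - var_between - w * var_u) / (1 - w)
  if (var_core <= 0 || m_core >= cut || m_core <= config$low_tail_upper) {
    stop("calibration error: MLD core component infeasible under these targets")
  }
  core <- .tnorm_calibrate(m_core, sqrt(var_core), config$low_tail_upper, cut)
  td <- .tnorm_calibrate(m_td, s_td, cut, U)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(config$rng_seed))
  n_mld <- config$n_mld; n_td <- config$n_td
  is_tail <- stats::runif(n_mld) < w
  mld_scores <- numeric(n_mld)
  mld_scores[is_tail] <- stats::runif(sum(is_tail), L, config$low_tail_upper)
  mld_scores[!is_tail] <- .tnorm_draw(sum(!is_tail), core$mu, core$sigma,
                                      config$low_tail_upper, cut)
  mld_scores <- pmin(mld_scores, cut - 1e-9)
  td_scores <- .tnorm_draw(n_td, td$mu, td$sigma, cut, U)

  raw <- c(td_scores, mld_scores)
  if (max(raw) <= min(raw)) stop("degenerate bounds: all scores identical")
  out <- data.frame(
    id = sprintf("child%03d", seq_len(n_td + n_mld)),
    group = c(rep("TD", n_td), rep("MLD", n_mld)),
    raw_score = raw,
    normalized_score = normalize_scores(raw)
  )
  out
}

#' Synthetic "observed" neural similarity for matched children
#'
#' Generates per-child observed add-sub similarity values on the correlation
#' scale, coupled to the model predictions through the Fisher-z domain:
#' `observed = tanh(coupling * atanh(predicted) + noise)`. With
#' `coupling = 1, noise_sd = 0` observed equals predicted; with
#' `coupling = 0` observed is independent noise.
#'
#' @param predicted Predicted similarity per child, in (-1, 1).
#' @param coupling Linear coupling in z-space.
#' @param noise_sd SD of z-space Gaussian noise.
#' @param rng_seed Seed.
#' @return Numeric vector of observed similarities in (-1, 1).
#' @export
generate_observed_nrs <- function(predicted, coupling = 1, noise_sd = 0,
                                  rng_seed = 1L) {
  if (any(abs(predicted) >= 1)) {
    stop("domain error: predicted similarities must lie strictly in (-1, 1)")
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  tanh(coupling * atanh(predicted) +
         stats::rnorm(length(predicted), 0, noise_sd))
}
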