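# Recursive numerical integration for sequential normal statistics.
#
# Sequentially computed log-rank statistics follow, asymptotically, the
# canonical joint normal model: Cov(Z_j, Z_k) = sqrt(t_j / t_k) for
# information fractions t_j <= t_k. On the Brownian scale S_k = sqrt(t_k) Z_k
# the increments are independent N(0, t_k - t_{k-1}), so the sub-density of
# S_k on the event "no efficacy bound crossed at looks 1..k" satisfies a
# one-dimensional convolution recursion. We propagate that sub-density on a
# trapezoid grid (the classical group-sequential recursion), which is exact
# enough at a few thousand grid points for ~1e-6 accuracy per stage.

# Sub-density of S at the penultimate stage under no crossing of bounds
# 1..(K-1); returns grid, weights and values so the last stage reduces to a
# closed-form normal-tail integral in the final bound.
.seq_nocross_density <- function(info, zbounds, ngrid = 2001, width = 8.5) {
  K <- length(info)
  cb <- zbounds * sqrt(info)                       # Brownian-scale bounds
  x <- seq(-width * sqrt(info[1]), cb[1], length.out = ngrid)
  f <- stats::dnorm(x, sd = sqrt(info[1]))
  if (K > 1) for (k in 2:K) {
    d <- info[k] - info[k - 1]
    y <- seq(-width * sqrt(info[k]), cb[k], length.out = ngrid)
    h <- x[2] - x[1]
    w <- rep(h, ngrid); w[c(1, ngrid)] <- h / 2
    f <- as.vector(stats::dnorm(outer(y, x, "-"), sd = sqrt(d)) %*% (f * w))
    x <- y
  }
  h <- x[2] - x[1]
  w <- rep(h, ngrid); w[c(1, ngrid)] <- h / 2
  list(x = x, w = w, f = f, info_last = info[K])
}

#' Crossing probability of a sequence of one-sided efficacy bounds
#'
#' Probability that a sequentially monitored standardized statistic exceeds
#' at least one of its one-sided efficacy boundaries, under the null and the
#' canonical joint normal model with correlation `sqrt(t_j / t_k)`.
#'
#' @param info_fractions Strictly increasing information fractions in
#'   `(0, 1]`, one per look.
#' @param p_bounds One-sided nominal p-value bounds, one per look.
#' @param ngrid Grid points per stage for the recursion.
#' @return Total crossing probability (the alpha actually spent).
#' @export
sequential_cross_prob <- function(info_fractions, p_bounds, ngrid = 2001) {
  stopifnot(length(info_fractions) == length(p_bounds),
            all(diff(info_fractions) > 0),
            all(info_fractions > 0), all(info_fractions <= 1),
            all(p_bounds > 0), all(p_bounds < 1))
  K <- length(info_fractions)
  zb <- stats::qnorm(1 - p_bounds)
  if (K == 1) return(p_bounds[1])
  dens <- .seq_nocross_density(info_fractions[seq_len(K - 1)],
                               zb[seq_len(K - 1)], ngrid = ngrid)
  d <- info_fractions[K] - dens$info_last
  cK <- zb[K] * sqrt(info_fractions[K])
  noncross <- sum(dens$f * dens$w *
                  stats::pnorm((cK - dens$x) / sqrt(d)))
  1 - noncross
}

#' Calibrate the final-look significance level under alpha spending
#'
#' Given the interim one-sided efficacy bounds and the information fractions
#' of the analysis schedule, solves (by bisection) for the final-look nominal
#' one-sided level at which the total probability of crossing any efficacy
#' bound equals `overall_alpha` under the canonical joint normal model. With
#' no interims the answer is `overall_alpha` itself; as the interim bounds
#' shrink to zero the final level rises to `overall_alpha`.
#'
#' @param efficacy_bounds Interim one-sided efficacy p-value bounds (may be
#'   empty).
#' @param info_fractions Information fractions of all looks including the
#'   final one (so one entry more than `efficacy_bounds`), strictly
#'   increasing in `(0, 1]`.
#' @param overall_alpha Total one-sided type-I error to preserve.
#' @param tol Absolute bisection tolerance on the returned level.
#' @param ngrid Grid points per stage for the recursion.
#' @return The final-look nominal one-sided significance level; always
#'   `<= overall_alpha`.
#' @examples
#' # the C-08 schedule: 148/220/312/398/473/538 events, final at 592
#' calibrate_final_alpha(
#'   efficacy_bounds = c(0.00025, 0.0005, 0.001, 0.001, 0.001, 0.001),
#'   info_fractions = c(148, 220, 312, 398, 473, 538, 592) / 592)
#' @export
calibrate_final_alpha <- function(efficacy_bounds, info_fractions,
                                  overall_alpha = 0.025, tol = 1e-5,
                                  ngrid = 2001) {
  K <- length(efficacy_bounds)
  stopifnot(length(info_fractions) == K + 1)
  if (K == 0) return(overall_alpha)
  stopifnot(all(diff(info_fractions) > 0), all(info_fractions > 0),
            all(info_fractions <= 1),
            all(efficacy_bounds > 0), all(efficacy_bounds < 1))
  interim_spend <- sequential_cross_prob(info_fractions[seq_len(K)],
                                         efficacy_bounds, ngrid = ngrid)
  if (interim_spend >= overall_alpha)
    stop(sprintf(
      "infeasible: interim efficacy bounds alone spend %.5f >= overall alpha %.5f",
      interim_spend, overall_alpha))
  dens <- .seq_nocross_density(info_fractions[seq_len(K)],
                               stats::qnorm(1 - efficacy_bounds), ngrid = ngrid)
  d <- info_fractions[K + 1] - dens$info_last
  cross <- function(alpha_final) {
    cK <- stats::qnorm(1 - alpha_final) * sqrt(info_fractions[K + 1])
    1 - sum(dens$f * dens$w * stats::pnorm((cK - dens$x) / sqrt(d)))
  }
  lo <- tol / 10; hi <- overall_alpha
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (cross(mid) > overall_alpha) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Per-look alpha spending of a boundary schedule
#'
#' Incremental probability, under the null, of first crossing each one-sided
#' efficacy bound.
#'
#' @inheritParams sequential_cross_prob
#' @return Numeric vector of incremental crossing probabilities, one per
#'   look; its sum is `sequential_cross_prob(info_fractions, p_bounds)`.
#' @export
alpha_spent_per_look <- function(info_fractions, p_bounds, ngrid = 2001) {
  cum <- vapply(seq_along(p_bounds), function(k)
    sequential_cross_prob(info_fractions[seq_len(k)], p_bounds[seq_len(k)],
                          ngrid = ngrid), 0)
  diff(c(0, cum))
}

#' Monte-Carlo probability of statistical success
#'
#' The probability that a simulated trial ends in statistical success -
#' stopping early for superiority or reaching significance at the final
#' analysis - at a fixed hazard reduction. At the effect the trial was
#' powered for this is the trial's power; at `delta = 0` (with futility
#' stopping disabled, see [disable_futility()]) it estimates the overall
#' type-I error.
#'
#' @param design A validated `trial_design`.
#' @param hazard_reduction Fixed treatment effect `delta`.
#' @param n_reps Number of replicates.
#' @param seed Master integer seed.
#' @return Named vector `c(power, se)`: the success probability and its
#'   Monte-Carlo standard error.
#' @export
power_at <- function(design, hazard_reduction, n_reps, seed = 1L) {
  tab <- estimate_outcome_table(design, hazard_reduction, n_reps, seed)
  p <- sum(tab$sup) + tab$final_success
  c(power = p, se = sqrt(max(0, p * (1 - p)) / n_reps))
}
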