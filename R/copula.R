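# Latent-Gaussian calibration for injecting a target Spearman correlation
# between a (possibly tied/discrete) factor and a continuous variable.
#
# Construction: x is driven by z = lambda * s(f) + sqrt(1 - lambda^2) * eps,
# where s(f) is the standardized normal score of the factor value (midrank
# convention for ties) and eps ~ N(0,1).  Because Spearman's rho is invariant
# under monotone maps of x, controlling rank correlation of z with f controls
# it for any monotone transform of z (e.g. log-normal peak areas).

# Midrank CDF, probabilities and standardized normal scores of the empirical
# distribution of f.  Returns per-level tables plus the per-observation score.
.factor_score <- function(f) {
  f <- as.numeric(f)
  v <- sort(unique(f))
  ix <- match(f, v)
  p <- tabulate(ix, length(v)) / length(f)
  cum <- cumsum(p)
  u <- cum - p / 2                     # midrank cdf P(F < v) + P(F = v)/2
  s <- stats::qnorm(u)
  mu <- sum(p * s)
  sd <- sqrt(sum(p * (s - mu)^2))
  if (sd == 0) stop("factor has no variation; cannot inject an effect")
  s <- (s - mu) / sd
  list(values = v, p = p, u = u, s = s,
       obs_score = s[ix])
}

# Population Spearman rho between f and x = lambda*s(f) + sqrt(1-lambda^2)*eps,
# computed from the empirical level distribution of f.
.spearman_of_lambda <- function(lambda, sc) {
  if (abs(lambda) >= 1) lambda <- sign(lambda) * (1 - 1e-12)
  p <- sc$p; u <- sc$u; s <- sc$s
  K <- length(p)
  denom <- sqrt(2 * (1 - lambda^2))
  # e_k = E[F_X(X) | f = v_k] = sum_j p_j P(X_j < X_k)
  d <- outer(s, s, "-")                    # s_k - s_j, K x K
  e <- as.vector(stats::pnorm(lambda * d / denom) %*% p)
  covar <- sum(p * u * e) - 0.25           # E[u]=E[e]=1/2
  var_f <- sum(p * u^2) - 0.25
  var_x <- 1 / 12                          # x continuous
  covar / sqrt(var_f * var_x)
}

# Solve for the latent coefficient lambda that yields the target Spearman rho
# against the given factor values.  Uses the closed form 2*sin(pi*rho/6) when
# the factor is effectively continuous (ties negligible).
.spearman_lambda <- function(factor_values, target_rho) {
  if (!is.numeric(target_rho) || length(target_rho) != 1L || !is.finite(target_rho))
    stop("target_rho must be a single finite number")
  if (abs(target_rho) >= 1)
    stop("|target_rho| must be < 1")
  if (target_rho == 0) return(0)
  sc <- .factor_score(factor_values)
  if (length(sc$values) > 100L)
    return(2 * sin(pi * target_rho / 6))
  rho_max <- .spearman_of_lambda(1 - 1e-9, sc)
  if (abs(target_rho) >= rho_max)
    stop(sprintf(
      "target_rho %.3f is not achievable: the factor's tie structure caps |rho| at %.3f",
      target_rho, rho_max))
  stats::uniroot(function(l) .spearman_of_lambda(l, sc) - target_rho,
                 interval = c(-1 + 1e-9, 1 - 1e-9), tol = 1e-10)$root
}

#' Inject a target Spearman correlation into a peak-area vector
#'
#' Re-arranges (re-draws the rank structure of) a vector of peak areas so that
#' its Spearman rank correlation with a clinical factor converges to
#' \code{target_rho} as the sample size grows, while preserving the empirical
#' marginal distribution of the areas exactly.  The mechanism is a Gaussian
#' copula on latent scores: the returned vector is the multiset of input
#' areas re-assigned by the ranks of
#' \code{lambda * s(f) + sqrt(1 - lambda^2) * eps}, with \code{lambda}
#' calibrated against the factor's tie structure so that rank (not linear)
#' correlation is controlled — matching a downstream Spearman analysis.
#'
#' @param areas numeric vector of non-negative peak areas.
#' @param factor_values numeric vector (same length) encoding the factor.
#' @param target_rho signed target Spearman correlation, \code{|rho| < 1}.
#'   For heavily tied factors (e.g. a binary group label) the achievable
#'   magnitude is capped below 1; an unreachable target is an error.
#' @return numeric vector: the same areas, re-assigned to samples.
#' @examples
#' set.seed(1)
#' a <- rlnorm(500, 13, 1)
#' g <- rep(0:1, each = 250)
#' cor(rank(inject_effect(a, g, 0.4)), rank(g))
#' @export
inject_effect <- function(areas, factor_values, target_rho) {
  if (length(areas) != length(factor_values))
    stop("areas and factor_values must have the same length")
  lambda <- .spearman_lambda(factor_values, target_rho)
  sc <- .factor_score(factor_values)
  z <- lambda * sc$obs_score +
    sqrt(1 - lambda^2) * stats::rnorm(length(areas))
  sort(areas)[rank(z, ties.method = "first")]
}
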