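#' Beta posterior over filtered counts
#'
#' State of the precision-cost observer: real-valued exponentially filtered
#' counts of heads (`nhat1`) and tails (`nhat0`). The inferred posterior is
#' Beta(nhat1 + 1, nhat0 + 1) (under the uniform prior), i.e. a density
#' proportional to p^nhat1 (1-p)^nhat0.
#'
#' @param nhat1,nhat0 Non-negative filtered counts.
#' @return An object of class `beta_posterior`.
#' @export
beta_posterior <- function(nhat1 = 0, nhat0 = 0) {
  nhat1 <- as.numeric(nhat1); nhat0 <- as.numeric(nhat0)
  if (length(nhat1) != 1L || length(nhat0) != 1L ||
      is.na(nhat1) || is.na(nhat0) || nhat1 < 0 || nhat0 < 0)
    stop("filtered counts must be single non-negative numbers", call. = FALSE)
  structure(list(nhat1 = nhat1, nhat0 = nhat0), class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("<beta_posterior> nhat1 = %.6g, nhat0 = %.6g; mean = %.6g, var = %.6g\n",
              x$nhat1, x$nhat0, posterior_mean(x), posterior_variance(x)))
  invisible(x)
}

#' One-step precision-cost update
#'
#' The loss-minimizing update after observing outcome `x`: the one-step
#' Bayesian update of the current belief, tempered by the exponent
#' 1/(1 + lambda). In filtered-count form,
#' nhat1' = (nhat1 + x)/(1 + lambda), nhat0' = (nhat0 + 1 - x)/(1 + lambda).
#' At lambda = 0 this is plain Bayesian counting; as lambda grows the state
#' is pulled toward the uniform belief (0, 0).
#'
#' @param post A [beta_posterior()].
#' @param x A single outcome, 0 or 1.
#' @param lambda Non-negative cost weight.
#' @return The updated `beta_posterior`.
#' @export
precision_update <- function(post, x, lambda) {
  stopifnot(inherits(post, "beta_posterior"))
  lambda <- check_lambda(lambda)
  if (length(x) != 1L || is.na(x) || !(x %in% c(0, 1)))
    stop("`x` must be a single 0 or 1 outcome", call. = FALSE)
  beta_posterior((post$nhat1 + x) / (1 + lambda),
                 (post$nhat0 + 1 - x) / (1 + lambda))
}

#' Exponentially filtered outcome counts
#'
#' Closed form of the precision-cost observer state after a whole sequence:
#' nhat1 = sum_{k=0}^{N-1} r^{k+1} x_{N-k} with forgetting ratio
#' r = 1/(1 + lambda), and symmetrically for tails. Identical to iterating
#' [precision_update()] from the uniform state (0, 0).
#'
#' @param seq A [coin_sequence()].
#' @param lambda Non-negative cost weight.
#' @return A [beta_posterior()].
#' @export
#' @examples
#' filtered_counts(coin_sequence(c(1, 0)), 1)  # nhat1 = 0.25, nhat0 = 0.5
filtered_counts <- function(seq, lambda) {
  stopifnot(inherits(seq, "coin_sequence"))
  lambda <- check_lambda(lambda)
  r <- 1 / (1 + lambda)
  x <- seq$outcomes
  w <- r^(seq$N:1)       # weight r^{N-i+1} on flip i
  beta_posterior(sum(w * x), sum(w * (1 - x)))
}

#' Posterior mean of the precision-cost observer
#'
#' The point estimate p-hat = (nhat1 + 1)/(nhat1 + nhat0 + 2), the mean of
#' the Beta(nhat1 + 1, nhat0 + 1) belief.
#'
#' @param post A [beta_posterior()].
#' @return A value in (0, 1).
#' @export
posterior_mean <- function(post) {
  stopifnot(inherits(post, "beta_posterior"))
  (post$nhat1 + 1) / (post$nhat1 + post$nhat0 + 2)
}

#' Posterior variance of the precision-cost observer
#'
#' Var = (nhat1 + 1)(nhat0 + 1) / \[(nhat1 + nhat0 + 2)^2 (nhat1 + nhat0 + 3)\].
#' At the uniform state (0, 0) this is 1/12, the variance of the uniform
#' density on \[0, 1\]. Because the filtered counts are bounded for
#' lambda > 0, the variance never tends to zero along a run: beliefs stay
#' uncertain no matter how much evidence accumulates.
#'
#' @param post A [beta_posterior()].
#' @return A positive value.
#' @export
posterior_variance <- function(post) {
  stopifnot(inherits(post, "beta_posterior"))
  s <- post$nhat1 + post$nhat0
  (post$nhat1 + 1) * (post$nhat0 + 1) / ((s + 2)^2 * (s + 3))
}

#' Long-run mean of the precision-cost estimate
#'
#' E\[p-hat\] = p/(1 + 2 lambda) + lambda/(1 + 2 lambda): a compromise
#' between the true probability and 1/2, so the observer systematically
#' underestimates the coin's bias (more so for stronger cost).
#'
#' @param p True head probability in \[0, 1\].
#' @param lambda Non-negative cost weight.
#' @return The expected stationary estimate.
#' @export
#' @examples
#' expected_estimate(0.6, 0.5)  # 0.55
expected_estimate <- function(p, lambda) {
  lambda <- check_lambda(lambda)
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  (p + lambda) / (1 + 2 * lambda)
}

#' Reachable range of the precision-cost estimate
#'
#' The filtered counts are bounded by the geometric sum 1/lambda, so after
#' burn-in the estimate is confined to
#' \[lambda/(1 + 2 lambda), (1 + lambda)/(1 + 2 lambda)\], symmetric about
#' 1/2 and shrinking onto 1/2 as lambda grows. For lambda = 0 the estimate
#' is unbounded in (0, 1).
#'
#' @param lambda Non-negative cost weight.
#' @return Numeric `c(low, high)`.
#' @export
#' @examples
#' stationary_bounds(1)  # 1/3, 2/3
stationary_bounds <- function(lambda) {
  lambda <- check_lambda(lambda)
  if (lambda == 0) return(c(low = 0, high = 1))
  c(low = lambda / (1 + 2 * lambda), high = (1 + lambda) / (1 + 2 * lambda))
}

#' AR(1) characterization of the precision-cost estimate
#'
#' In the stationary regime (filtered counts summing to 1/lambda) the
#' estimate follows a first-order autoregressive process:
#' p-hat_{N+1} = (1 - b) mu + b p-hat_N + g (x_{N+1} - p), with mean
#' mu = [expected_estimate()], coefficient b = 1/(1 + lambda), and
#' innovation gain g = lambda / ((1 + lambda)(1 + 2 lambda)). Small lambda
#' means slow mean reversion and long flights away from 1/2.
#'
#' @param p True head probability.
#' @param lambda Positive cost weight (at lambda = 0 the estimate is not an
#'   AR process and an error is raised).
#' @return A list with elements `mean`, `coefficient`, `innovation_gain`.
#' @export
ar1_parameters <- function(p, lambda) {
  lambda <- check_lambda(lambda)
  if (lambda == 0)
    stop("the Bayesian estimate (lambda = 0) does not follow an AR(1) process",
         call. = FALSE)
  list(mean = expected_estimate(p, lambda),
       coefficient = 1 / (1 + lambda),
       innovation_gain = lambda / ((1 + lambda) * (1 + 2 * lambda)))
}

#' Long-run expected posterior variance
#'
#' Closed form of the stationary expectation of [posterior_variance()] over
#' outcome sequences with head probability p:
#' \deqn{E[Var] = \frac{\lambda\,(\lambda(1+\lambda)(2+\lambda) + 2p(1-p))}
#'   {(2+\lambda)(1+2\lambda)^2(1+3\lambda)}.}
#' Limits: lambda * p(1-p) as lambda -> 0 (the Bayesian posterior
#' concentrates) and (1/12)(1 - 1/(3 lambda)) -> 1/12 as lambda -> infinity
#' (the belief stays uniform). The formula follows from the deterministic
#' stationary count sum 1/lambda and the variance of the filtered head
#' count p(1-p)/(lambda(lambda + 2)); see
#' [mc_expected_posterior_variance()] for the simulation cross-check.
#'
#' @param p True head probability in \[0, 1\].
#' @param lambda Non-negative cost weight.
#' @return The expected posterior variance.
#' @export
expected_posterior_variance <- function(p, lambda) {
  lambda <- check_lambda(lambda)
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (lambda == 0) return(0 * p)
  lambda * (lambda * (1 + lambda) * (2 + lambda) + 2 * p * (1 - p)) /
    ((2 + lambda) * (1 + 2 * lambda)^2 * (1 + 3 * lambda))
}

#' Monte-Carlo oracle for the expected posterior variance
#'
#' Averages [posterior_variance()] at the end of `runs` independently
#' simulated sequences of `n_flips` outcomes. Serves as the simulation
#' ground truth that the closed form [expected_posterior_variance()] is
#' tested against.
#'
#' @param p True head probability.
#' @param lambda Non-negative cost weight.
#' @param n_flips Sequence length per run.
#' @param runs Number of independent sequences.
#' @param seed Integer seed.
#' @return A list with `mean` (Monte-Carlo estimate) and `se` (standard
#'   error over runs).
#' @export
mc_expected_posterior_variance <- function(p, lambda, n_flips = 1e4, runs = 200,
                                           seed = 1) {
  lambda <- check_lambda(lambda)
  set.seed(seed)
  r <- 1 / (1 + lambda)
  v <- vapply(seq_len(runs), function(i) {
    x <- stats::rbinom(n_flips, 1L, p)
    n1 <- as.numeric(stats::filter(r * x, r, method = "recursive"))[n_flips]
    s <- if (lambda == 0) n_flips else r * (1 - r^n_flips) / (1 - r)
    posterior_variance(beta_posterior(n1, s - n1))
  }, numeric(1))
  list(mean = mean(v), se = stats::sd(v) / sqrt(runs))
}

#' Grid density of a precision-cost belief
#'
#' The Beta(nhat1 + 1, nhat0 + 1) belief discretized on a K-cell grid, for
#' comparison with grid-based observers and the numerical minimizer.
#'
#' @param post A [beta_posterior()].
#' @param K Grid resolution.
#' @return A [grid_distribution()].
#' @export
precision_posterior_grid <- function(post, K) {
  grid_beta(post$nhat1 + 1, post$nhat0 + 1, K)
}
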