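#' Log per-observation factor of the unpredictability-cost posterior
#'
#' After N flips with empirical head frequency f = n/N, the
#' unpredictability-cost belief is proportional to the N-th power of
#' \deqn{\varphi_f(p) = p^f (1-p)^{1-f} e^{-\lambda H(p)},}
#' where H is the Bernoulli outcome entropy. This returns
#' log phi = f log(p) + (1 - f) log(1 - p) - lambda H(p), up to an additive
#' constant. Its maxima determine the inferred probability at large N.
#'
#' @param p Evaluation points in (0, 1) (vectorized). The endpoint values 0
#'   and 1 are allowed only when f is exactly 0 or 1.
#' @param f Empirical head frequency in \[0, 1\].
#' @param lambda Non-negative cost weight.
#' @return Log values (additive constant ignored); -Inf at unreachable
#'   endpoints.
#' @export
#' @examples
#' log_phi(0.5, 0.5, 2)  # -3 log(2)
log_phi <- function(p, f, lambda) {
  lambda <- check_lambda(lambda)
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("`f` must be a single frequency in [0, 1]", call. = FALSE)
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  out <- rep(-Inf, length(p))
  inner <- p > 0 & p < 1
  q <- p[inner]
  out[inner] <- f * log(q) + (1 - f) * log1p(-q) - lambda * bernoulli_entropy(q)
  if (f == 0) out[p == 0] <- 0
  if (f == 1) out[p == 1] <- 0
  out
}

#' Per-observation profile on a grid
#'
#' Evaluates [log_phi()] at the midpoints of a K-cell grid and returns it as
#' a `phi_profile` object (frequency, cost weight, grid log-values up to an
#' additive constant).
#'
#' @param f Empirical head frequency in \[0, 1\].
#' @param lambda Non-negative cost weight.
#' @param K Grid resolution (default 2001, odd so 0.5 is a cell center).
#' @return An object of class `phi_profile`.
#' @export
phi_profile <- function(f, lambda, K = 2001) {
  centers <- (seq_len(K) - 0.5) / K
  structure(list(f = f, lambda = check_lambda(lambda), K = K,
                 centers = centers, log_values = log_phi(centers, f, lambda)),
            class = "phi_profile")
}

#' @export
print.phi_profile <- function(x, ...) {
  cat(sprintf("<phi_profile> f = %.6g, lambda = %g, K = %d; grid argmax at p = %.4f\n",
              x$f, x$lambda, x$K, x$centers[which.max(x$log_values)]))
  invisible(x)
}

#' Unpredictability-cost posterior on a grid
#'
#' The belief after observing n heads in N flips: a density proportional to
#' \eqn{[\varphi_{n/N}(p)]^N}, computed in log space with max-subtraction
#' before exponentiation so that N up to 10^6 is numerically safe. The
#' posterior depends on the sequence only through (n, N) — no path
#' dependence — and concentrates as N grows. N = 0 returns the uniform
#' prior.
#'
#' @param n Number of heads (0 <= n <= N).
#' @param N Number of flips.
#' @param lambda Non-negative cost weight.
#' @param K Grid resolution.
#' @return A [grid_distribution()].
#' @export
unpredictability_posterior <- function(n, N, lambda, K = 2001) {
  lambda <- check_lambda(lambda)
  n <- as.numeric(n); N <- as.numeric(N)
  if (N < 0 || n < 0 || n > N) stop("need 0 <= n <= N", call. = FALSE)
  if (N == 0) return(make_grid(K))
  centers <- (seq_len(K) - 0.5) / K
  grid_from_log(N * log_phi(centers, n / N, lambda))
}

# First derivative of log_phi in p: (f - p)/(p(1-p)) + lambda*log(p/(1-p)).
dlog_phi <- function(p, f, lambda) {
  (f - p) / (p * (1 - p)) + lambda * (log(p) - log1p(-p))
}

# Curvature of log_phi at p = 1/2 for f = 1/2 is 4*(lambda - 1): the
# pitchfork criterion separating one maximum (lambda < 1) from two.
phi_curvature_at_half <- function(lambda) 4 * (check_lambda(lambda) - 1)

#' Local maxima of the per-observation profile
#'
#' Locates the interior local maxima of [log_phi()] for a given empirical
#' frequency f and cost weight lambda, by scanning the derivative
#' (f - p)/(p(1-p)) + lambda log(p/(1-p)) for downward sign changes and
#' refining each bracket with root-finding. The profile has either one
#' maximum or two (the bifurcated regime); at f = 1/2 two maxima exist
#' exactly when lambda > 1.
#'
#' @param f Empirical head frequency in \[0, 1\]. The degenerate endpoint
#'   frequencies 0 and 1 give a single boundary maximum at 0 or 1.
#' @param lambda Non-negative cost weight.
#' @return An object of class `bifurcation_result`: list with `lambda`, `f`,
#'   `maxima` (increasing locations), `log_heights`.
#' @export
find_local_maxima <- function(f, lambda) {
  lambda <- check_lambda(lambda)
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("`f` must be a single frequency in [0, 1]", call. = FALSE)
  if (f == 0 || f == 1) {
    return(structure(list(lambda = lambda, f = f, maxima = f, log_heights = 0),
                     class = "bifurcation_result"))
  }
  delta <- 1e-9
  grid <- seq(delta, 1 - delta, length.out = 4001)
  g <- dlog_phi(grid, f, lambda)
  # downward sign changes of the derivative bracket local maxima
  idx <- which(g[-length(g)] > 0 & g[-1] <= 0)
  maxima <- vapply(idx, function(i) {
    stats::uniroot(function(p) dlog_phi(p, f, lambda),
                   c(grid[i], grid[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  if (length(maxima) == 0) maxima <- grid[which.max(log_phi(grid, f, lambda))]
  structure(list(lambda = lambda, f = f, maxima = maxima,
                 log_heights = log_phi(maxima, f, lambda)),
            class = "bifurcation_result")
}

#' @export
print.bifurcation_result <- function(x, ...) {
  cat(sprintf("<bifurcation_result> lambda = %g, f = %.6g: %d maxim%s at %s\n",
              x$lambda, x$f, length(x$maxima),
              if (length(x$maxima) == 1) "um" else "a",
              paste(sprintf("%.6f", x$maxima), collapse = ", ")))
  invisible(x)
}

#' Large-N inferred probability of the unpredictability-cost observer
#'
#' The location of the global maximum of the per-observation profile: the
#' value the belief concentrates on as N grows with empirical frequency f
#' held fixed. For lambda > 0 the cost exacerbates the empirical bias
#' (|p-hat - 1/2| >= |f - 1/2|); for lambda > 1 even an infinitesimal bias
#' yields an appreciable inferred bias. At the symmetric point f = 1/2 with
#' lambda > 1 the two maxima are co-equal: the return value carries both
#' locations and attribute `tie = TRUE`.
#'
#' @param f Empirical head frequency in \[0, 1\].
#' @param lambda Non-negative cost weight.
#' @return The global argmax (length 1), or both locations with attribute
#'   `tie = TRUE` on an exact tie.
#' @export
#' @examples
#' asymptotic_estimate(0.6, 0)    # 0.6
#' asymptotic_estimate(0.5, 0.5)  # 0.5
asymptotic_estimate <- function(f, lambda) {
  res <- find_local_maxima(f, lambda)
  if (length(res$maxima) == 1L) return(res$maxima)
  d <- res$log_heights[2] - res$log_heights[1]
  if (abs(d) < 1e-12)
    return(structure(res$maxima, tie = TRUE))
  res$maxima[which.max(res$log_heights)]
}

#' Fixed points of the fair-coin profile
#'
#' For f = 1/2 the profile maxima converge, as lambda crosses 1 from below,
#' from the single point 1/2 into a symmetric pair p_low < 1/2 < p_high with
#' p_low = 1 - p_high (a pitchfork bifurcation). p_high solves
#' (2p - 1)/(2 p (1 - p)) = lambda log(p/(1-p)) on (1/2, 1), found by
#' root-finding on the bracket (1/2 + 1e-9, 1 - 1e-9) to tolerance 1e-12.
#'
#' @param lambda Non-negative cost weight.
#' @return A `bifurcation_result` with one location (0.5) for lambda <= 1,
#'   two symmetric locations for lambda > 1.
#' @export
#' @examples
#' fixed_points(2)$maxima  # ~0.102, ~0.898
fixed_points <- function(lambda) {
  lambda <- check_lambda(lambda)
  if (lambda <= 1) {
    return(structure(list(lambda = lambda, f = 0.5, maxima = 0.5,
                          log_heights = log_phi(0.5, 0.5, lambda)),
                     class = "bifurcation_result"))
  }
  delta <- 1e-9
  p_high <- stats::uniroot(function(p) dlog_phi(p, 0.5, lambda),
                           c(0.5 + delta, 1 - delta), tol = 1e-12)$root
  maxima <- c(1 - p_high, p_high)
  structure(list(lambda = lambda, f = 0.5, maxima = maxima,
                 log_heights = log_phi(maxima, 0.5, lambda)),
            class = "bifurcation_result")
}

#' Precomputed estimate-versus-frequency profile
#'
#' Builds a fast interpolator for [asymptotic_estimate()] as a function of
#' the empirical frequency f, for repeated trajectory evaluation at a fixed
#' lambda. The global-argmax curve is interpolated separately on each side
#' of f = 1/2 (it is discontinuous there for lambda > 1); exact ties at
#' f = 1/2 are resolved by the `prev_sign` argument (hysteresis).
#'
#' @param lambda Non-negative cost weight.
#' @param n_points Interpolation nodes per half-interval.
#' @return A function `(f, prev_sign = 0)` vectorized in `f`.
#' @export
estimate_profile <- function(lambda, n_points = 1024) {
  lambda <- check_lambda(lambda)
  eps <- 1e-7
  f_lo <- seq(eps, 0.5 - eps, length.out = n_points)
  f_hi <- 1 - rev(f_lo)
  est_lo <- vapply(f_lo, function(f) asymptotic_estimate(f, lambda)[1], numeric(1))
  est_hi <- rev(1 - est_lo)  # symmetry p_hat(1 - f) = 1 - p_hat(f)
  at_half <- fixed_points(lambda)$maxima  # length 1 (<=1) or 2 (>1)
  lower_half <- at_half[1]
  upper_half <- at_half[length(at_half)]
  fn_lo <- stats::approxfun(c(f_lo, 0.5), c(est_lo, lower_half), rule = 2)
  fn_hi <- stats::approxfun(c(0.5, f_hi), c(upper_half, est_hi), rule = 2)
  function(f, prev_sign = 0) {
    out <- numeric(length(f))
    lo <- f < 0.5; hi <- f > 0.5; tie <- f == 0.5
    out[lo] <- fn_lo(f[lo])
    out[hi] <- fn_hi(f[hi])
    if (any(tie)) out[tie] <- if (prev_sign >= 0) upper_half else lower_half
    out
  }
}

#' Export a bifurcation result as JSON
#'
#' Writes the cost weight, empirical frequency, maxima locations and their
#' log-heights to a JSON file.
#'
#' @param res A `bifurcation_result` from [find_local_maxima()] or
#'   [fixed_points()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bifurcation_result <- function(res, path) {
  stopifnot(inherits(res, "bifurcation_result"))
  jsonlite::write_json(
    list(lambda = res$lambda, f = res$f, maxima = res$maxima,
         log_heights = res$log_heights),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
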