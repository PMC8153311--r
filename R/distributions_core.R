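#' Binary outcome sequence
#'
#' Container for an ordered sequence of coin-flip outcomes (1 = 'head',
#' 0 = 'tail'), the basic input of every observer in the package.
#'
#' @param outcomes Integer or numeric vector of 0/1 outcomes.
#' @param p_true Optional generating probability in \[0, 1\] (recorded for
#'   provenance when the sequence was simulated).
#' @param seed Optional integer seed used to generate the sequence.
#'
#' @return An object of class `coin_sequence`: a list with elements
#'   `outcomes`, `N` (number of flips), `n` (number of heads), `p_true`,
#'   `seed`.
#' @seealso [simulate_coin()] to draw a sequence, [write_coin_sequence()].
#' @export
#' @examples
#' coin_sequence(c(1, 0, 1, 1))
coin_sequence <- function(outcomes, p_true = NULL, seed = NULL) {
  outcomes <- as.integer(outcomes)
  if (length(outcomes) < 1L || anyNA(outcomes) || !all(outcomes %in% c(0L, 1L)))
    stop("`outcomes` must be a non-empty vector of 0/1 values", call. = FALSE)
  if (!is.null(p_true)) {
    p_true <- as.numeric(p_true)
    if (length(p_true) != 1L || is.na(p_true) || p_true < 0 || p_true > 1)
      stop("`p_true` must be a single probability in [0, 1]", call. = FALSE)
  }
  structure(
    list(outcomes = outcomes, N = length(outcomes), n = sum(outcomes),
         p_true = p_true, seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "coin_sequence"
  )
}

#' @export
print.coin_sequence <- function(x, ...) {
  cat(sprintf("<coin_sequence> N = %d flips, n = %d heads (freq %.4f)\n",
              x$N, x$n, x$n / x$N))
  if (!is.null(x$p_true)) cat(sprintf("  p_true = %g", x$p_true))
  if (!is.null(x$seed)) cat(sprintf("  seed = %d", x$seed))
  if (!is.null(x$p_true) || !is.null(x$seed)) cat("\n")
  invisible(x)
}

# Validate a cost weight: a single non-negative real.
check_lambda <- function(lambda) {
  lambda <- as.numeric(lambda)
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("`lambda` must be a single non-negative number", call. = FALSE)
  lambda
}

#' Discretized density on the open unit interval
#'
#' Represents a probability density over the Bernoulli parameter p as masses
#' on K equal-width cells tiling (0, 1), evaluated at cell midpoints. The
#' endpoints 0 and 1 are excluded so that log(p) and log(1 - p) stay finite
#' on the grid.
#'
#' @param masses Numeric vector of K non-negative cell masses summing to 1.
#' @param centers Optional midpoints; defaults to the canonical midpoint grid
#'   `(seq_len(K) - 0.5) / K`.
#'
#' @return An object of class `grid_distribution` with elements `K`,
#'   `centers`, `masses`.
#' @seealso [make_grid()] for the uniform density, [precision_cost()],
#'   [unpredictability_cost()], [kl_divergence()].
#' @export
grid_distribution <- function(masses, centers = NULL) {
  masses <- as.numeric(masses)
  K <- length(masses)
  if (K < 2L) stop("a grid distribution needs at least 2 cells", call. = FALSE)
  if (anyNA(masses) || any(masses < 0))
    stop("`masses` must be non-negative and free of NAs", call. = FALSE)
  s <- sum(masses)
  if (abs(s - 1) > 1e-10)
    stop(sprintf("`masses` must sum to 1 (got %.12g)", s), call. = FALSE)
  if (is.null(centers)) {
    centers <- (seq_len(K) - 0.5) / K
  } else {
    centers <- as.numeric(centers)
    if (length(centers) != K) stop("`centers` must match `masses` in length", call. = FALSE)
    if (any(centers <= 0) || any(centers >= 1) || any(diff(centers) <= 0))
      stop("`centers` must be strictly increasing inside (0, 1)", call. = FALSE)
    if (max(abs(diff(centers) - 1 / K)) > 1e-8)
      stop("`centers` must be equally spaced with spacing 1/K", call. = FALSE)
  }
  structure(list(K = K, centers = centers, masses = masses),
            class = "grid_distribution")
}

#' @export
print.grid_distribution <- function(x, ...) {
  m <- sum(x$masses * x$centers)
  cat(sprintf("<grid_distribution> K = %d cells on (0,1); mean = %.4f, entropy cost = %.4f nats\n",
              x$K, m, precision_cost(x)))
  invisible(x)
}

#' Uniform grid density
#'
#' The uniform density on (0, 1) discretized on K midpoint cells: the prior
#' every observer starts from, and the zero point of the precision cost.
#'
#' @param K Number of cells (at least 2). The package default elsewhere is
#'   2001, odd so that p = 0.5 is a representable cell center.
#' @return A `grid_distribution` with all masses equal to 1/K.
#' @export
#' @examples
#' make_grid(4)$centers   # 0.125 0.375 0.625 0.875
make_grid <- function(K) {
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 2L)
    stop("`K` must be a single integer >= 2", call. = FALSE)
  grid_distribution(rep(1 / K, K))
}

# Build a grid_distribution from unnormalized log-density values at the
# canonical midpoints of a K-cell grid (max-subtracted before exponentiation).
grid_from_log <- function(log_vals, K = length(log_vals)) {
  w <- exp(log_vals - max(log_vals))
  grid_distribution(w / sum(w))
}

#' Beta density discretized on the grid
#'
#' The Beta(a, b) density evaluated at the K cell midpoints and normalized
#' to cell masses; a convenient smooth test density and the shape of every
#' precision-cost belief.
#'
#' @param a,b Positive shape parameters.
#' @param K Grid resolution.
#' @return A [grid_distribution()].
#' @export
grid_beta <- function(a, b, K) {
  centers <- (seq_len(K) - 0.5) / K
  grid_from_log((a - 1) * log(centers) + (b - 1) * log1p(-centers))
}

#' Precision cost (negative differential entropy)
#'
#' The cost of representing a precise belief: the negative Shannon
#' differential entropy of the density, \eqn{\int P \ln P \, dp}, computed on
#' the grid as \eqn{\sum_i m_i \ln(m_i K)}. It is exactly zero for the uniform
#' density and grows as mass concentrates; it equals the Kullback-Leibler
#' divergence from the density to the uniform density on the same grid.
#'
#' @param dist A [grid_distribution()].
#' @return The cost in nats. Zero-mass cells contribute 0 (the x log x limit).
#' @export
#' @examples
#' precision_cost(make_grid(100))                 # 0
#' precision_cost(grid_beta(2, 2, 4096))          # ~ log(6) - 5/3
precision_cost <- function(dist) {
  stopifnot(inherits(dist, "grid_distribution"))
  m <- dist$masses
  pos <- m > 0
  sum(m[pos] * log(m[pos] * dist$K))
}

#' Bernoulli outcome entropy
#'
#' Shannon entropy of a single coin flip with head probability p,
#' \eqn{H(p) = -p \ln p - (1-p) \ln(1-p)}, in nats. Endpoints use the limit
#' convention H(0) = H(1) = 0.
#'
#' @param p Probability (vectorized), each in \[0, 1\].
#' @return Entropy values in \[0, ln 2\].
#' @export
#' @examples
#' bernoulli_entropy(0.5)  # log(2)
bernoulli_entropy <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  h <- numeric(length(p))
  inner <- p > 0 & p < 1
  q <- p[inner]
  h[inner] <- -q * log(q) - (1 - q) * log1p(-q)
  h
}

#' Unpredictability cost (expected outcome entropy)
#'
#' The cost of believing in an unpredictable environment: the Bernoulli
#' outcome entropy H(p) averaged over the belief,
#' \eqn{\sum_i m_i H(c_i)}. Bounded in \[0, ln 2\]; maximal for a belief
#' concentrated at p = 1/2, minimal for beliefs concentrated near a
#' deterministic coin.
#'
#' @param dist A [grid_distribution()].
#' @return The cost in nats.
#' @export
unpredictability_cost <- function(dist) {
  stopifnot(inherits(dist, "grid_distribution"))
  sum(dist$masses * bernoulli_entropy(dist$centers))
}

#' Kullback-Leibler divergence between two grid densities
#'
#' \eqn{D_{KL}(Q \| P) = \sum_i q_i \ln(q_i / p_i)} over cells where Q has
#' mass. The divergence the observers minimize against the one-step Bayesian
#' posterior.
#'
#' @param Q,P [grid_distribution()] objects on the same grid.
#' @return Non-negative divergence in nats; `Inf` if Q puts mass where P has
#'   none.
#' @export
kl_divergence <- function(Q, P) {
  stopifnot(inherits(Q, "grid_distribution"), inherits(P, "grid_distribution"))
  if (Q$K != P$K || max(abs(Q$centers - P$centers)) > 1e-12)
    stop("Q and P must live on the same grid", call. = FALSE)
  q <- Q$masses; p <- P$masses
  pos <- q > 0
  if (any(p[pos] == 0)) return(Inf)
  sum(q[pos] * (log(q[pos]) - log(p[pos])))
}

#' Write / read a grid density as CSV
#'
#' Two-column CSV (`center`, `mass`); the inverse reconstructs the
#' `grid_distribution`.
#'
#' @param dist A [grid_distribution()].
#' @param path File path.
#' @return `write_grid_distribution` returns `path` invisibly;
#'   `read_grid_distribution` returns a `grid_distribution`.
#' @export
write_grid_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "grid_distribution"))
  utils::write.csv(data.frame(center = dist$centers, mass = dist$masses),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_distribution
#' @export
read_grid_distribution <- function(path) {
  df <- utils::read.csv(path)
  m <- df$mass
  grid_distribution(m / sum(m), df$center)
}

#' Write / read a coin sequence as CSV plus JSON sidecar
#'
#' One-column CSV of 0/1 outcomes; a `.json` sidecar records `p_true`,
#' `seed`, `N` and `n`.
#'
#' @param seq A [coin_sequence()].
#' @param path CSV file path; the sidecar is `path` with `.json` appended.
#' @return `write_coin_sequence` returns `path` invisibly;
#'   `read_coin_sequence` returns a `coin_sequence`.
#' @export
write_coin_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "coin_sequence"))
  utils::write.csv(data.frame(outcome = seq$outcomes), path, row.names = FALSE)
  meta <- list(N = seq$N, n = seq$n)
  if (!is.null(seq$p_true)) meta$p_true <- seq$p_true
  if (!is.null(seq$seed)) meta$seed <- seq$seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coin_sequence
#' @export
read_coin_sequence <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  coin_sequence(df$outcome,
                p_true = meta$p_true,
                seed = meta$seed)
}
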