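#' Simulate a Bernoulli coin-flip sequence
#'
#' Draws N independent flips with head probability p, reproducibly from an
#' integer seed.
#'
#' @param p Head probability in \[0, 1\].
#' @param N Number of flips (>= 1).
#' @param seed Integer seed.
#' @return A [coin_sequence()] with `p_true` and `seed` recorded.
#' @export
#' @examples
#' simulate_coin(0.5, 10, seed = 7)
simulate_coin <- function(p, N, seed) {
  p <- as.numeric(p)
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("`p` must be a single probability in [0, 1]", call. = FALSE)
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 1L)
    stop("`N` must be a single integer >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  coin_sequence(stats::rbinom(N, 1L, p), p_true = p, seed = seed)
}

# Replace zero entries of a sign vector by the most recent nonzero sign
# (hysteresis); leading zeros are left at 0.
fill_zero_signs <- function(s) {
  idx <- which(s != 0)
  if (length(idx) == 0L) return(s)
  pos <- findInterval(seq_along(s), idx)
  out <- numeric(length(s))
  out[pos > 0] <- s[idx[pos[pos > 0]]]
  out
}

#' Run a costly observer over a sequence
#'
#' Produces the time series of point estimates p-hat_1..p-hat_N. The
#' precision observer uses the closed-form fast path (recursively filtered
#' counts, Beta posterior mean; no grid needed). The unpredictability
#' observer reports the global argmax of the per-observation profile at the
#' running empirical frequency n/N; an exact tie at n = N/2 (possible for
#' lambda > 1) keeps the estimate on the branch of the previous sign
#' (hysteresis). Estimates start at flip 1; the prior mean 0.5 is not part
#' of the trajectory.
#'
#' @param seq A [coin_sequence()].
#' @param lambda Non-negative cost weight.
#' @param cost `"precision"` or `"unpredictability"`.
#' @param profile Optional precomputed estimate-vs-frequency function for the
#'   unpredictability observer (see [estimate_profile()]); pass it when
#'   running many sequences at the same lambda.
#' @return An object of class `estimate_trajectory`: list with `estimates`,
#'   `cost_type`, `lambda`, `source`, and for the precision observer the
#'   filtered-count series `nhat1` and their (deterministic) sum `count_sum`.
#' @export
#' @examples
#' run_observer(coin_sequence(c(1, 1, 0)), 0, "precision")$estimates
run_observer <- function(seq, lambda, cost = c("precision", "unpredictability"),
                         profile = NULL) {
  stopifnot(inherits(seq, "coin_sequence"))
  cost <- match.arg(cost)
  lambda <- check_lambda(lambda)
  x <- seq$outcomes
  N <- seq$N
  if (cost == "precision") {
    r <- 1 / (1 + lambda)
    nhat1 <- as.numeric(stats::filter(r * x, r, method = "recursive"))
    count_sum <- if (lambda == 0) as.numeric(seq_len(N))
                 else r * (1 - r^seq_len(N)) / (1 - r)
    estimates <- (nhat1 + 1) / (count_sum + 2)
    out <- list(estimates = estimates, cost_type = cost, lambda = lambda,
                source = seq, nhat1 = nhat1, count_sum = count_sum)
  } else {
    if (is.null(profile)) profile <- estimate_profile(lambda)
    f <- cumsum(x) / seq_len(N)
    estimates <- profile(f)
    tie <- which(f == 0.5)
    if (length(tie) > 0L) {
      s <- fill_zero_signs(sign(f - 0.5))
      branch <- fixed_points(lambda)$maxima
      lower <- branch[1]; upper <- branch[length(branch)]
      estimates[tie] <- ifelse(s[tie] >= 0, upper, lower)
    }
    out <- list(estimates = estimates, cost_type = cost, lambda = lambda,
                source = seq)
  }
  structure(out, class = "estimate_trajectory")
}

#' @export
print.estimate_trajectory <- function(x, ...) {
  cat(sprintf("<estimate_trajectory> %s cost, lambda = %g, N = %d flips; final p_hat = %.4f\n",
              x$cost_type, x$lambda, length(x$estimates),
              x$estimates[length(x$estimates)]))
  invisible(x)
}

#' Flights of constant inferred-bias sign
#'
#' Splits a trajectory into maximal runs ("flights") over which the sign of
#' p-hat - 1/2 is constant. Estimates exactly at 1/2 inherit the previous
#' sign (hysteresis: the belief only switches when the estimate crosses
#' 1/2); an initial stretch at exactly 1/2 is discarded. The final run is
#' right-censored by the end of the experiment and is excluded from
#' duration statistics by default; `censor = "both"` also drops the first
#' run.
#'
#' @param traj An [run_observer()] trajectory (length >= 2).
#' @param censor Which boundary runs to drop: `"last"` (default) or
#'   `"both"`.
#' @return A data frame of class `flight_record` with columns `start_index`,
#'   `duration_T`, `sign` (`"above"`/`"below"`).
#' @export
flight_durations <- function(traj, censor = c("last", "both")) {
  stopifnot(inherits(traj, "estimate_trajectory"))
  censor <- match.arg(censor)
  est <- traj$estimates
  if (length(est) < 2L) stop("trajectory must have length >= 2", call. = FALSE)
  s <- fill_zero_signs(sign(est - 0.5))
  keep <- s != 0  # initial undecided stretch at exactly 1/2
  s <- s[keep]
  offset <- which(keep)[1] - 1L
  if (length(s) == 0L)
    return(structure(data.frame(start_index = integer(), duration_T = integer(),
                                sign = character()),
                     class = c("flight_record", "data.frame")))
  runs <- rle(s)
  start <- offset + c(1L, 1L + cumsum(runs$lengths[-length(runs$lengths)]))
  rec <- data.frame(start_index = start,
                    duration_T = runs$lengths,
                    sign = ifelse(runs$values > 0, "above", "below"),
                    stringsAsFactors = FALSE)
  drop <- nrow(rec)  # right-censored final flight
  if (censor == "both" && nrow(rec) > 1L) drop <- c(1L, drop)
  rec <- rec[-drop, , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec, class = c("flight_record", "data.frame"))
}

#' Mean flight duration
#'
#' Arithmetic mean of the uncensored flight durations. For the precision
#' observer on a fair coin with lambda >= 1 the durations are
#' geometric(1/2), so the mean is 2 flips.
#'
#' @param records A [flight_durations()] result.
#' @return Mean duration in flips.
#' @export
mean_flight_duration <- function(records) {
  stopifnot(inherits(records, "flight_record"))
  if (nrow(records) == 0L)
    stop("no uncensored flights to average", call. = FALSE)
  if (nrow(records) < 100L)
    warning("fewer than 100 flights; the mean is a noisy estimate")
  mean(records$duration_T)
}

#' Random walk of head-count fluctuations
#'
#' The partial sums of (x_i - 1/2), i.e. n_k - k/2: the unbiased random
#' walk whose sign drives the unpredictability observer's belief switches.
#' Values are exact multiples of 1/2 (internally the doubled, integer-valued
#' walk is used).
#'
#' @param seq A [coin_sequence()].
#' @return Numeric vector of length N.
#' @export
#' @examples
#' random_walk(coin_sequence(c(1, 0, 1, 0)))  # 0.5 0 0.5 0
random_walk <- function(seq) {
  stopifnot(inherits(seq, "coin_sequence"))
  cumsum(2L * seq$outcomes - 1L) / 2
}

#' Majority-side sojourn fraction of a walk
#'
#' Per-step side of the walk (sign of its value, zeros inheriting the
#' previous side — the standard sojourn convention), the fraction of steps
#' spent on the positive side, and the fraction on the majority side. For
#' an unbiased walk the side fraction follows the arcsine law, so the
#' majority fraction averages 1/2 + 1/pi (about 81.8%) regardless of walk
#' length.
#'
#' @param walk Numeric walk values (length >= 2), e.g. from [random_walk()].
#' @return An object of class `walk_stats`: list with `side_fraction`
#'   (positive side) and `t_maj`.
#' @export
majority_side_fraction <- function(walk) {
  walk <- as.numeric(walk)
  if (length(walk) < 2L) stop("walk must have length >= 2", call. = FALSE)
  s <- fill_zero_signs(sign(walk))
  s <- s[s != 0]
  if (length(s) == 0L) stop("degenerate all-zero walk", call. = FALSE)
  frac <- mean(s > 0)
  structure(list(side_fraction = frac, t_maj = max(frac, 1 - frac)),
            class = "walk_stats")
}

#' @export
print.walk_stats <- function(x, ...) {
  cat(sprintf("<walk_stats> positive-side fraction = %.4f, majority-side fraction = %.4f\n",
              x$side_fraction, x$t_maj))
  invisible(x)
}

#' Expected majority-side fraction under the arcsine law
#'
#' Closed-form mean of max(U, 1 - U) when U follows the arcsine density
#' 1/(pi sqrt(u(1-u))) on (0, 1): equal to 1/2 + 1/pi, about 0.8183. This
#' is the long-run average fraction of time an unbiased random walk spends
#' on its majority side.
#'
#' @return 1/2 + 1/pi.
#' @export
folded_arcsine_mean <- function() 0.5 + 1 / pi

#' Ensemble majority-side statistics of fair random walks
#'
#' Simulates `runs` independent fair-coin sequences of `N` flips, forms each
#' walk of partial sums of (x_i - 1/2), and collects the per-walk
#' majority-side fractions. Their mean estimates the folded-arcsine
#' expectation 1/2 + 1/pi.
#'
#' @param runs Number of walks.
#' @param N Steps per walk.
#' @param seed Integer base seed; run i uses `seed + i - 1`.
#' @return A list with `t_maj` (per-run fractions), `mean`, `se`, and
#'   `side_fraction` (per-run positive-side fractions).
#' @export
ensemble_majority_fraction <- function(runs, N, seed) {
  seed <- as.integer(seed)
  side <- vapply(seq_len(runs), function(i) {
    walk <- random_walk(simulate_coin(0.5, N, seed + i - 1L))
    majority_side_fraction(walk)$side_fraction
  }, numeric(1))
  t_maj <- pmax(side, 1 - side)
  list(t_maj = t_maj, mean = mean(t_maj), se = stats::sd(t_maj) / sqrt(runs),
       side_fraction = side)
}

#' Majority-belief fraction of the unpredictability observer
#'
#' For a strong unpredictability cost (lambda > 1) on a fair coin the
#' inferred bias never converges: it switches between the two fixed points
#' as the head-count random walk crosses zero. This measures, per run, the
#' fraction of flips (after burn-in) spent at the majority sign of
#' p-hat - 1/2 (with hysteresis at ties), averaged over `runs` simulated
#' sequences. The expected value is the folded-arcsine mean, about 0.82,
#' independent of N.
#'
#' @param p True head probability (0.5 for the fair-coin scenario).
#' @param lambda Cost weight; must exceed 1 (below the bifurcation the
#'   estimate converges to 1/2 and there is no switching to measure).
#' @param N Flips per run.
#' @param runs Number of runs.
#' @param seed Integer base seed; run i uses `seed + i - 1`.
#' @param burn_in Flips discarded at the start of each run (default 100).
#' @return A list with `fractions` (per-run majority-belief fractions),
#'   `mean`, and `se`.
#' @export
switch_fraction_unpredictability <- function(p, lambda, N, runs, seed,
                                             burn_in = 100) {
  lambda <- check_lambda(lambda)
  if (lambda <= 1)
    stop("below the bifurcation (lambda <= 1) the estimate converges to 1/2; ",
         "no switching to measure", call. = FALSE)
  if (N <= burn_in) stop("`N` must exceed `burn_in`", call. = FALSE)
  seed <- as.integer(seed)
  prof <- estimate_profile(lambda)
  fractions <- vapply(seq_len(runs), function(i) {
    seq_i <- simulate_coin(p, N, seed + i - 1L)
    traj <- run_observer(seq_i, lambda, "unpredictability", profile = prof)
    s <- fill_zero_signs(sign(traj$estimates - 0.5))
    s <- s[(burn_in + 1):N]
    s <- s[s != 0]
    frac <- mean(s > 0)
    max(frac, 1 - frac)
  }, numeric(1))
  list(fractions = fractions, mean = mean(fractions),
       se = stats::sd(fractions) / sqrt(runs))
}
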