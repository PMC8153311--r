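test_that("simulate_coin is reproducible and respects degenerate probabilities", {
  expect_equal(simulate_coin(1, 10, 1)$outcomes, rep(1L, 10))
  expect_equal(simulate_coin(0, 10, 1)$outcomes, rep(0L, 10))
  a <- simulate_coin(0.5, 100, 99)
  b <- simulate_coin(0.5, 100, 99)
  expect_identical(a$outcomes, b$outcomes)
  big <- simulate_coin(0.5, 1e5, 3)
  expect_lt(abs(big$n / big$N - 0.5), 4 / sqrt(big$N))
})

test_that("run_observer produces the Bayes-Laplace mean at zero cost", {
  s <- coin_sequence(c(1, 1, 0, 1))
  traj <- run_observer(s, 0, "precision")
  expect_equal(traj$estimates,
               (cumsum(s$outcomes) + 1) / (seq_len(4) + 2))
})

test_that("a streak then one tail reverses the lambda = 1 belief to exactly 1/2", {
  traj <- run_observer(coin_sequence(c(rep(1, 200), 0)), 1, "precision")
  expect_equal(traj$estimates[200], 2 / 3, tolerance = 1e-12)
  expect_equal(traj$estimates[201], 0.5, tolerance = 1e-14)
})

test_that("the unpredictability trajectory lives near the fixed points", {
  traj <- run_observer(simulate_coin(0.5, 1e4, 5), 2, "unpredictability")
  fp <- fixed_points(2)$maxima
  est <- traj$estimates[101:1e4]
  dist_to_fp <- pmin(abs(est - fp[1]), abs(est - fp[2]))
  expect_lt(max(dist_to_fp), 0.02)
  # sign of the estimate equals sign of the walk at every non-tie step
  walk <- random_walk(traj$source)[101:1e4]
  nontie <- walk != 0
  expect_equal(sign(est - 0.5)[nontie], sign(walk)[nontie])
})

test_that("flight segmentation applies hysteresis and censoring", {
  mk_traj <- function(est) structure(
    list(estimates = est, cost_type = "precision", lambda = 1,
         source = coin_sequence(rep(1, length(est)))),
    class = "estimate_trajectory")
  # signs +,+,-,+ : final run censored
  fl <- flight_durations(mk_traj(c(0.6, 0.7, 0.4, 0.6)))
  expect_equal(fl$duration_T, c(2, 1))
  expect_equal(fl$sign, c("above", "below"))
  # censor both boundary runs
  fl2 <- flight_durations(mk_traj(c(0.6, 0.7, 0.4, 0.6)), censor = "both")
  expect_equal(fl2$duration_T, 1)
  # estimates at exactly 1/2 inherit the previous sign
  fl3 <- flight_durations(mk_traj(c(0.6, 0.5, 0.5, 0.4, 0.4, 0.6)))
  expect_equal(fl3$duration_T, c(3, 2))
  # an initial stretch at 1/2 is discarded
  fl4 <- flight_durations(mk_traj(c(0.5, 0.5, 0.6, 0.4, 0.6)))
  expect_equal(fl4$start_index[1], 3)
  expect_error(flight_durations(mk_traj(0.6)), "length >= 2")
})

test_that("mean_flight_duration averages geometric durations to 2", {
  set.seed(4)
  durations <- stats::rgeom(10000, 0.5) + 1
  rec <- structure(data.frame(start_index = seq_along(durations),
                              duration_T = durations,
                              sign = "above"),
                   class = c("flight_record", "data.frame"))
  expect_equal(mean_flight_duration(rec), 2, tolerance = 0.05)
  empty <- structure(data.frame(start_index = integer(), duration_T = integer(),
                                sign = character()),
                     class = c("flight_record", "data.frame"))
  expect_error(mean_flight_duration(empty), "no uncensored")
})

test_that("flight durations are geometric(1/2) for strong precision cost", {
  traj <- run_observer(simulate_coin(0.5, 2e5, 17), 2, "precision")
  fl <- flight_durations(traj)
  tab <- table(factor(pmin(fl$duration_T, 7), levels = 1:7))
  probs <- c(0.5^(1:6), 0.5^6)  # P(T = k), tail pooled at 7+
  expect_gt(stats::chisq.test(as.vector(tab), p = probs)$p.value, 0.01)
  # empirical P(T = k) close to (1/2)^k for k = 1..6
  phat <- as.vector(tab[1:6]) / nrow(fl)
  expect_equal(phat, 0.5^(1:6), tolerance = 0.05)
})

test_that("mean flight duration decreases with the cost weight", {
  means <- sapply(c(0.05, 0.2, 0.5, 1, 2), function(lam) {
    traj <- run_observer(simulate_coin(0.5, 2e5, 23), lam, "precision")
    mean_flight_duration(flight_durations(traj))
  })
  # non-increasing: strictly shorter flights up to lambda = 1, then flat at 2
  # (one flip can always flip the belief once lambda >= 1)
  expect_true(all(diff(means) < 0.03))
  expect_true(all(diff(means[1:4]) < 0))
  expect_gt(means[1], 2)                       # weak cost: long flights
  expect_equal(means[4], 2, tolerance = 0.1)   # lambda = 1: one flip away
})

test_that("conditional spread of the estimate is small under a weak cost", {
  sds <- sapply(c(0.1, 1), function(lam) {
    traj <- run_observer(simulate_coin(0.5, 1e5, 29), lam, "precision")
    est <- traj$estimates[1001:1e5]
    c(unconditional = stats::sd(est),
      conditional = stats::sd(diff(est)) / sqrt(2))
  })
  # innovation (conditional) spread grows with lambda ...
  expect_lt(sds["conditional", 1], sds["conditional", 2])
  # ... and is a much smaller share of the overall spread when lambda is small
  expect_lt(sds["conditional", 1] / sds["unconditional", 1],
            sds["conditional", 2] / sds["unconditional", 2])
})

test_that("random_walk forms the half-integer partial sums", {
  expect_equal(random_walk(coin_sequence(rep(1, 4))), c(0.5, 1, 1.5, 2))
  expect_equal(random_walk(coin_sequence(c(1, 0, 1, 0))), c(0.5, 0, 0.5, 0))
  ok <- sapply(1:100, function(i) {
    w <- random_walk(simulate_coin(0.5, 1e4, 300 + i))
    abs(w[1e4]) < 4 * sqrt(1e4) / 2
  })
  expect_gte(mean(ok), 0.99)
})

test_that("majority_side_fraction applies the sojourn zero convention", {
  expect_equal(majority_side_fraction(c(0.5, 1, 0.5, 1))$t_maj, 1)
  # zeros inherit the previous side
  ws <- majority_side_fraction(c(0.5, 0, -0.5, 0))
  expect_equal(ws$side_fraction, 0.5)
  expect_equal(ws$t_maj, 0.5)
  expect_error(majority_side_fraction(rep(0, 5)), "all-zero")
  w <- majority_side_fraction(c(-1, -2, -1, 0, 1))
  expect_equal(w$t_maj, max(w$side_fraction, 1 - w$side_fraction))
})

test_that("folded arcsine mean matches quadrature and simulation", {
  quad <- stats::integrate(function(u) pmax(u, 1 - u) / (pi * sqrt(u * (1 - u))),
                           0, 1, rel.tol = 1e-10)$value
  expect_equal(folded_arcsine_mean(), quad, tolerance = 1e-8)
  expect_equal(folded_arcsine_mean(), 0.8183, tolerance = 1e-4)
  # arcsine density integrates to 1
  expect_equal(stats::integrate(function(u) 1 / (pi * sqrt(u * (1 - u))),
                                0, 1, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
  ens <- ensemble_majority_fraction(500, 5000, 11)
  expect_lt(abs(ens$mean - folded_arcsine_mean()), 0.03)
})

test_that("side fractions of fair walks follow the arcsine distribution", {
  ens <- ensemble_majority_fraction(1000, 5000, 123)
  ks <- suppressWarnings(
    stats::ks.test(ens$side_fraction, function(q) 2 / pi * asin(sqrt(q))))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("switch intervals of the unpredictability observer are heavy-tailed", {
  traj <- run_observer(simulate_coin(0.5, 1e6, 37), 2, "unpredictability")
  fl <- flight_durations(traj)
  surv <- sapply(c(10, 100), function(t) mean(fl$duration_T > t))
  slope <- (log(surv[2]) - log(surv[1])) / log(10)
  # first-return scaling of a simple random walk: survival exponent -1/2
  expect_lt(abs(slope + 0.5), 0.15)
})

test_that("the majority-belief fraction is about 82% regardless of N", {
  sw3 <- switch_fraction_unpredictability(0.5, 2, 1e3, 300, 7)
  sw4 <- switch_fraction_unpredictability(0.5, 2, 1e4, 300, 7)
  expect_lt(abs(sw3$mean - sw4$mean), 0.03)
  expect_equal(sw4$mean, folded_arcsine_mean(), tolerance = 0.03)
  # a biased coin settles into one dominant belief
  swb <- switch_fraction_unpredictability(0.7, 2, 2000, 50, 7)
  expect_gt(swb$mean, 0.97)
  # below the bifurcation there is nothing to measure
  expect_error(switch_fraction_unpredictability(0.5, 0.5, 1e3, 10, 1),
               "bifurcation")
})
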