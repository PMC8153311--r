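#' Regularized inference loss on the simplex
#'
#' The objective every observer minimizes at each flip:
#' \deqn{L(Q) = D_{KL}(Q \| B) + \lambda\, C[Q],}
#' where B is the one-step Bayesian posterior and C is either the precision
#' cost (negative entropy of Q) or the unpredictability cost (expected
#' outcome entropy under Q).
#'
#' @param Q Candidate belief, a [grid_distribution()].
#' @param B Bayesian target, a [grid_distribution()] on the same grid.
#' @param cost `"precision"` or `"unpredictability"`.
#' @param lambda Non-negative cost weight.
#' @return The loss in nats.
#' @export
inference_loss <- function(Q, B, cost = c("precision", "unpredictability"),
                           lambda = 0) {
  cost <- match.arg(cost)
  lambda <- check_lambda(lambda)
  kl_divergence(Q, B) + lambda *
    switch(cost, precision = precision_cost(Q),
           unpredictability = unpredictability_cost(Q))
}

# Euclidean norm of the loss gradient projected onto the simplex tangent
# (gradient minus its Q-weighted mean): the first-order optimality measure.
simplex_grad <- function(q, b, cost, lambda, hK, logK) {
  g <- log(q) - log(b) +
    if (cost == "precision") lambda * (log(q) + logK) else lambda * hK
  g - sum(q * g)
}

#' Numerical minimizer of the regularized inference loss
#'
#' Minimizes [inference_loss()] over the probability simplex by
#' exponentiated-gradient (mirror-descent) iterations
#' \eqn{q \leftarrow q e^{-\eta \nabla L} / Z}, which preserve positivity and
#' normalization. The objective is convex in Q for both costs, so the
#' iteration converges to the interior optimum; it serves as a blind check
#' that the closed-form posteriors really are the loss minimizers.
#'
#' @param B Bayesian target, a strictly positive [grid_distribution()].
#' @param cost `"precision"` or `"unpredictability"`.
#' @param lambda Non-negative cost weight.
#' @param step Initial step size, on the curvature scale of the objective:
#'   the step actually taken starts at `step / (1 + lambda)` and is
#'   backtracked on loss increase.
#' @param tol Convergence threshold on the max projected-gradient component.
#' @param max_iter Iteration cap.
#' @param trace Record the loss after every iteration (attribute
#'   `loss_trace`).
#' @return The minimizing `grid_distribution`, with attributes `iterations`
#'   and `grad_norm` (and `loss_trace` if requested).
#' @export
minimize_loss <- function(B, cost = c("precision", "unpredictability"),
                          lambda = 0, step = 1, tol = 1e-10,
                          max_iter = 1e5, trace = FALSE) {
  cost <- match.arg(cost)
  lambda <- check_lambda(lambda)
  stopifnot(inherits(B, "grid_distribution"))
  b <- B$masses
  if (any(b <= 0))
    stop("the Bayesian target must be strictly positive on the grid", call. = FALSE)
  K <- B$K
  logK <- log(K)
  hK <- bernoulli_entropy(B$centers)
  q <- rep(1 / K, K)
  loss_q <- inference_loss(grid_distribution(q), B, cost, lambda)
  loss_trace <- if (trace) loss_q
  it <- 0L
  repeat {
    g <- simplex_grad(q, b, cost, lambda, hK, logK)
    gn <- max(abs(g))
    if (gn < tol || it >= max_iter) break
    # KL term curvature is 1/q, the precision cost adds lambda/q: a step of
    # order 1/(1 + lambda) is the natural unit for both costs
    eta <- step / (1 + lambda)
    accepted <- FALSE
    repeat {
      w <- q * exp(-eta * g)
      q_new <- w / sum(w)
      loss_new <- inference_loss(grid_distribution(q_new), B, cost, lambda)
      # accept descent up to floating-point noise in the loss
      if (loss_new <= loss_q + 1e-13 * max(1, abs(loss_q))) {
        accepted <- TRUE
        break
      }
      eta <- eta / 2
      if (eta < 1e-12) break
    }
    if (!accepted) break  # at the numerical floor; gradient is as small as it gets
    q <- q_new
    loss_q <- loss_new
    if (trace) loss_trace <- c(loss_trace, loss_q)
    it <- it + 1L
  }
  if (it >= max_iter && gn >= tol)
    warning(sprintf("minimizer hit the iteration cap (grad norm %.3g)", gn))
  out <- grid_distribution(q, B$centers)
  attr(out, "iterations") <- it
  attr(out, "grad_norm") <- gn
  if (trace) attr(out, "loss_trace") <- loss_trace
  out
}

# Closed-form minimizer used as the reference in tests and oracle reports:
# Q propto B^(1/(1+lambda)) for the precision cost, Q propto B e^(-lambda H)
# for the unpredictability cost.
closed_form_minimizer <- function(B, cost, lambda) {
  lb <- log(B$masses)
  lv <- switch(cost,
    precision = lb / (1 + lambda),
    unpredictability = lb - lambda * bernoulli_entropy(B$centers)
  )
  grid_distribution(exp(lv - max(lv)) / sum(exp(lv - max(lv))), B$centers)
}

# Total variation distance between two grid distributions.
total_variation <- function(Q, P) 0.5 * sum(abs(Q$masses - P$masses))

#' Sequential costly inference on the grid
#'
#' Runs the full online procedure numerically: starting from the uniform
#' prior, each flip forms the one-step Bayesian target (previous inferred
#' belief times the Bernoulli likelihood, normalized) and replaces it by the
#' loss minimizer. With `minimizer = "numerical"` every step calls
#' [minimize_loss()]; with `"closed_form"` the known solution is applied
#' directly. The sequential target is what makes the closed forms emerge:
#' iterating it yields exponentially filtered counts (precision) and the
#' N-th-power profile (unpredictability). `target = "full_data"` instead
#' tempers the full-history Bayesian posterior at each step — a deliberately
#' wrong reading kept to demonstrate that it does not reproduce the
#' filtered-count recursion.
#'
#' @param seq A [coin_sequence()].
#' @param lambda Non-negative cost weight.
#' @param cost `"precision"` or `"unpredictability"`.
#' @param K Grid resolution.
#' @param minimizer `"numerical"` or `"closed_form"`.
#' @param target `"sequential"` (the model) or `"full_data"` (demonstration).
#' @return A list of [grid_distribution()] beliefs, one per flip.
#' @export
sequential_inference <- function(seq, lambda,
                                 cost = c("precision", "unpredictability"),
                                 K = 501, minimizer = c("numerical", "closed_form"),
                                 target = c("sequential", "full_data")) {
  stopifnot(inherits(seq, "coin_sequence"))
  cost <- match.arg(cost)
  minimizer <- match.arg(minimizer)
  target <- match.arg(target)
  lambda <- check_lambda(lambda)
  centers <- (seq_len(K) - 0.5) / K
  loglik1 <- log(centers)
  loglik0 <- log1p(-centers)
  out <- vector("list", seq$N)
  prev <- make_grid(K)
  bayes_full <- make_grid(K)  # full-history Bayesian posterior (for target = "full_data")
  for (i in seq_len(seq$N)) {
    ll <- if (seq$outcomes[i] == 1L) loglik1 else loglik0
    if (target == "sequential") {
      B <- grid_from_log(log(prev$masses) + ll)
    } else {
      bayes_full <- grid_from_log(log(bayes_full$masses) + ll)
      B <- bayes_full
    }
    prev <- if (minimizer == "numerical") minimize_loss(B, cost, lambda)
            else closed_form_minimizer(B, cost, lambda)
    out[[i]] <- prev
  }
  out
}

#' Per-step oracle comparison of numerical and closed-form observers
#'
#' Runs [sequential_inference()] with the numerical minimizer on a sequence
#' and reports, per flip, the total-variation distance to the closed-form
#' belief (the filtered-count Beta density for the precision cost, the
#' N-th-power profile for the unpredictability cost).
#'
#' @inheritParams sequential_inference
#' @return A data frame with columns `flip`, `tv` (total variation to the
#'   closed form).
#' @export
oracle_check <- function(seq, lambda, cost = c("precision", "unpredictability"),
                         K = 501) {
  stopifnot(inherits(seq, "coin_sequence"))
  cost <- match.arg(cost)
  lambda <- check_lambda(lambda)
  numeric_run <- sequential_inference(seq, lambda, cost, K, minimizer = "numerical")
  tv <- vapply(seq_len(seq$N), function(i) {
    n_i <- sum(seq$outcomes[seq_len(i)])
    ref <- if (cost == "precision") {
      post <- filtered_counts(coin_sequence(seq$outcomes[seq_len(i)]), lambda)
      precision_posterior_grid(post, K)
    } else {
      unpredictability_posterior(n_i, i, lambda, K)
    }
    total_variation(numeric_run[[i]], ref)
  }, numeric(1))
  data.frame(flip = seq_len(seq$N), tv = tv)
}
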