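#' Belief states
#'
#' A belief state is the posterior probability vector over the `k` candidate
#' target locations. `belief_state()` validates (and lightly sanitizes) a
#' numeric vector into one.
#'
#' @param p Numeric vector of `k` probabilities summing to 1 (tolerance 1e-9;
#'   the result is renormalized to machine precision).
#' @return A plain numeric vector summing to 1.
#' @export
belief_state <- function(p) {
  if (!is.numeric(p) || length(p) < 2L || any(!is.finite(p)))
    stop("belief must be a finite numeric vector of length >= 2")
  if (any(p < -1e-12)) stop("belief entries must be non-negative")
  p <- pmax(p, 0)
  s <- sum(p)
  if (abs(s - 1) > 1e-9) stop("belief entries must sum to 1")
  p / s
}

#' Bayesian belief update
#'
#' Posterior over target location after observing `x` while fixating `j`:
#' `p'_i` is proportional to `f_{i,j}(x) p_i`, renormalized.
#'
#' @inheritParams likelihood
#' @param p Belief state (prior).
#' @return Updated belief state.
#' @examples
#' m <- observation_model(3, 0.9)
#' bayes_update(rep(1/3, 3), x = 1, j = 1, m)  # (9/11, 1/11, 1/11)
#' @export
bayes_update <- function(p, x, j, model) {
  p <- belief_state(p)
  lik <- vapply(seq_along(p), function(i) likelihood(i, j, x, model),
                numeric(1))
  w <- lik * p
  s <- sum(w)
  if (s <= 0) stop("degenerate update: observation has zero predictive probability")
  w / s
}

#' Predictive distribution of the next observation
#'
#' Marginal probability of each observation outcome under belief `p` when
#' fixating `j`: `P(x) = sum_i p_i f_{i,j}(x)`.
#'
#' @inheritParams bayes_update
#' @return Named numeric vector over the outcome alphabet (names `"0"`,`"1"`
#'   for the foveal model; outcome indices for the peripheral model). Sums
#'   to 1.
#' @export
predictive <- function(p, j, model) {
  p <- belief_state(p)
  out <- vapply(seq_len(model$n_out), function(o) {
    x <- if (model$n_out == 2L) o - 1L else o
    sum(p * vapply(seq_along(p), function(i) likelihood(i, j, x, model),
                   numeric(1)))
  }, numeric(1))
  names(out) <- if (model$n_out == 2L) c("0", "1") else seq_len(model$n_out)
  out
}

#' Shannon entropy of a belief state (nats)
#'
#' `H(p) = -sum_i p_i log p_i`, with `0 log 0 = 0`.
#'
#' @param p Belief state.
#' @return Non-negative entropy in nats.
#' @export
entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Row-wise entropy of a matrix of beliefs.
row_entropy <- function(P) {
  Z <- P * log(P)
  Z[P <= 0] <- 0
  -rowSums(Z)
}
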