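#' Foveal observation model
#'
#' Binary Bernoulli observation model for a visual-search task with `k`
#' candidate target locations. Fixating a location yields a binary observation
#' whose distribution depends on whether the fixated location holds the
#' target: the outcome favoured by the target (`x = 1`) occurs with
#' probability `beta` when the target is fixated and `1 - beta` otherwise.
#'
#' @param k Number of candidate target locations (>= 2).
#' @param beta Reliability of a fixated observation, in (0.5, 1].
#'
#' @return An object of class `c("foveal_model", "observation_model")` with
#'   fields `k` (locations), `n_fix` (fixation locations, equal to `k`),
#'   `n_out` (observation alphabet size, 2) and `beta`.
#' @examples
#' m <- observation_model(k = 3, beta = 0.9)
#' likelihood(1, 1, 1, m)  # 0.9
#' @export
observation_model <- function(k, beta) {
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k))
    stop("`k` must be a single integer >= 2")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0.5 || beta > 1)
    stop("`beta` must lie in (0.5, 1]")
  structure(
    list(k = as.integer(k), n_fix = as.integer(k), n_out = 2L,
         beta = beta, kind = "foveal"),
    class = c("foveal_model", "observation_model"))
}

#' Peripheral-vision observation model
#'
#' Three-location task in which the observer may also fixate intermediate
#' locations. The fixation set has 7 elements: the three stimulus locations
#' (l1, l2, l3), the three midpoints between pairs (l12, l23, l13) and the
#' centre (l123). Each observation is a 3-vector of independent binary
#' components, one per stimulus location, with reliability determined by the
#' fixation--location geometry: a directly fixated stimulus is read at tier
#' `beta1`, the two stimuli adjacent to a fixated midpoint at `beta2`, all
#' three stimuli from the centre at `beta3`, and any remaining far stimulus at
#' `beta4`. Component m favours outcome 1 when location m holds the target
#' (success probability = tier) and 0 otherwise (success probability =
#' 1 - tier).
#'
#' @param betas Numeric vector `(beta1, beta2, beta3, beta4)` with
#'   `1 > beta1 > beta2 > beta3 > beta4 >= 0.5`.
#'
#' @return An object of class `c("peripheral_model", "observation_model")`
#'   with `k = 3` locations, `n_fix = 7` fixation locations and an observation
#'   alphabet of the 8 binary 3-vectors (`n_out = 8`). Field `tier` is the
#'   7 x 3 matrix of per-component reliabilities; `outcomes` the 8 x 3 matrix
#'   of binary observation vectors (row o is outcome index o); `fix_labels`
#'   the fixation names.
#' @examples
#' m <- peripheral_model(c(0.62, 0.6, 0.55, 0.5))
#' m$tier["l123", ]  # all three components read at beta3
#' @export
peripheral_model <- function(betas) {
  if (length(betas) != 4L || any(!is.finite(betas)))
    stop("`betas` must be 4 finite probabilities (beta1..beta4)")
  if (!(1 > betas[1] && betas[1] > betas[2] && betas[2] > betas[3] &&
        betas[3] > betas[4] && betas[4] >= 0.5))
    stop("require 1 > beta1 > beta2 > beta3 > beta4 >= 0.5")
  fix_labels <- c("l1", "l2", "l3", "l12", "l23", "l13", "l123")
  tier <- rbind(
    c(1, 4, 4),  # l1: direct + two far
    c(4, 1, 4),  # l2
    c(4, 4, 1),  # l3
    c(2, 2, 4),  # l12: two adjacent + far
    c(4, 2, 2),  # l23
    c(2, 4, 2),  # l13
    c(3, 3, 3))  # l123: centre
  tier <- matrix(betas[tier], nrow = 7L,
                 dimnames = list(fix_labels, paste0("loc", 1:3)))
  outcomes <- as.matrix(expand.grid(x1 = 0:1, x2 = 0:1, x3 = 0:1))
  structure(
    list(k = 3L, n_fix = 7L, n_out = 8L, betas = betas, tier = tier,
         outcomes = outcomes, fix_labels = fix_labels, kind = "peripheral"),
    class = c("peripheral_model", "observation_model"))
}

#' @export
print.observation_model <- function(x, ...) {
  if (x$kind == "foveal") {
    cat(sprintf("Foveal observation model: k = %d locations, beta = %g\n",
                x$k, x$beta))
  } else {
    cat(sprintf(
      "Peripheral observation model: k = %d locations, %d fixations (%s)\n",
      x$k, x$n_fix, paste(x$fix_labels, collapse = ", ")))
    cat(sprintf("  tiers beta1..beta4 = %s\n",
                paste(format(x$betas), collapse = ", ")))
  }
  invisible(x)
}

#' Observation likelihood
#'
#' Probability `f_{i,j}(x)` of observation `x` when the target is at location
#' `i` and the observer fixates location `j`. For the foveal model `x` is a
#' scalar in {0, 1} and the likelihood is `beta^x (1-beta)^(1-x)` if `i = j`
#' and `(1-beta)^x beta^(1-x)` otherwise. For the peripheral model `x` is a
#' binary 3-vector (or an outcome index 1..8) and the likelihood is the
#' product of the three component Bernoullis at their geometry-mapped tiers.
#'
#' @param i Target location index.
#' @param j Fixation index (1..`model$n_fix`).
#' @param x Observation: scalar 0/1 (foveal) or binary 3-vector (peripheral).
#' @param model An [observation_model()] or [peripheral_model()].
#' @return A probability.
#' @export
likelihood <- function(i, j, x, model) {
  stopifnot(inherits(model, "observation_model"))
  if (i < 1 || i > model$k || i != round(i)) stop("invalid location index `i`")
  if (j < 1 || j > model$n_fix || j != round(j)) stop("invalid fixation `j`")
  if (inherits(model, "foveal_model")) {
    if (length(x) != 1L || !(x %in% c(0, 1))) stop("`x` must be 0 or 1")
    b <- model$beta
    if (i == j) b^x * (1 - b)^(1 - x) else (1 - b)^x * b^(1 - x)
  } else {
    if (length(x) == 1L) x <- model$outcomes[x, ]
    if (length(x) != 3L || !all(x %in% c(0, 1)))
      stop("`x` must be a binary 3-vector or an outcome index")
    q <- ifelse(seq_len(3) == i, model$tier[j, ], 1 - model$tier[j, ])
    prod(q^x * (1 - q)^(1 - x))
  }
}

# Likelihood tables: list over fixations j of k x n_out matrices L[[j]][i, o]
# with rows summing to 1. Internal workhorse used by solvers and simulator.
likelihood_tables <- function(model) {
  k <- model$k
  lapply(seq_len(model$n_fix), function(j) {
    L <- matrix(NA_real_, k, model$n_out)
    for (i in seq_len(k)) for (o in seq_len(model$n_out))
      L[i, o] <- likelihood(i, j, if (model$n_out == 2L) o - 1L else o, model)
    L
  })
}
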