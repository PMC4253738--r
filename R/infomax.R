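#' Solve the Infomax policy on the belief grid
#'
#' Infomax chooses fixations to minimize the expected cumulative future
#' entropy of the posterior belief. On the discretized simplex the value
#' satisfies
#' `V_I(p) = min_j sum_x P(x | p, j) [H(p') + V_I(p')]`
#' with `p'` the Bayes posterior, and `V_I(p) = 0` wherever
#' `max_i p_i >= stop_threshold` (thresholded beliefs are absorbing: the
#' policy stops and declares the maximum-probability location). Infomax has
#' no intrinsic stopping rule; the default threshold is the closed-form
#' stopping bound [theorem1_threshold()], which makes the stopping region a
#' provable subset of the C-DAC one at `cs = 0`.
#'
#' The value and policy are independent of the current fixation location by
#' construction (the action table has identical columns).
#'
#' @param model Observation model.
#' @param grid [belief_grid()].
#' @param stop_threshold Stopping threshold in (0.5, 1).
#' @param horizon `"converged"` (iterate the absorbing recursion to a fixed
#'   point) or a positive integer number of backward-induction steps (for
#'   sensitivity checks).
#' @param tol Sup-norm convergence tolerance for `"converged"`.
#' @param max_iter Sweep cap for `"converged"`.
#' @param backup Optional precomputed backup operator (internal reuse).
#' @return An object of class `c("infomax_policy", "grid_policy",
#'   "sensing_policy")` with `V` (entropy-to-absorption, npoints x n_fix,
#'   identical columns), `action`, `Q` (per-fixation action values),
#'   `stop_threshold`, `iterations`.
#' @export
solve_infomax <- function(model, grid, stop_threshold,
                          horizon = "converged", tol = 1e-6, max_iter = 2000,
                          backup = NULL) {
  stopifnot(inherits(grid, "belief_grid"), grid$k == model$k)
  if (!is.numeric(stop_threshold) || stop_threshold <= 0.5 || stop_threshold >= 1)
    stop("`stop_threshold` must lie in (0.5, 1)")
  bk <- if (is.null(backup)) build_backup(model, grid) else backup
  F_ <- model$n_fix
  maxp <- apply(grid$points, 1L, max)
  absorbing <- maxp >= stop_threshold
  # expected one-step posterior entropy, per candidate fixation
  EH <- vapply(seq_len(F_), function(j)
    rowSums(bk$pred[[j]] * bk$Hpost[[j]]), numeric(grid$npoints))
  v <- numeric(grid$npoints)
  it <- 0L
  n_steps <- if (identical(horizon, "converged")) max_iter else as.integer(horizon)
  repeat {
    it <- it + 1L
    Q <- vapply(seq_len(F_), function(j) EH[, j] + backup_ev(bk, j, v),
                numeric(grid$npoints))
    vnew <- do.call(pmin, lapply(seq_len(F_), function(j) Q[, j]))
    vnew[absorbing] <- 0
    res <- max(abs(vnew - v))
    v <- vnew
    if (identical(horizon, "converged")) {
      if (res < tol) break
      if (it >= max_iter)
        stop(sprintf("Infomax recursion did not converge in %d sweeps (residual %.3g)",
                     max_iter, res))
    } else if (it >= n_steps) break
  }
  Q <- vapply(seq_len(F_), function(j) EH[, j] + backup_ev(bk, j, v),
              numeric(grid$npoints))
  fix_choice <- max.col(-Q, ties.method = "first")        # lowest index on ties
  declare <- max.col(grid$points, ties.method = "first") - 1L
  act <- ifelse(absorbing, declare, model$k + fix_choice - 1L)
  structure(
    list(V = matrix(v, grid$npoints, F_), action = matrix(act, grid$npoints, F_),
         Q = Q, model = model, grid = grid, stop_threshold = stop_threshold,
         horizon = horizon, iterations = it, family = "infomax",
         declare_rule = "any", costs = NULL),
    class = c("infomax_policy", "grid_policy", "sensing_policy"))
}
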