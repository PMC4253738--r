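#' Behavioural cost parameters
#'
#' The C-DAC behavioural cost of a search that takes `tau` observations,
#' makes `n_s` fixation switches and declares location `delta` when the
#' target is at `s` is `c * tau + cs * n_s + 1{delta != s}`; the unit error
#' cost is a normalization.
#'
#' @param c Cost per unit time (per observation step), > 0.
#' @param cs Cost per fixation switch, >= 0.
#' @return An object of class `cost_params`.
#' @export
cost_params <- function(c, cs = 0) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0) stop("`c` must be > 0")
  if (!is.numeric(cs) || length(cs) != 1L || cs < 0) stop("`cs` must be >= 0")
  structure(list(c = c, cs = cs), class = "cost_params")
}

#' @export
print.cost_params <- function(x, ...) {
  cat(sprintf("Behavioural costs: c = %g per step, cs = %g per switch, error cost 1\n",
              x$c, x$cs))
  invisible(x)
}

#' Expected cost of stopping and declaring a location
#'
#' In the stationary (incremental) formulation, declaring location `i` under
#' belief `p` costs the error probability `1 - p_i` (time and switch costs
#' already sunk are dropped).
#'
#' @param p Belief state.
#' @param i Location index.
#' @return `1 - p[i]`.
#' @export
stop_cost <- function(p, i) {
  p <- belief_state(p)
  if (i < 1 || i > length(p) || i != round(i)) stop("invalid location index")
  1 - p[i]
}

#' One-step continuation value
#'
#' Expected cost of taking one more observation at fixation `j` (from current
#' fixation `current`) and then following the value function `V`:
#' `c + cs * 1{j != current} + E[V(p', j)]`, the expectation running over the
#' observation outcomes with `p'` the Bayes posterior, evaluated on the grid
#' by barycentric interpolation.
#'
#' @param p Belief state.
#' @param current Current fixation index.
#' @param j Candidate fixation index.
#' @param V Value table: `npoints x n_fix` matrix (column per fixation), or a
#'   solved policy object carrying one in `$V`.
#' @param costs [cost_params()].
#' @param model Observation model.
#' @param grid [belief_grid()].
#' @return Expected continuation cost (scalar).
#' @export
continuation_value <- function(p, current, j, V, costs, model, grid) {
  if (is.list(V) && !is.null(V$V)) V <- V$V
  if (is.null(dim(V))) V <- matrix(V, ncol = 1L)
  p <- belief_state(p)
  pr <- predictive(p, j, model)
  ev <- 0
  for (o in seq_len(model$n_out)) {
    if (pr[o] <= 0) next
    x <- if (model$n_out == 2L) o - 1L else o
    ev <- ev + pr[o] * interpolate(V[, min(j, ncol(V))],
                                   bayes_update(p, x, j, model), grid)
  }
  unname(costs$c + costs$cs * (j != current) + ev)
}

# Stop-value table: npoints x n_fix. declare_rule "any" allows declaring any
# location (min_i 1 - p_i, fixation-independent); "current" only the fixated
# location (foveal models only).
stop_value_table <- function(model, grid, declare_rule) {
  P <- grid$points
  if (declare_rule == "any") {
    sv <- 1 - apply(P, 1L, max)
    matrix(sv, grid$npoints, model$n_fix)
  } else {
    if (model$n_fix != model$k)
      stop("declare_rule = \"current\" requires fixations to coincide with locations")
    1 - P
  }
}

#' Solve the C-DAC control problem by value iteration
#'
#' Computes the optimal stationary policy for the cost-sensitive active
#' sensing problem: at each step the observer either stops and declares a
#' location (cost `1 - p_i`) or takes one more observation at some fixation
#' (cost `c`, plus `cs` if it differs from the current fixation, plus the
#' expected optimal cost from the posterior). Value iteration runs on the
#' discretized belief simplex, initialized at the stopping cost, sweeping
#' until the sup-norm change falls below `tol`.
#'
#' @param model Observation model ([observation_model()] or
#'   [peripheral_model()]).
#' @param costs [cost_params()].
#' @param grid [belief_grid()] over `model$k` locations.
#' @param tol Sup-norm convergence tolerance (default 1e-6).
#' @param declare_rule `"any"` (declare any location; the literal Bellman
#'   recursion) or `"current"` (only the fixated location may be declared,
#'   emulating the human task in which the response selects the last viewed
#'   patch). Peripheral models always use `"any"`.
#' @param max_iter Maximum number of sweeps (default 500).
#' @param backup Optional precomputed backup operator (internal reuse).
#' @return An object of class `c("cdac_policy", "sensing_policy")` with
#'   fields `V` (npoints x n_fix value table), `action` (npoints x n_fix
#'   integer action codes: `0..k-1` = declare location, `k..k+n_fix-1` =
#'   fixate), `iterations`, `residual`, plus the environment objects.
#' @examples
#' m <- observation_model(3, 0.9)
#' g <- belief_grid(3, 30)
#' pol <- solve_cdac(m, cost_params(0.1, 0.1), g)
#' predict(pol, p = c(0.9, 0.05, 0.05), fixation = 1)
#' @export
solve_cdac <- function(model, costs, grid, tol = 1e-6,
                       declare_rule = c("any", "current"), max_iter = 500,
                       backup = NULL) {
  declare_rule <- match.arg(declare_rule)
  if (inherits(model, "peripheral_model")) declare_rule <- "any"
  stopifnot(inherits(costs, "cost_params"), inherits(grid, "belief_grid"),
            grid$k == model$k, tol > 0)
  bk <- if (is.null(backup)) build_backup(model, grid) else backup
  F_ <- model$n_fix
  sv <- stop_value_table(model, grid, declare_rule)
  V <- sv
  it <- 0L; res <- Inf
  repeat {
    it <- it + 1L
    EV <- vapply(seq_len(F_), function(j) backup_ev(bk, j, V[, j]),
                 numeric(grid$npoints))
    Vnew <- V
    for (cur in seq_len(F_)) {
      cont <- costs$c + EV[, cur]
      for (j in seq_len(F_)) if (j != cur)
        cont <- pmin(cont, costs$c + costs$cs + EV[, j])
      Vnew[, cur] <- pmin(sv[, cur], cont)
    }
    res <- max(abs(Vnew - V))
    V <- Vnew
    if (res < tol) break
    if (it >= max_iter)
      stop(sprintf("value iteration did not converge in %d sweeps (residual %.3g)",
                   max_iter, res))
  }
  EV <- vapply(seq_len(F_), function(j) backup_ev(bk, j, V[, j]),
               numeric(grid$npoints))
  action <- extract_policy(model, costs, grid, EV, declare_rule)
  structure(
    list(V = V, action = action, model = model, costs = costs, grid = grid,
         declare_rule = declare_rule, tol = tol, iterations = it,
         residual = res, family = "cdac"),
    class = c("cdac_policy", "grid_policy", "sensing_policy"))
}

# Greedy policy extraction with the documented deterministic tie-break:
# declare beats fixate; among declares, lowest location index; among
# fixations, the current location first, then lowest index. Candidate
# columns are laid out in exactly that priority order, and max.col(...,
# "first") picks the first minimum.
extract_policy <- function(model, costs, grid, EV, declare_rule) {
  F_ <- model$n_fix; k <- model$k; P <- grid$points
  action <- matrix(0L, grid$npoints, F_)
  for (cur in seq_len(F_)) {
    if (declare_rule == "any") {
      dec_vals <- 1 - P
      dec_codes <- 0:(k - 1L)
    } else {
      dec_vals <- 1 - P[, cur, drop = FALSE]
      dec_codes <- cur - 1L
    }
    fix_order <- c(cur, setdiff(seq_len(F_), cur))
    fix_vals <- vapply(fix_order, function(j)
      costs$c + costs$cs * (j != cur) + EV[, j], numeric(grid$npoints))
    vals <- cbind(dec_vals, fix_vals)
    codes <- c(dec_codes, k + fix_order - 1L)
    best <- max.col(-vals, ties.method = "first")
    action[, cur] <- codes[best]
  }
  action
}

#' Closed-form stopping-threshold bound
#'
#' For the binary foveal task, stopping and declaring location `i` is
#' provably optimal whenever `p_i` exceeds the larger root `p*` in (0, 1) of
#' `p (2 beta - 1) (1 - p) = c (beta p + (1 - beta)(1 - p))`, i.e. of the
#' quadratic `(2b-1) p^2 - (2b-1)(1-c) p + c (1-b) = 0`. The bound is an
#' inner bound of the optimal stopping region and is also used as the default
#' stopping threshold for the Infomax comparator.
#'
#' @param beta Observation reliability in (0.5, 1).
#' @param c Cost per unit time, > 0.
#' @return The threshold `p*` in (0, 1).
#' @examples
#' theorem1_threshold(0.9, 0.1)    # ~0.8859
#' theorem1_threshold(0.68, 0.005) # ~0.9905
#' @export
theorem1_threshold <- function(beta, c) {
  if (beta <= 0.5 || beta >= 1) stop("`beta` must lie in (0.5, 1)")
  if (c <= 0) stop("`c` must be > 0")
  a <- 2 * beta - 1
  b <- -a * (1 - c)
  cc <- c * (1 - beta)
  disc <- b^2 - 4 * a * cc
  if (disc < 0)
    stop("threshold saturation: no real root (stopping optimal everywhere)")
  p <- (-b + sqrt(disc)) / (2 * a)
  if (p <= 0 || p >= 1)
    stop("threshold saturation: no root in (0, 1)")
  p
}

#' Stopping region of a solved policy
#'
#' Grid points at which the policy's action, at the given fixation, is to
#' stop and declare a location.
#'
#' @param policy A solved grid policy (e.g. from [solve_cdac()]).
#' @param fixation Fixation index.
#' @return Integer vector of grid-point indices.
#' @export
stopping_region <- function(policy, fixation) {
  stopifnot(inherits(policy, "grid_policy"))
  which(policy$action[, fixation] < policy$model$k)
}

#' Stay region of a solved policy
#'
#' Grid points at which the policy, at the given fixation, continues
#' observing at the currently fixated location.
#'
#' @inheritParams stopping_region
#' @return Integer vector of grid-point indices.
#' @export
stay_region <- function(policy, fixation) {
  stopifnot(inherits(policy, "grid_policy"))
  which(policy$action[, fixation] == policy$model$k + fixation - 1L)
}
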