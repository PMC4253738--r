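#' Myopic one-step approximation of C-DAC
#'
#' Evaluates the one-step-lookahead value
#' `V(p, k) = min( stop, min_j ( c + cs 1{j != k} + min_l (1 - E[p'_l]) ) )`
#' literally, with the expected posterior computed by summing over the
#' observation outcomes (by the belief martingale this expectation equals the
#' current belief, so continuing at the current location is never chosen: it
#' costs `c` for zero expected improvement in stopping cost). Under
#' `declare_rule = "current"` the post-continuation declaration `l` is
#' restricted to the location just fixated, which reproduces the asymmetric
#' switching boundaries of the full solver in attenuated form; under `"any"`
#' the policy stops everywhere (the literal formula is dominated by immediate
#' stopping).
#'
#' @param p Belief state.
#' @param current Current fixation index.
#' @param model Observation model.
#' @param costs [cost_params()].
#' @param declare_rule `"any"` or `"current"`.
#' @return The chosen action: list with `type` (`"declare"`/`"fixate"`),
#'   `index`, and the integer `code` (`0..k-1` declare, `k..` fixate).
#' @export
myopic_action <- function(p, current, model, costs,
                          declare_rule = c("any", "current")) {
  declare_rule <- match.arg(declare_rule)
  if (declare_rule == "current" && model$n_fix != model$k)
    stop("declare_rule = \"current\" requires fixations to coincide with locations")
  p <- belief_state(p)
  k <- model$k; F_ <- model$n_fix
  if (declare_rule == "any") {
    dec_vals <- 1 - p
    dec_codes <- 0:(k - 1L)
  } else {
    dec_vals <- 1 - p[current]
    dec_codes <- current - 1L
  }
  fix_order <- c(current, setdiff(seq_len(F_), current))
  fix_vals <- vapply(fix_order, function(j) {
    pr <- predictive(p, j, model)
    ep <- numeric(k)
    for (o in seq_len(model$n_out)) {
      if (pr[o] <= 0) next
      x <- if (model$n_out == 2L) o - 1L else o
      ep <- ep + pr[o] * bayes_update(p, x, j, model)
    }
    allowed <- if (declare_rule == "current") j else seq_len(k)
    costs$c + costs$cs * (j != current) + min(1 - ep[allowed])
  }, numeric(1))
  vals <- c(dec_vals, fix_vals)
  codes <- c(dec_codes, k + fix_order - 1L)
  best <- which.min(vals)                 # first minimum = documented tie-break
  decode_action(codes[best], k)
}

#' Myopic policy object
#'
#' Wraps [myopic_action()] as a `sensing_policy` usable with the simulator
#' and analysis layer.
#'
#' @inheritParams myopic_action
#' @return Object of class `c("myopic_policy", "sensing_policy")`.
#' @export
myopic_policy <- function(model, costs, declare_rule = c("any", "current")) {
  declare_rule <- match.arg(declare_rule)
  structure(list(model = model, costs = costs, declare_rule = declare_rule,
                 family = "myopic"),
            class = c("myopic_policy", "sensing_policy"))
}

#' Myopic stopping region on a grid
#'
#' Grid points where [myopic_action()] stops, at the given fixation
#' (vectorized literal evaluation of the one-step values).
#'
#' @param model Observation model.
#' @param costs [cost_params()].
#' @param grid [belief_grid()].
#' @param fixation Current fixation index.
#' @param declare_rule `"any"` or `"current"`.
#' @return Integer vector of grid-point indices.
#' @export
myopic_region <- function(model, costs, grid, fixation,
                          declare_rule = c("any", "current")) {
  declare_rule <- match.arg(declare_rule)
  P <- grid$points; k <- model$k
  L <- likelihood_tables(model)
  stopv <- if (declare_rule == "any") 1 - apply(P, 1L, max) else 1 - P[, fixation]
  cont <- rep(Inf, grid$npoints)
  for (j in seq_len(model$n_fix)) {
    EP <- matrix(0, grid$npoints, k)       # E[p' | fixate j], outcome-summed
    for (o in seq_len(model$n_out)) {
      U <- P %*% diag(L[[j]][, o], nrow = k)
      EP <- EP + U                          # pred * posterior = unnormalized U
    }
    allowed <- if (declare_rule == "current") j else seq_len(k)
    best_dec <- do.call(pmin, lapply(allowed, function(l) 1 - EP[, l]))
    cont <- pmin(cont, costs$c + costs$cs * (j != fixation) + best_dec)
  }
  which(stopv <= cont)
}

# Vectorized myopic action codes over a grid (same tie-break as
# myopic_action); used for region/boundary comparisons.
myopic_action_map <- function(model, costs, grid, fixation,
                              declare_rule = c("any", "current")) {
  declare_rule <- match.arg(declare_rule)
  P <- grid$points; k <- model$k
  L <- likelihood_tables(model)
  if (declare_rule == "any") {
    dec_vals <- 1 - P
    dec_codes <- 0:(k - 1L)
  } else {
    dec_vals <- 1 - P[, fixation, drop = FALSE]
    dec_codes <- fixation - 1L
  }
  fix_order <- c(fixation, setdiff(seq_len(model$n_fix), fixation))
  fix_vals <- vapply(fix_order, function(j) {
    EP <- matrix(0, grid$npoints, k)
    for (o in seq_len(model$n_out))
      EP <- EP + P %*% diag(L[[j]][, o], nrow = k)
    allowed <- if (declare_rule == "current") j else seq_len(k)
    best_dec <- do.call(pmin, lapply(allowed, function(l) 1 - EP[, l]))
    costs$c + costs$cs * (j != fixation) + best_dec
  }, numeric(grid$npoints))
  vals <- cbind(dec_vals, fix_vals)
  codes <- c(dec_codes, k + fix_order - 1L)
  codes[max.col(-vals, ties.method = "first")]
}

#' Uniform-random baseline policy
#'
#' Fixates uniformly at random until the maximum belief exceeds a threshold,
#' then stops and declares the maximum-probability location. Serves as a
#' floor baseline.
#'
#' @param model Observation model.
#' @param threshold Stopping threshold on the maximum belief, in (0.5, 1].
#' @param costs Optional [cost_params()] carried along for simulation
#'   summaries.
#' @return Object of class `c("random_policy", "sensing_policy")`.
#' @export
random_policy <- function(model, threshold, costs = NULL) {
  if (threshold <= 0.5 || threshold > 1) stop("`threshold` must lie in (0.5, 1]")
  structure(list(model = model, threshold = threshold, costs = costs,
                 family = "random"),
            class = c("random_policy", "sensing_policy"))
}

#' Calibrate a policy's stopping threshold to a target accuracy
#'
#' Bisection on the stopping threshold until the simulated accuracy of the
#' policy built by `policy_builder(threshold)` matches `target_accuracy`
#' within `tol` (used, e.g., to match Infomax's accuracy to C-DAC's for fair
#' behavioural comparison). Each evaluation simulates `n_trials` trials with
#' the same master seed, so the accuracy curve is a deterministic
#' (approximately monotone increasing) function of the threshold.
#'
#' @param policy_builder Function taking a threshold and returning a
#'   `sensing_policy`.
#' @param sim_args Named list of arguments to [run_experiment()] other than
#'   `policy` and `seed` (must include `model`, `costs`, `target_distribution`).
#' @param target_accuracy Target accuracy in (0, 1).
#' @param tol Acceptable accuracy mismatch (default 0.01).
#' @param bracket Threshold search interval (default `c(0.55, 0.995)`).
#' @param n_trials Trials per evaluation (default 2000).
#' @param seed Master seed for every evaluation.
#' @param max_iter Bisection iteration cap.
#' @return List with `threshold`, `accuracy`, and the evaluation trace.
#' @export
calibrate_threshold <- function(policy_builder, sim_args, target_accuracy,
                                tol = 0.01, bracket = c(0.55, 0.995),
                                n_trials = 2000, seed = 1, max_iter = 20) {
  eval_acc <- function(th) {
    pol <- policy_builder(th)
    trials <- do.call(run_experiment,
                      c(list(policy = pol, n_trials = n_trials, seed = seed),
                        sim_args))
    mean(trials$correct)
  }
  lo <- bracket[1]; hi <- bracket[2]
  acc_lo <- eval_acc(lo); acc_hi <- eval_acc(hi)
  trace <- data.frame(threshold = c(lo, hi), accuracy = c(acc_lo, acc_hi))
  if (target_accuracy < acc_lo - tol || target_accuracy > acc_hi + tol)
    stop(sprintf(
      "calibration bracket failure: accuracy range [%.3f, %.3f] does not cover target %.3f",
      acc_lo, acc_hi, target_accuracy))
  th <- (lo + hi) / 2; acc <- NA_real_
  for (i in seq_len(max_iter)) {
    th <- (lo + hi) / 2
    acc <- eval_acc(th)
    trace <- rbind(trace, data.frame(threshold = th, accuracy = acc))
    if (abs(acc - target_accuracy) <= tol) break
    if (acc < target_accuracy) lo <- th else hi <- th
  }
  list(threshold = th, accuracy = acc, trace = trace)
}
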