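# Decode an integer action code: 0..k-1 = declare location code+1,
# k..k+n_fix-1 = fixate location code-k+1.
decode_action <- function(code, k) {
  code <- as.integer(code)
  if (code < k) list(type = "declare", index = code + 1L, code = code)
  else list(type = "fixate", index = code - k + 1L, code = code)
}

#' Action prescribed by a policy at a belief state
#'
#' Dispatches on the policy family: grid policies look up the action at the
#' nearest grid point (actions are categorical, so no interpolation); the
#' myopic policy evaluates its closed-form one-step values; the random
#' baseline draws from the current RNG stream.
#'
#' @param policy A `sensing_policy`.
#' @param p Belief state.
#' @param current Current fixation index.
#' @return List with `type` (`"declare"` or `"fixate"`), `index`, `code`.
#' @export
policy_action <- function(policy, p, current) UseMethod("policy_action")

#' @export
policy_action.grid_policy <- function(policy, p, current) {
  idx <- nearest_grid_point(policy$grid, p)
  decode_action(policy$action[idx, current], policy$model$k)
}

#' @export
policy_action.myopic_policy <- function(policy, p, current) {
  myopic_action(p, current, policy$model, policy$costs, policy$declare_rule)
}

#' @export
policy_action.random_policy <- function(policy, p, current) {
  k <- policy$model$k
  if (max(p) >= policy$threshold)
    decode_action(which.max(p) - 1L, k)
  else
    decode_action(k + sample.int(policy$model$n_fix, 1L) - 1L, k)
}

#' @export
predict.sensing_policy <- function(object, p, fixation = 1L, ...) {
  policy_action(object, p, fixation)
}

#' @export
print.sensing_policy <- function(x, ...) {
  cat(sprintf("<%s policy>\n", x$family))
  if (!is.null(x$model)) print(x$model)
  if (!is.null(x$costs)) print(x$costs)
  if (!is.null(x$grid)) print(x$grid)
  if (!is.null(x$iterations))
    cat(sprintf("  solved in %d sweeps\n", x$iterations))
  if (!is.null(x$declare_rule))
    cat(sprintf("  declare rule: %s\n", x$declare_rule))
  if (!is.null(x$stop_threshold))
    cat(sprintf("  stop threshold: %.6g\n", x$stop_threshold))
  invisible(x)
}

#' @export
summary.grid_policy <- function(object, ...) {
  k <- object$model$k
  tab <- apply(object$action, 2L, function(a) {
    c(stop = mean(a < k), stay = NA, switch = NA)
  })
  for (cur in seq_len(ncol(object$action))) {
    a <- object$action[, cur]
    tab["stay", cur] <- mean(a == k + cur - 1L)
    tab["switch", cur] <- mean(a >= k & a != k + cur - 1L)
  }
  colnames(tab) <- paste0("fix", seq_len(ncol(tab)))
  cat(sprintf("<%s policy> action fractions over %d grid points:\n",
              object$family, object$grid$npoints))
  print(round(tab, 4))
  invisible(tab)
}

#' Plot a three-location policy map
#'
#' Renders the action prescribed at every grid point, at a given fixation,
#' on the belief triangle (affine transform of `(p1, p2, p3)` for visual
#' symmetry). Blue: stop and declare; green/orange/brown: fixate location
#' 1/2/3 (additional fixations of peripheral models get further colours).
#'
#' @param x A solved grid policy.
#' @param fixation Fixation index whose action map to draw.
#' @param cex Point size.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.grid_policy <- function(x, fixation = 1L, cex = 0.4, ...) {
  if (x$model$k != 3L) stop("policy plotting is implemented for k = 3")
  P <- x$grid$points
  xx <- P[, 2] + 0.5 * P[, 3]
  yy <- sqrt(3) / 2 * P[, 3]
  a <- x$action[, fixation]
  k <- x$model$k
  pal <- c("steelblue3",                                  # declare (any loc)
           c("forestgreen", "darkorange2", "tan4",
             "orchid4", "turquoise4", "goldenrod3", "firebrick")[
               seq_len(x$model$n_fix)])
  col <- rep(pal[1], length(a))
  fixate <- a >= k
  col[fixate] <- pal[1 + (a[fixate] - k + 1)]
  graphics::plot(xx, yy, col = col, pch = 15, cex = cex, asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%s policy, fixating %d", x$family, fixation),
                 ...)
  graphics::polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  invisible(x)
}

#' Simulate search trials from a policy
#'
#' Convenience wrapper around [run_experiment()] drawing environment objects
#' from the policy itself.
#'
#' @param object A `sensing_policy` carrying `model` (and `costs`).
#' @param nsim Number of trials.
#' @param seed Master seed.
#' @param target_distribution Distribution of the true target location
#'   (default uniform).
#' @param prior Prior belief at trial start (default `target_distribution`).
#' @param ... Passed on to [run_experiment()].
#' @return A trial-log data frame; see [run_experiment()].
#' @export
simulate.sensing_policy <- function(object, nsim = 1, seed = NULL,
                                    target_distribution = NULL, prior = NULL,
                                    ...) {
  k <- object$model$k
  if (is.null(target_distribution)) target_distribution <- rep(1 / k, k)
  if (is.null(prior)) prior <- target_distribution
  costs <- object$costs
  if (is.null(costs)) costs <- cost_params(1e-9, 0)
  run_experiment(object, model = object$model, costs = costs,
                 n_trials = nsim, target_distribution = target_distribution,
                 prior = prior, seed = seed, ...)
}
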