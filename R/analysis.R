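#' Summary statistics of a trial log
#'
#' Accuracy, mean number of observation steps, mean number of fixation
#' switches and mean realized behavioural cost, with standard errors. The
#' cost decomposition `mean_cost = c * mean_steps + cs * mean_switches +
#' (1 - accuracy)` is enforced as an invariant.
#'
#' @param trials A `trial_log` (see [run_experiment()]).
#' @param costs [cost_params()]; defaults to the log's `"costs"` attribute.
#' @return Object of class `summary_stats` (a one-row data frame).
#' @export
summarize <- function(trials, costs = attr(trials, "costs")) {
  if (is.null(trials) || nrow(trials) == 0L) stop("empty trial log")
  if (is.null(costs)) stop("cost parameters required")
  n <- nrow(trials)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  out <- data.frame(
    condition = trials$condition[1],
    n_trials = n,
    accuracy = mean(trials$correct),
    mean_steps = mean(trials$steps),
    mean_switches = mean(trials$switches),
    mean_cost = mean(trials$behavioral_cost),
    se_accuracy = se(as.numeric(trials$correct)),
    se_steps = se(trials$steps),
    se_switches = se(trials$switches),
    se_cost = se(trials$behavioral_cost),
    stringsAsFactors = FALSE)
  recomposed <- costs$c * out$mean_steps + costs$cs * out$mean_switches +
    (1 - out$accuracy)
  if (abs(recomposed - out$mean_cost) > 1e-8)
    stop("cost decomposition invariant violated")
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "%d trials%s: accuracy %.3f (se %.3f), steps %.2f (se %.2f), switches %.2f (se %.2f), cost %.4f (se %.4f)\n",
    x$n_trials,
    if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
    x$accuracy, x$se_accuracy, x$mean_steps, x$se_steps,
    x$mean_switches, x$se_switches, x$mean_cost, x$se_cost))
  invisible(x)
}

#' Confirmation-bias table
#'
#' Conditions trials on the first-fixated location and contrasts the most
#' probable ("9") location class against the pooled less probable ("1 and
#' 3") locations, mirroring the behavioural analysis of biased-prior visual
#' search: hit rate (declared the first-fixated location when it held the
#' target), false-alarm rate (declared it when it did not), and mean first
#' -fixation duration (consecutive steps at the first fixation before the
#' first switch or stop) separately for target-present and distractor trials,
#' the duration columns restricted to correct trials. The two less probable
#' locations are pooled because few trials start there.
#'
#' @param trials A `trial_log`.
#' @param labeled Index of the most probable ("9") location.
#' @param min_n Cells with fewer trials than this are flagged `NA`.
#' @return Data frame of class `confirmation_bias_table` with one row per
#'   class (`"9"`, `"1 and 3"`): `n`, `hit_rate`, `fa_rate`,
#'   `dur_target`, `dur_distractor` (durations in model steps).
#' @export
confirmation_bias_table <- function(trials, labeled, min_n = 5L) {
  if (nrow(trials) == 0L) stop("empty trial log")
  first <- trials$initial_fixation
  cls <- ifelse(first == labeled, "9", "1 and 3")
  cell <- function(v, n_ok) if (n_ok >= min_n) v else NA_real_
  rows <- lapply(c("9", "1 and 3"), function(cl) {
    tr <- trials[cls == cl, , drop = FALSE]
    on_target <- tr$true_target == tr$initial_fixation
    hit_n <- sum(on_target)
    fa_n <- sum(!on_target)
    hit <- cell(mean(tr$declared[on_target] == tr$initial_fixation[on_target],
                     na.rm = TRUE), hit_n)
    fa <- cell(mean(tr$declared[!on_target] == tr$initial_fixation[!on_target],
                    na.rm = TRUE), fa_n)
    cor_t <- tr$correct & on_target
    cor_d <- tr$correct & !on_target
    dur_t <- cell(mean(tr$first_duration[cor_t]), sum(cor_t))
    dur_d <- cell(mean(tr$first_duration[cor_d]), sum(cor_d))
    data.frame(class = cl, n = nrow(tr), hit_rate = hit, fa_rate = fa,
               dur_target = dur_t, dur_distractor = dur_d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("confirmation_bias_table", "data.frame")
  out
}

#' Compare policies across environments with paired seeds
#'
#' Simulates every supplied policy/environment pair with the same master
#' seed (hence identical per-trial targets and observation noise streams
#' wherever the fixation sequences coincide) and tabulates summary
#' statistics.
#'
#' @param policy_sets Named list; each element a list with components
#'   `policy`, `model`, `costs`, and optionally `prior`,
#'   `target_distribution`, `initial_fixation`, `condition`.
#' @param n_trials Trials per cell.
#' @param seed Master seed shared by all cells.
#' @param max_steps Per-trial step cap.
#' @return Data frame with one `summary_stats` row per cell, labelled by the
#'   list names.
#' @export
compare_policies <- function(policy_sets, n_trials, seed = 1, max_steps = 1e4) {
  stopifnot(length(names(policy_sets)) == length(policy_sets))
  rows <- lapply(names(policy_sets), function(nm) {
    ps <- policy_sets[[nm]]
    k <- ps$model$k
    td <- if (is.null(ps$target_distribution)) rep(1 / k, k) else ps$target_distribution
    pr <- if (is.null(ps$prior)) td else ps$prior
    init <- if (is.null(ps$initial_fixation)) "policy" else ps$initial_fixation
    log <- run_experiment(ps$policy, ps$model, ps$costs, n_trials,
                          target_distribution = td, prior = pr,
                          initial_fixation = init, seed = seed,
                          max_steps = max_steps,
                          condition = if (is.null(ps$condition)) nm else ps$condition)
    st <- summarize(log, ps$costs)
    cbind(data.frame(cell = nm, stringsAsFactors = FALSE), st)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("policy_comparison", "data.frame")
  out
}
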