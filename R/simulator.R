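#' Sample an observation
#'
#' Draws one observation from the model given the true target location and
#' the current fixation, using the current RNG stream. Foveal: a single
#' Bernoulli draw with success probability `beta` if the target is fixated
#' and `1 - beta` otherwise. Peripheral: three independent Bernoulli
#' components at their geometry-mapped reliability tiers, favouring 1 at the
#' target and 0 at distractors.
#'
#' @param s True target location.
#' @param fixation Current fixation index.
#' @param model Observation model.
#' @return Scalar 0/1 (foveal) or binary 3-vector (peripheral).
#' @export
sample_observation <- function(s, fixation, model) {
  if (inherits(model, "foveal_model")) {
    pr <- if (fixation == s) model$beta else 1 - model$beta
    stats::rbinom(1L, 1L, pr)
  } else {
    q <- ifelse(seq_len(3) == s, model$tier[fixation, ], 1 - model$tier[fixation, ])
    stats::rbinom(3L, 1L, q)
  }
}

# Outcome index of an observation (1-based column of the likelihood tables).
obs_index <- function(x, model) {
  if (model$n_out == 2L) x + 1L else 1L + x[1] + 2L * x[2] + 4L * x[3]
}

#' Simulate one search trial
#'
#' Rolls out a policy in the task environment: starting from the prior and
#' an initial fixation, repeatedly samples an observation at the current
#' fixation, updates the belief by Bayes' rule, and consults the policy
#' (grid policies act at the nearest grid point). A fixation action extends
#' or switches the fixation; a declare action terminates the trial. The
#' policy is consulted only after at least one observation. Uses the current
#' RNG stream; seed externally for reproducibility.
#'
#' @param policy A `sensing_policy`.
#' @param model Observation model (must match the policy's environment).
#' @param costs [cost_params()] used for the realized behavioural cost.
#' @param prior Prior belief over target location.
#' @param true_target True target location index.
#' @param initial_fixation Starting fixation; `NULL` picks
#'   `argmin_i V(prior, i)` for value-based grid policies (lowest index on
#'   ties) and fixation 1 otherwise.
#' @param max_steps Safeguard cap on observations; reaching it truncates the
#'   trial, which counts as an error declaration.
#' @return A `trial_record`: list with `true_target`, `prior`, `fixations`
#'   (per-step), `observations`, `declared`, `correct`, `steps`, `switches`,
#'   `behavioral_cost`, `truncated`.
#' @export
simulate_trial <- function(policy, model, costs, prior, true_target,
                           initial_fixation = NULL, max_steps = 1e4) {
  prior <- belief_state(prior)
  ltab <- likelihood_tables(model)
  if (is.null(initial_fixation)) {
    if (!is.null(policy$V) && !is.null(policy$grid)) {
      idx <- nearest_grid_point(policy$grid, prior)
      initial_fixation <- which.min(policy$V[idx, ])
    } else initial_fixation <- 1L
  }
  fix <- as.integer(initial_fixation)
  p <- prior
  fixations <- integer(0)
  observations <- vector("list", 0L)
  declared <- NA_integer_; truncated <- FALSE
  steps <- 0L
  repeat {
    x <- sample_observation(true_target, fix, model)
    steps <- steps + 1L
    fixations[steps] <- fix
    observations[[steps]] <- x
    w <- p * ltab[[fix]][, obs_index(x, model)]
    p <- w / sum(w)
    act <- policy_action(policy, p, fix)
    if (act$type == "declare") { declared <- act$index; break }
    fix <- act$index
    if (steps >= max_steps) { truncated <- TRUE; break }
  }
  switches <- if (steps > 1L) sum(diff(fixations) != 0L) else 0L
  correct <- !truncated && !is.na(declared) && declared == true_target
  cost <- costs$c * steps + costs$cs * switches + as.numeric(!correct)
  rec <- structure(
    list(true_target = as.integer(true_target), prior = prior,
         fixations = fixations, observations = observations,
         declared = declared, correct = isTRUE(correct), steps = steps,
         switches = switches, behavioral_cost = cost, truncated = truncated,
         final_belief = p),
    class = "trial_record")
  validate_trial_record(rec, costs)
  rec
}

# Invariants every trial record must satisfy.
validate_trial_record <- function(rec, costs) {
  stopifnot(
    rec$steps == length(rec$observations),
    rec$steps == length(rec$fixations),
    rec$switches == if (rec$steps > 1L) sum(diff(rec$fixations) != 0L) else 0L,
    abs(rec$behavioral_cost -
          (costs$c * rec$steps + costs$cs * rec$switches +
             as.numeric(!rec$correct))) < 1e-12)
  invisible(rec)
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "Trial: target %d, declared %s (%s), %d steps, %d switches, cost %.4g%s\n",
    x$true_target, ifelse(is.na(x$declared), "none", x$declared),
    ifelse(x$correct, "correct", "error"), x$steps, x$switches,
    x$behavioral_cost, if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

# Run-length encode a fixation sequence as "fix x count" segments.
rle_fixations <- function(fx) {
  r <- rle(fx)
  paste(sprintf("%dx%d", r$values, r$lengths), collapse = ",")
}

#' Run a block of simulated search trials
#'
#' Draws i.i.d. true target locations from `target_distribution`, derives a
#' per-trial seed stream from the master seed (trial results are independent
#' of execution order), simulates each trial, and returns a trial log with
#' one row per trial.
#'
#' @inheritParams simulate_trial
#' @param n_trials Number of trials.
#' @param target_distribution Distribution of the true target location.
#' @param prior Prior belief handed to the policy each trial (defaults to
#'   `target_distribution`).
#' @param initial_fixation `"policy"` (value-based choice), `"uniform"`
#'   (uniform over the `k` stimulus-location fixations; used to populate
#'   first-fixation-conditioned analyses), or a fixed fixation index.
#' @param seed Master seed (integer) for target draws and per-trial streams.
#' @param condition Optional condition label stored in the log.
#' @return Data frame of class `trial_log`, one row per trial, with columns
#'   `trial_id`, `condition`, `true_target`, `initial_fixation`,
#'   `first_duration`, `steps`, `switches`, `declared`, `correct`,
#'   `behavioral_cost`, `truncated`, `fixation_sequence` (run-length
#'   encoded), `seed`. The cost parameters are attached as attribute
#'   `"costs"`.
#' @export
run_experiment <- function(policy, model, costs, n_trials, target_distribution,
                           prior = NULL, initial_fixation = "policy",
                           seed = NULL, max_steps = 1e4, condition = NA_character_) {
  target_distribution <- belief_state(target_distribution)
  if (is.null(prior)) prior <- target_distribution
  if (!is.null(seed)) set.seed(seed)
  if (n_trials == 0L) {
    out <- empty_trial_log()
    attr(out, "costs") <- costs
    return(out)
  }
  targets <- sample.int(model$k, n_trials, replace = TRUE,
                        prob = target_distribution)
  init <- if (identical(initial_fixation, "uniform")) {
    sample.int(model$k, n_trials, replace = TRUE)
  } else if (identical(initial_fixation, "policy")) {
    rep(NA_integer_, n_trials)
  } else rep(as.integer(initial_fixation), n_trials)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  rows <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    set.seed(trial_seeds[t])
    rec <- simulate_trial(policy, model, costs, prior, targets[t],
                          initial_fixation = if (is.na(init[t])) NULL else init[t],
                          max_steps = max_steps)
    first_dur <- rle(rec$fixations)$lengths[1]
    rows[[t]] <- data.frame(
      trial_id = t, condition = condition, true_target = rec$true_target,
      initial_fixation = rec$fixations[1], first_duration = first_dur,
      steps = rec$steps, switches = rec$switches,
      declared = ifelse(is.na(rec$declared), NA_integer_, rec$declared),
      correct = rec$correct, behavioral_cost = rec$behavioral_cost,
      truncated = rec$truncated,
      fixation_sequence = rle_fixations(rec$fixations),
      seed = trial_seeds[t], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("trial_log", "data.frame")
  attr(out, "costs") <- costs
  out
}

empty_trial_log <- function() {
  out <- data.frame(
    trial_id = integer(0), condition = character(0), true_target = integer(0),
    initial_fixation = integer(0), first_duration = integer(0),
    steps = integer(0), switches = integer(0), declared = integer(0),
    correct = logical(0), behavioral_cost = numeric(0), truncated = logical(0),
    fixation_sequence = character(0), seed = integer(0),
    stringsAsFactors = FALSE)
  class(out) <- c("trial_log", "data.frame")
  out
}

#' Point score of an experimental trial
#'
#' The task's incentive scheme: `100 - 12.5 * seconds - 25 * switches`, plus
#' 50 points for a correct response or minus 50 for an incorrect one.
#'
#' @param seconds Response time in seconds (>= 0).
#' @param switches Number of fixation switches.
#' @param correct Logical; was the response correct?
#' @return Points earned (vectorized).
#' @examples
#' score_trial(2, 1, TRUE)   # 100
#' score_trial(0, 0, TRUE)   # 150
#' @export
score_trial <- function(seconds, switches, correct) {
  if (any(seconds < 0)) stop("`seconds` must be >= 0")
  100 - 12.5 * seconds - 25 * switches + ifelse(correct, 50, -50)
}

#' Write / read a trial log as CSV
#'
#' @param trials A `trial_log` data frame.
#' @param path File path.
#' @return `read_trials()` returns the trial log (costs must be re-supplied
#'   to [summarize()] explicitly).
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("trial_log", "data.frame")
  out
}
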