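make_log <- function(n = 50, seed = 17, cs = 0.1, beta = 0.68,
                     prior = c(9, 3, 1) / 13, init = "uniform",
                     rule = "current", n_grid = 60) {
  m <- fov(beta)
  g <- belief_grid(3, n_grid)
  co <- cost_params(0.005, cs)
  pol <- cached(paste0("an_", beta, "_", cs, "_", rule, "_", n_grid),
                solve_cdac(m, co, g, declare_rule = rule))
  run_experiment(pol, m, co, n, prior, initial_fixation = init, seed = seed)
}

test_that("summarize computes means, standard errors and the cost identity", {
  tr <- make_log(300)
  st <- summarize(tr)
  expect_equal(st$n_trials, 300)
  expect_true(st$accuracy >= 0 && st$accuracy <= 1)
  expect_equal(st$mean_cost,
               0.005 * st$mean_steps + 0.1 * st$mean_switches +
                 (1 - st$accuracy))
  # order invariance
  st2 <- summarize(tr[sample(nrow(tr)), ], attr(tr, "costs"))
  expect_equal(st$mean_cost, st2$mean_cost)
  expect_equal(st$accuracy, st2$accuracy)
  expect_error(summarize(tr[0, ], attr(tr, "costs")), "empty")
  # single correct 1-step trial
  one <- tr[1, ]; one$steps <- 1L; one$switches <- 0L; one$correct <- TRUE
  one$behavioral_cost <- 0.005
  s1 <- summarize(one, cost_params(0.005, 0.1))
  expect_equal(s1$accuracy, 1)
  expect_equal(s1$mean_cost, 0.005)
})

test_that("confirmation-bias table is clean for noiseless search", {
  m <- observation_model(3, 1)
  g <- belief_grid(3, 40)
  co <- cost_params(0.05, 0.1)
  pol <- solve_cdac(m, co, g, declare_rule = "current")
  tr <- run_experiment(pol, m, co, 400, c(9, 3, 1) / 13,
                       initial_fixation = "uniform", seed = 23)
  cb <- confirmation_bias_table(tr, labeled = 1)
  expect_equal(cb$hit_rate, c(1, 1))
  expect_equal(cb$fa_rate, c(0, 0))
  expect_equal(sum(cb$n), 400)
})

test_that("sparse cells are flagged rather than fabricated", {
  tr <- make_log(40)
  tr_small <- tr[tr$initial_fixation == 1, ][1:3, ]
  cb <- confirmation_bias_table(tr_small, labeled = 1, min_n = 5)
  expect_true(is.na(cb$hit_rate[cb$class == "1 and 3"]) ||
                cb$n[cb$class == "1 and 3"] == 0)
})

test_that("switch cost reduces C-DAC switching (paired seeds)", {
  t0 <- make_log(n = 1500, cs = 0, seed = 29, prior = rep(1 / 3, 3),
                 init = "policy")
  t1 <- make_log(n = 1500, cs = 0.1, seed = 29, prior = rep(1 / 3, 3),
                 init = "policy")
  d <- mean(t0$switches) - mean(t1$switches)
  se <- sqrt(var(t0$switches) / nrow(t0) + var(t1$switches) / nrow(t1))
  expect_gt(d, 3 * se)
})

test_that("compare_policies pairs seeds across cells", {
  m <- fov(0.8)
  g <- belief_grid(3, 40)
  co <- cost_params(0.02, 0.05)
  pol <- solve_cdac(m, co, g)
  sets <- list(a = list(policy = pol, model = m, costs = co),
               b = list(policy = pol, model = m, costs = co))
  cmp <- compare_policies(sets, n_trials = 200, seed = 3)
  expect_equal(nrow(cmp), 2)
  # identical policies under paired seeds give identical statistics
  expect_equal(cmp$mean_cost[1], cmp$mean_cost[2])
  expect_equal(cmp$accuracy[1], cmp$accuracy[2])
})

test_that("policy export round-trips bit-exactly and drives the simulator", {
  pol <- cdac60(0.1)
  csv <- tempfile(fileext = ".csv")
  write_policy(pol, csv)
  back <- read_policy(csv)
  expect_identical(back$action, pol$action)
  expect_identical(back$V, pol$V)
  expect_equal(back$model$beta, 0.9)
  expect_equal(back$costs$cs, 0.1)
  a <- run_experiment(pol, pol$model, pol$costs, 30, rep(1 / 3, 3), seed = 6)
  b <- run_experiment(back, back$model, back$costs, 30, rep(1 / 3, 3), seed = 6)
  expect_identical(a$fixation_sequence, b$fixation_sequence)
  expect_identical(a$behavioral_cost, b$behavioral_cost)
})

test_that("trial logs round-trip through CSV", {
  tr <- make_log(25)
  path <- tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$behavioral_cost, tr$behavioral_cost)
  expect_equal(back$fixation_sequence, tr$fixation_sequence)
})

test_that("the command-line interface wires the pieces together", {
  # threshold subcommand prints the closed-form bound
  out <- capture.output(status <- cdac_cli(c("threshold", "--beta", "0.9",
                                             "--c", "0.1")))
  expect_equal(status, 0L)
  expect_equal(as.numeric(out), 0.8858899, tolerance = 1e-6)
  # malformed invocations exit nonzero
  expect_gt(suppressMessages(cdac_cli(c("frobnicate"))), 0L)
  expect_gt(suppressMessages(cdac_cli(c("solve", "--config", "missing.yaml"))),
            0L)
  expect_gt(suppressMessages(cdac_cli(c("threshold", "--beta"))), 0L)
  # solve -> simulate -> analyze round trip on a coarse grid
  dir <- tempfile(); dir.create(dir)
  cfg <- file.path(dir, "env.yaml")
  writeLines(c("k: 3", "beta: 0.8", "c: 0.02", "cs: 0.05", "grid_n: 30",
               "n_trials: 50", "seed: 5"), cfg)
  pol_csv <- file.path(dir, "policy.csv")
  expect_equal(suppressMessages(
    cdac_cli(c("solve", "--config", cfg, "--family", "cdac",
               "--out", pol_csv))), 0L)
  expect_true(file.exists(pol_csv))
  expect_true(file.exists(file.path(dir, "policy.json")))
  trials_csv <- file.path(dir, "trials.csv")
  expect_equal(suppressMessages(
    cdac_cli(c("simulate", "--policy", pol_csv, "--config", cfg,
               "--out", trials_csv))), 0L)
  expect_true(file.exists(trials_csv))
  summ <- file.path(dir, "summary.json")
  expect_equal(suppressMessages(
    cdac_cli(c("analyze", "--trials", trials_csv, "--config", cfg,
               "--out", summ))), 0L)
  st <- jsonlite::read_json(summ)
  expect_true(st$accuracy >= 0 && st$accuracy <= 1)
  unlink(dir, recursive = TRUE)
})
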