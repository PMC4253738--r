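test_that("sample_observation matches its Bernoulli parameters", {
  m1 <- observation_model(3, 1)
  set.seed(1)
  expect_true(all(replicate(20, sample_observation(2, 2, m1)) == 1))
  expect_true(all(replicate(20, sample_observation(2, 1, m1)) == 0))
  m <- fov(0.9)
  set.seed(2)
  draws <- replicate(1e5, sample_observation(1, 1, m))
  se <- sqrt(0.9 * 0.1 / 1e5)
  expect_lt(abs(mean(draws) - 0.9), 3 * se)
})

test_that("peripheral tier map follows the fixation geometry", {
  pm <- peripheral_model(c(0.62, 0.6, 0.55, 0.5))
  expect_equal(unname(pm$tier["l1", ]), c(0.62, 0.5, 0.5))
  expect_equal(unname(pm$tier["l12", ]), c(0.6, 0.6, 0.5))
  expect_equal(unname(pm$tier["l123", ]), rep(0.55, 3))
  expect_equal(unname(pm$tier["l13", ]), c(0.6, 0.5, 0.6))
  # center fixation: every component Bernoulli(beta3) for the target and
  # Bernoulli(1 - beta3) for distractors; x = 0 contributes one minus that
  x <- c(1, 0, 1)
  expect_equal(likelihood(1, 7, x, pm), 0.55 * 0.55 * 0.45)
  expect_equal(likelihood(2, 7, x, pm), 0.45 * 0.45 * 0.45)
  expect_equal(likelihood(3, 7, x, pm), 0.45 * 0.55 * 0.55)
  # direct fixation of l1: component 1 at beta1, the far ones at beta4 = 0.5
  expect_equal(likelihood(1, 1, c(1, 1, 0), pm), 0.62 * 0.5 * 0.5)
  expect_equal(likelihood(2, 1, c(0, 1, 0), pm), 0.62 * 0.5 * 0.5)
  expect_error(peripheral_model(c(0.6, 0.62, 0.55, 0.5)), "beta1")
})

test_that("noiseless search declares the target in one step", {
  m <- observation_model(3, 1)
  g <- belief_grid(3, 40)
  pol <- solve_cdac(m, cost_params(0.05, 0.1), g, declare_rule = "current")
  set.seed(3)
  rec <- simulate_trial(pol, m, cost_params(0.05, 0.1), rep(1 / 3, 3),
                        true_target = 2, initial_fixation = 2)
  expect_equal(rec$steps, 1L)
  expect_true(rec$correct)
  expect_equal(rec$switches, 0L)
  expect_equal(rec$behavioral_cost, 0.05)
})

test_that("accuracy is exactly 1 with noiseless observations", {
  m <- observation_model(3, 1)
  g <- belief_grid(3, 40)
  co <- cost_params(0.05, 0.1)
  for (rule in c("any", "current")) {
    pol <- solve_cdac(m, co, g, declare_rule = rule)
    tr <- run_experiment(pol, m, co, 200, rep(1 / 3, 3), seed = 8)
    expect_equal(mean(tr$correct), 1)
  }
})

test_that("trials replay deterministically from their seed", {
  m <- fov(0.8)
  g <- belief_grid(3, 40)
  co <- cost_params(0.02, 0.05)
  pol <- solve_cdac(m, co, g)
  set.seed(11)
  a <- simulate_trial(pol, m, co, rep(1 / 3, 3), 1, 1)
  set.seed(11)
  b <- simulate_trial(pol, m, co, rep(1 / 3, 3), 1, 1)
  expect_identical(a$fixations, b$fixations)
  expect_identical(a$observations, b$observations)
  expect_identical(a$declared, b$declared)
  # different master seeds give different logs
  t1 <- run_experiment(pol, m, co, 20, rep(1 / 3, 3), seed = 1)
  t2 <- run_experiment(pol, m, co, 20, rep(1 / 3, 3), seed = 2)
  expect_false(identical(t1$fixation_sequence, t2$fixation_sequence))
})

test_that("trial records satisfy the behavioural-cost decomposition", {
  m <- fov(0.7)
  g <- belief_grid(3, 40)
  co <- cost_params(0.01, 0.03)
  pol <- solve_cdac(m, co, g, declare_rule = "current")
  tr <- run_experiment(pol, m, co, 100, c(9, 3, 1) / 13, seed = 21,
                       initial_fixation = "uniform")
  expect_equal(tr$behavioral_cost,
               co$c * tr$steps + co$cs * tr$switches + as.numeric(!tr$correct))
  # declare-current: the declared location is the final fixation
  last_fix <- as.integer(sub(".*?(\\d+)x\\d+$", "\\1", tr$fixation_sequence))
  expect_equal(tr$declared, last_fix)
})

test_that("experiment-level draws respect the target distribution", {
  m <- fov(0.9)
  g <- belief_grid(3, 40)
  co <- cost_params(0.1, 0)
  pol <- solve_cdac(m, co, g)
  expect_equal(nrow(run_experiment(pol, m, co, 0, rep(1 / 3, 3), seed = 1)), 0)
  td <- c(1, 3, 9) / 13
  tr <- run_experiment(pol, m, co, 4000, td, seed = 31)
  freq <- tabulate(tr$true_target, 3) / 4000
  se <- sqrt(td * (1 - td) / 4000)
  expect_true(all(abs(freq - td) < 3 * se))
})

test_that("a solved policy beats the random baseline on realized cost", {
  m <- fov(0.68)
  g <- belief_grid(3, 60)
  co <- cost_params(0.005, 0.1)
  pol <- solve_cdac(m, co, g, declare_rule = "current")
  rnd <- random_policy(m, theorem1_threshold(0.68, 0.005), co)
  prior <- c(9, 3, 1) / 13
  tc <- run_experiment(pol, m, co, 1500, prior, seed = 13)
  tr <- run_experiment(rnd, m, co, 1500, prior, seed = 13)
  expect_lte(mean(tc$behavioral_cost), mean(tr$behavioral_cost))
})

test_that("step cap truncates pathological searches as errors", {
  # near-uninformative observations and negligible time cost never reach the
  # stopping threshold
  m <- observation_model(3, 0.5 + 1e-12)
  rp <- random_policy(m, threshold = 0.99, costs = cost_params(1e-6, 0))
  set.seed(5)
  rec <- simulate_trial(rp, m, cost_params(1e-6, 0), rep(1 / 3, 3), 1, 1,
                        max_steps = 50)
  expect_true(rec$truncated)
  expect_false(rec$correct)
  expect_equal(rec$steps, 50L)
})

test_that("score_trial implements the point schedule", {
  expect_equal(score_trial(2, 1, TRUE), 100)
  expect_equal(score_trial(0, 0, TRUE), 150)
  expect_equal(score_trial(8, 0, FALSE), -50)
  expect_equal(score_trial(c(2, 0), c(1, 0), c(TRUE, TRUE)), c(100, 150))
  expect_error(score_trial(-1, 0, TRUE), ">= 0")
})
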