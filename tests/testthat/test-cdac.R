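test_that("stop_cost is the declaration error probability", {
  expect_equal(stop_cost(c(1, 0, 0), 1), 0)
  expect_equal(stop_cost(rep(1 / 3, 3), 2), 2 / 3)
  expect_equal(stop_cost(c(9, 3, 1) / 13, 1), 4 / 13)
})

test_that("continuation_value composes cost, switch cost and expected next value", {
  m <- fov(0.9)
  g <- grid60()
  co <- cost_params(0.1, 0)
  # stop-cost value field; belief absorbing at the corner, V = 0 there
  V <- matrix(1 - apply(g$points, 1, max), g$npoints, 3)
  expect_equal(continuation_value(c(1, 0, 0), 1, 1, V, co, m, g), 0.1)
  # two-location case by hand: posteriors (0.9,0.1)/(0.1,0.9) each w.p. 0.5
  m2 <- observation_model(2, 0.9)
  g2 <- belief_grid(2, 200)
  V2 <- matrix(1 - apply(g2$points, 1, max), g2$npoints, 2)
  expect_equal(continuation_value(c(0.5, 0.5), 1, 1, V2, co, m2, g2), 0.2)
  # near-uninformative observations leave the belief (and value) in place
  mu <- observation_model(3, 0.5 + 1e-9)
  got <- continuation_value(c(0.5, 0.3, 0.2), 1, 2, V, cost_params(0.1, 0.05),
                            mu, g)
  expect_equal(got, 0.1 + 0.05 + 0.5, tolerance = 1e-6)
})

test_that("theorem1_threshold solves the stopping-bound quadratic", {
  for (case in list(c(0.9, 0.1), c(0.68, 0.005), c(0.75, 0.02))) {
    b <- case[1]; cc <- case[2]
    p <- theorem1_threshold(b, cc)
    # substitution into the threshold equation
    expect_lt(abs(p * (2 * b - 1) * (1 - p) -
                    cc * (b * p + (1 - b) * (1 - p))), 1e-10)
  }
  expect_equal(theorem1_threshold(0.9, 0.1), 0.8859, tolerance = 1e-4)
  expect_equal(theorem1_threshold(0.68, 0.005), 0.9905, tolerance = 1e-4)
  # zero sampling-cost limit: threshold approaches 1
  expect_gt(theorem1_threshold(0.9, 1e-9), 1 - 1e-6)
  expect_error(theorem1_threshold(0.9, 10), "saturation")
})

decode_action_test <- function(code, k) {
  if (code < k) list(type = "declare", index = code + 1L)
  else list(type = "fixate", index = code - k + 1L)
}

test_that("value iteration yields zero cost and declaration at corners", {
  pol <- cdac60(0.1)
  g <- grid60()
  for (i in 1:3) {
    corner <- which(g$points[, i] == 1)
    expect_equal(pol$V[corner, ], rep(0, 3))
    expect_equal(decode_action_test(pol$action[corner, 1], 3),
                 list(type = "declare", index = i))
  }
})

test_that("value function is Bellman-consistent and fixation-independent without switch cost", {
  g <- grid60()
  pol0 <- cached("cdac60_cs0", solve_cdac(fov(), cost_params(0.1, 0), g))
  # never worse than immediate best declaration, never negative
  sv <- 1 - apply(g$points, 1, max)
  expect_true(all(pol0$V <= sv + 1e-12))
  expect_true(all(pol0$V >= -1e-12))
  # cs = 0: value independent of the current fixation
  expect_lt(max(abs(pol0$V - pol0$V[, 1])), 1e-6)
})

test_that("k = 2 grid solution matches an exact finite-horizon recursion", {
  m2 <- observation_model(2, 0.9)
  co <- cost_params(0.1, 0)
  g2 <- belief_grid(2, 200)
  pol <- solve_cdac(m2, co, g2)
  # independent oracle: exact recursion on real-valued beliefs, no grid.
  # horizon 6 suffices: continuation costs 0.1/step and stopping costs <= 0.5
  oracle <- function(p, cur, h) {
    best <- 1 - max(p)
    if (h == 0) return(best)
    for (j in 1:2) {
      ev <- 0
      for (x in 0:1) {
        lik <- if (j == 1) c(0.9^x * 0.1^(1 - x), 0.1^x * 0.9^(1 - x))
               else c(0.1^x * 0.9^(1 - x), 0.9^x * 0.1^(1 - x))
        w <- lik * p
        pr <- sum(w)
        ev <- ev + pr * oracle(w / pr, j, h - 1)
      }
      best <- min(best, co$c + co$cs * (j != cur) + ev)
    }
    best
  }
  idx <- seq(1, g2$npoints, by = 10)
  vo <- sapply(idx, function(i) oracle(g2$points[i, ], 1, 6))
  # tolerance: twice the h^2 discretization scale of the grid (h = 1/200)
  expect_lt(max(abs(pol$V[idx, 1] - vo)), 2e-4)
})

test_that("stopping region contains the closed-form inner bound and grows with switch cost", {
  g <- grid60()
  pol0 <- cached("cdac60_cs0", solve_cdac(fov(), cost_params(0.1, 0), g))
  pol1 <- cdac60(0.1)
  s0 <- stopping_region(pol0, 1)
  s1 <- stopping_region(pol1, 1)
  # corners always stop
  for (i in 1:3) expect_true(which(g$points[, i] == 1) %in% s0)
  # theorem-1 inner bound at cs = 0
  pstar <- theorem1_threshold(0.9, 0.1)
  inner <- which(apply(g$points, 1, max) > pstar)
  expect_true(all(inner %in% s0))
  # switch cost enlarges the stopping region (set inclusion)
  expect_true(all(s0 %in% s1))
  expect_gt(length(s1), length(s0))
})

test_that("larger switch cost grows the stay region and shrinks the switch region", {
  g <- grid60()
  pol0 <- cached("cdac60_cs0", solve_cdac(fov(), cost_params(0.1, 0), g))
  pol1 <- cdac60(0.1)
  st0 <- stay_region(pol0, 1); st1 <- stay_region(pol1, 1)
  s1 <- stopping_region(pol1, 1)
  expect_gt(length(st1), length(st0))
  # stay points that still continue under the larger cs remain stay points
  expect_true(all(setdiff(st0, s1) %in% st1))
  # switch region shrinks as a set
  all_idx <- seq_len(g$npoints)
  sw0 <- setdiff(all_idx, c(stopping_region(pol0, 1), st0))
  sw1 <- setdiff(all_idx, c(s1, st1))
  expect_true(all(sw1 %in% sw0))
})

test_that("solved values and policy are permutation-equivariant", {
  g <- grid60()
  pol <- cdac60(0.1)
  perm <- c(2, 1, 3)
  idx_perm <- cdac:::grid_index(g, g$q[, perm])
  expect_lt(max(abs(pol$V[idx_perm, perm] - pol$V)), 1e-12)
  act_perm <- matrix(permute_code(pol$action[idx_perm, perm], perm),
                     nrow(pol$action))
  # remaining mismatches are deterministic lowest-index tie-breaks
  expect_gt(mean(act_perm == pol$action), 0.95)
})

test_that("declare-current restricts declarations to the fixated location", {
  g <- grid60()
  pol <- cached("cdac60_cur",
                solve_cdac(fov(), cost_params(0.1, 0.1), grid60(),
                           declare_rule = "current"))
  for (cur in 1:3) {
    dec <- pol$action[, cur][pol$action[, cur] < 3]
    expect_true(all(dec == cur - 1L))
  }
})

test_that("non-convergence raises a diagnostic error", {
  expect_error(
    solve_cdac(fov(0.51), cost_params(1e-9, 0), belief_grid(3, 8),
               max_iter = 3),
    "did not converge")
})
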