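test_that("interval partition construction follows the recorded minima", {
  traj <- list(
    list(a = 100, p = c(1e-6, 1e-4, 0.02, 0.30, 1), Ts = 4L),
    list(a = 100, p = c(1e-6, 1e-4, 0.05, 1), Ts = 3L),
    list(a = 200, p = c(1e-6, 1e-4, 0.03, 0.20, 1), Ts = 4L))
  pre <- fake_prelim(traj)
  part <- build_intervals(pre)
  expect_equal(part$G, 4)
  # breaks: m0, common F1 value, min p_2, min p_3, 1
  expect_equal(part$breaks, c(1e-6, 1e-4, 0.02, 0.20, 1))
  expect_true(all(diff(part$breaks) > 0))

  # inconsistent F1 PCV is a data error
  bad <- fake_prelim(list(list(a = 100, p = c(1e-6, 1e-4, 1), Ts = 2L),
                          list(a = 100, p = c(1e-6, 2e-4, 1), Ts = 2L)))
  expect_error(build_intervals(bad), "inconsistent")
})

test_that("interval lookup uses half-open intervals with terminal point 1", {
  part <- structure(list(G = 4, breaks = c(1e-6, 1e-4, 0.02, 0.20, 1)),
                    class = "pcv_partition")
  expect_equal(interval_of(1, part), 4)        # ideal pair
  expect_equal(interval_of(1e-4, part), 1)     # the F1 point
  expect_equal(interval_of(0.02, part), 2)     # lower bound belongs
  expect_equal(interval_of(0.20, part), 3)     # upper bound -> next interval
  expect_equal(interval_of(0.1999999, part), 2)
  expect_equal(interval_of(1e-6, part), 0)     # founder point
  expect_equal(interval_of(1e-8, part), 0)     # clamp below the partition
  expect_equal(interval_of(c(1e-4, 0.5, 1), part), c(1, 3, 4))
  expect_error(interval_of(1.5, part), "0, 1")
})

test_that("transition estimation counts interval moves and normalises rows", {
  # hand trajectory set under one action: interval-1 transitions
  # 1->1, 1->2 (run 1) and 1->2 (run 2)
  traj <- list(
    list(a = 100, p = c(1e-6, 1e-4, 1.5e-4, 0.03, 0.5, 1), Ts = 5L),
    list(a = 100, p = c(1e-6, 1e-4, 0.02, 0.25, 1), Ts = 4L))
  pre <- fake_prelim(traj)
  part <- structure(list(G = 4, breaks = c(1e-6, 1e-4, 0.02, 0.20, 1)),
                    class = "pcv_partition")
  est <- estimate_transitions(pre, part)
  N <- est$counts[["100"]]
  expect_equal(N[1, ], c(1, 2, 0, 0))
  expect_equal(N[2, ], c(0, 0, 2, 0))
  expect_equal(N[3, ], c(0, 0, 0, 2))
  W <- est$W[["100"]]
  expect_equal(W[1, ], c(1 / 3, 2 / 3, 0, 0))
  expect_equal(rowSums(W), rep(1, 4))
  # unobserved rows (interval 4 here) self-transition
  expect_equal(W[4, 4], 1)
  # no backwards transitions
  expect_true(all(W[lower.tri(W)] == 0))
})

test_that("step rewards combine linear cost and success-gated revenue", {
  cfg <- mati_config()
  expect_equal(step_reward(400, "m3.b10", 3, cfg), -4000)
  expect_equal(step_reward(0, "success", 5, cfg), 1.5e6)
  expect_equal(step_reward(0, "m2.b4", 2, cfg), 0)
  expect_equal(step_reward(100, "success", 9, cfg), -1000)  # past deadline
})

test_that("assembled transition matrices are stochastic with correct budget flow", {
  W <- matrix(c(0.4, 0.5, 0.1,
                0,   0.7, 0.3,
                0,   0,   1), 3, 3, byrow = TRUE)
  cfg <- mati_config(T = 3, budget_max = 4000,
                     budgets = c(3000, 4000), actions = c(0, 100, 200))
  mdp <- assemble_mdp(list(`100` = W, `200` = W), cfg)
  G <- 3; B <- 4
  expect_equal(mdp$n_states, (G - 1) * B + 2)
  for (P in mdp$P) {
    expect_equal(rowSums(P), rep(1, mdp$n_states), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
  # absorbing states
  for (P in mdp$P) {
    expect_equal(P[mdp$i_fail, mdp$i_fail], 1)
    expect_equal(P[mdp$i_succ, mdp$i_succ], 1)
  }
  # a = 100 costs exactly one $1,000 unit: (g=1, b=2) -> budget 1 states
  P100 <- mdp$P[["100"]]
  s <- mdp$state_index(1, 2)
  expect_equal(P100[s, mdp$state_index(1, 1)], 0.4)
  expect_equal(P100[s, mdp$state_index(2, 1)], 0.5)
  expect_equal(P100[s, mdp$i_succ], 0.1)
  # spending the last unit: non-success mass falls to failure
  s1 <- mdp$state_index(1, 1)
  expect_equal(P100[s1, mdp$i_fail], 0.9)
  expect_equal(P100[s1, mdp$i_succ], 0.1)
  # a = 0 in a live state is an immediate failure
  expect_equal(mdp$P[["0"]][s, mdp$i_fail], 1)
  # unaffordable action marked infeasible
  expect_false(mdp$feasible[s1, which(cfg$actions == 200)])
  expect_true(mdp$feasible[s1, which(cfg$actions == 100)])
})

test_that("backward induction solves a hand-checkable two-interval model", {
  # 2 intervals (1 live), success prob 0.5 per $1,000 spent on a = 100
  W100 <- matrix(c(0.5, 0.5, 0, 1), 2, 2, byrow = TRUE)
  W200 <- matrix(c(0.2, 0.8, 0, 1), 2, 2, byrow = TRUE)
  cfg <- mati_config(T = 2, budget_max = 2000, budgets = 2000,
                     actions = c(0, 100, 200), lambda = 1)
  mdp <- assemble_mdp(list(`100` = W100, `200` = W200), cfg)
  sol <- backward_induction(mdp)
  # epoch 1 (the only decision): success at t = 2 is worth 1.8e6
  # a=100: -1000 + 0.5 * 1.8e6 = 899000 ; a=200: -2000 + 0.8*1.8e6 = 1438000
  s <- mdp$state_index(1, 2)
  expect_equal(sol$u[1, s], 1438000)
  expect_equal(sol$d[1, s], 200)
  # with only one unit left, a=200 is infeasible
  s1 <- mdp$state_index(1, 1)
  expect_equal(sol$u[1, s1], 899000)
  expect_equal(sol$d[1, s1], 100)
})

test_that("terminal values seed the recursion and lambda = 0 is myopic", {
  set.seed(41)
  mdp <- random_fh_mdp(4, 3, T = 3, lambda = 0)
  sol <- backward_induction(mdp)
  expect_equal(sol$u[3, ], mdp$terminal)
  r <- mdp$reward(2)
  r[!mdp$feasible] <- -Inf
  expect_equal(sol$u[2, ], apply(r, 1, max))
  expect_equal(sol$d_idx[2, ], unname(max.col(r, ties.method = "first")))
})

test_that("policy evaluation reproduces the backward-induction value", {
  set.seed(42)
  for (i in 1:5) {
    mdp <- random_fh_mdp(sample(2:5, 1), sample(2:3, 1), sample(2:4, 1))
    sol <- backward_induction(mdp)
    expect_equal(evaluate_policy(mdp, sol$d_idx), sol$u, tolerance = 1e-12)
  }
})

test_that("enumeration oracle handles degenerate action spaces", {
  set.seed(43)
  # single action: oracle value equals direct policy evaluation
  mdp <- random_fh_mdp(3, 1, T = 3)
  o <- enumerate_policies_oracle(mdp)
  expect_equal(o$n_policies, 1)
  expect_equal(o$value,
               evaluate_policy(mdp, matrix(1L, 2, 3))[1, ])
  # two identical actions: same value, tie broken to the first
  P <- list(matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2),
            matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2))
  r <- matrix(1, 2, 2)
  mdp2 <- new_fh_mdp(P, r, c(0, 0), matrix(TRUE, 2, 2), 0.9, 3, 1:2)
  o2 <- enumerate_policies_oracle(mdp2)
  sol2 <- backward_induction(mdp2)
  expect_equal(o2$value, sol2$u[1, ])
  expect_true(all(o2$best_d_idx == 1))
  expect_true(all(sol2$d_idx == 1))
  # cap refuses oversized instances
  big <- random_fh_mdp(6, 3, T = 4)
  expect_error(enumerate_policies_oracle(big, cap = 100), "too large")
})

test_that("model bundles round-trip through JSON", {
  fit <- toy_fit()
  path <- withr::local_tempfile(fileext = ".json")
  write_mati_model(fit, path)
  back <- read_mati_model(path)
  expect_equal(back$partition$breaks, fit$partition$breaks, tolerance = 1e-14)
  expect_equal(back$solution$u, fit$solution$u, tolerance = 1e-12)
  expect_identical(back$policy_array, fit$policy_array)
  expect_equal(back$transitions$W, fit$transitions$W, tolerance = 1e-14)
})
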