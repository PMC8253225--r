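test_that("CTP outcome probabilities sum to one per budget", {
  fit <- toy_fit()
  ctp <- ctp_analysis(fit, budgets = c(4000, 6000, 8000), n_reps = 20,
                      seed = 51)
  for (B in unique(ctp$budget)) {
    rows <- ctp[ctp$budget == B, ]
    expect_equal(sum(rows$probability), 1, tolerance = 1e-12)
    expect_true(all(rows$se >= 0 & rows$se <= 0.5 / sqrt(20) + 1e-9))
    expect_true(all(rows$n == 20))
  }
})

test_that("a budget below the smallest action cost always fails", {
  fit <- toy_fit()
  ctp <- ctp_analysis(fit, budgets = 900, n_reps = 10, seed = 52)
  fail <- ctp[ctp$outcome == "failure", ]
  expect_equal(fail$probability, 1)
  expect_equal(nrow(ctp[ctp$budget == 900, ]), 1)
})

test_that("experiment tables are reproducible under the master seed", {
  fit <- toy_fit()
  c1 <- ctp_analysis(fit, budgets = c(5000, 7000), n_reps = 10, seed = 53)
  c2 <- ctp_analysis(fit, budgets = c(5000, 7000), n_reps = 10, seed = 53)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("success probability rises with budget and shows diminishing returns", {
  fit <- toy_fit()
  budgets <- c(3000, 5000, 8000, 10000)
  ctp <- ctp_analysis(fit, budgets = budgets, n_reps = 40, seed = 54)
  p_succ <- vapply(budgets, function(B) {
    rows <- ctp[ctp$budget == B & ctp$outcome != "failure", ]
    sum(rows$probability)
  }, numeric(1))
  # allow small Monte-Carlo wiggle on the monotone trend
  mc_tol <- 3 * sqrt(0.25 / 40)
  expect_true(all(diff(p_succ) >= -mc_tol))
  expect_gt(p_succ[length(p_succ)], p_succ[1])
})

test_that("the dynamic policy dominates every static strategy in-model", {
  fit <- toy_fit()
  cmp <- compare_strategies(fit, budget = 8000, static_Ks = c(100, 200),
                            n_reps = 12, seed = 55)
  v <- cmp$values
  dyn <- v$in_model_value[v$strategy == "dynamic"]
  expect_true(all(dyn >= v$in_model_value[v$strategy != "dynamic"] - 1e-6))
  # outcome table covers every strategy with probabilities summing to 1
  for (s in unique(cmp$table$strategy))
    expect_equal(sum(cmp$table$probability[cmp$table$strategy == s]), 1,
                 tolerance = 1e-12)
})

test_that("revenue-curve regression recovers known parameters", {
  set.seed(56)
  a <- c(a1 = 1.6e6, a2 = -8e6, a3 = -0.12)
  budgets <- seq(11000, 80000, by = 3000)
  x <- budgets / 1000
  y <- a[1] + a[2] * exp(a[3] * x) + rnorm(length(x), 0, 2e3)
  curve <- fit_revenue_curve(budgets, y)
  expect_lt(abs(curve$coef[["a1"]] - a[1]) / abs(a[1]), 0.05)
  expect_lt(abs(curve$coef[["a2"]] - a[2]) / abs(a[2]), 0.05)
  expect_lt(abs(curve$coef[["a3"]] - a[3]) / abs(a[3]), 0.05)
  # the marginal curve is the analytic derivative of the fitted curve
  h <- 1
  xs <- 30000
  fitted <- function(b) curve$coef[["a1"]] +
    curve$coef[["a2"]] * exp(curve$coef[["a3"]] * b / 1000)
  expect_equal(curve$marginal(xs),
               (fitted(xs + h) - fitted(xs - h)) / (2 * h) * 1000,
               tolerance = 1e-6)
  # analytic optimum: marginal = unit
  expect_equal(curve$marginal(curve$optimal_budget), 1000, tolerance = 1e-6)
})

test_that("allocation breakdown equals direct arithmetic on the spend matrix", {
  fit <- toy_fit()
  ctp <- ctp_analysis(fit, budgets = c(6000, 9000), n_reps = 15, seed = 57)
  bd <- allocation_breakdown(fit, ctp = ctp)
  sims <- attr(ctp, "sims")
  for (B in c(6000, 9000)) {
    spend <- attr(sims[[as.character(B)]], "spend")
    manual <- colMeans(spend) / sum(colMeans(spend))
    got <- bd$proportion[bd$budget == B]
    expect_equal(got, unname(manual), tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    # failed runs still contribute their partial spend
    expect_equal(sum(colMeans(spend)) * 15,
                 sum(sims[[as.character(B)]]$total_cost))
  }
})
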