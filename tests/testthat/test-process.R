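test_that("static allocation truncates to the largest affordable multiple", {
  pol <- static_policy(400)
  cfg <- mati_config()
  expect_equal(allocate(pol, 1, NULL, 32000, NULL, config = cfg), 400L)
  # the 600-strategy on $32,000: 600 in generations 1-5, then 200
  pol600 <- static_policy(600)
  remaining <- 32000
  ks <- integer(0)
  for (t in 0:6) {
    k <- allocate(pol600, t, NULL, remaining, NULL, config = cfg)
    if (k == 0) break
    ks <- c(ks, k)
    remaining <- remaining - 10 * k
  }
  expect_equal(ks, c(600L, 600L, 600L, 600L, 600L, 200L))
  expect_equal(remaining, 0)
})

test_that("dynamic allocation spends minimally at t = 0 and stops when broke", {
  fit <- toy_fit()
  pol <- mdp_policy(fit)
  cfg <- fit$config
  expect_equal(allocate(pol, 0, NULL, 8000, fit$map, config = cfg), 100L)
  expect_equal(allocate(pol, 0, NULL, 500, fit$map, config = cfg), 0L)
  expect_equal(allocate(pol, 2, NULL, 900, fit$map, best_pcv = 0.5,
                        config = cfg), 0L)
  # beyond the solved horizon the project is out of time
  expect_equal(allocate(pol, cfg$T, NULL, 8000, fit$map, best_pcv = 0.5,
                        config = cfg), 0L)
  # in-range lookups return actions from the action grid
  k <- allocate(pol, 2, NULL, 6000, fit$map, best_pcv = 0.05, config = cfg)
  expect_true(k %in% cfg$actions)
  expect_lte(10 * k, 6000)
})

test_that("an ideal starting genotype succeeds immediately", {
  map <- toy_map()
  fd <- make_founders(map, character(0))  # elite already ideal
  r <- run_mati(fd$elite, fd$donor, map, 5000, static_policy(100),
                T = 4, seed = 1)
  expect_equal(r$Ts, 0)
  expect_true(r$success)
  expect_equal(r$total_cost, 0)
  expect_equal(nrow(r$trace), 0)
})

test_that("a zero allocation with budget remaining fails the project", {
  map <- toy_map()
  fd <- toy_founders()
  # $500 cannot buy the smallest progeny batch
  r <- run_mati(fd$elite, fd$donor, map, 500, static_policy(100),
                T = 4, seed = 2)
  expect_false(r$success)
  expect_equal(r$Ts, Inf)
  expect_equal(r$reward, 0)
})

test_that("single-locus introgression with K = 200 succeeds by generation 2", {
  m1 <- map_from_f(numeric(0))
  elite <- matrix(0L, 1, 2)
  donor <- matrix(c(1L, 0L), 1, 2)  # one copy of the missing allele
  ts <- vapply(1:300, function(i)
    run_mati(elite, donor, m1, budget = 1e5, static_policy(200), T = 8,
             seed = i)$Ts, numeric(1))
  # P(no ideal among 200 F2) = (3/4)^200, negligible
  expect_gte(mean(ts <= 2), 0.99)
  expect_true(all(ts >= 2))  # the F1 is never ideal
})

test_that("budget accounting is exact and runs are seed-deterministic", {
  fit <- toy_fit()
  map <- toy_map()
  fd <- toy_founders()
  for (pol in list(static_policy(200), mdp_policy(fit))) {
    r1 <- run_mati(fd$elite, fd$donor, map, 8000, pol, T = 4,
                   config = fit$config, seed = 33)
    r2 <- run_mati(fd$elite, fd$donor, map, 8000, pol, T = 4,
                   config = fit$config, seed = 33)
    expect_identical(r1$trace, r2$trace)
    expect_identical(r1$Ts, r2$Ts)
    expect_equal(r1$total_cost, sum(10 * r1$trace$K))
    # remaining budget never goes negative
    expect_true(all(r1$trace$budget_before - 10 * r1$trace$K >= 0))
    expect_equal(diff(r1$trace$budget_before),
                 -10 * r1$trace$K[-nrow(r1$trace)])
  }
})

test_that("the selected-pair PCV trace never decreases within a run", {
  fit <- toy_fit()
  map <- toy_map()
  fd <- toy_founders()
  for (seed in 1:10) {
    r <- run_mati(fd$elite, fd$donor, map, 9000, mdp_policy(fit), T = 4,
                  config = fit$config, seed = seed)
    if (nrow(r$trace) >= 2) {
      expect_true(all(diff(r$trace$log10_pcv) >= -1e-12))
      expect_true(all(diff(r$trace$interval) >= 0))
    }
  }
})

test_that("realized rewards follow the revenue schedule", {
  fit <- toy_fit()
  map <- toy_map()
  fd <- toy_founders()
  r <- run_mati(fd$elite, fd$donor, map, 8000, mdp_policy(fit), T = 4,
                config = fit$config, seed = 9)
  if (r$success) {
    expect_equal(r$revenue, 2e6 - 1e5 * r$Ts)
    expect_equal(r$reward, r$revenue - r$total_cost)
  } else {
    expect_equal(r$revenue, 0)
    expect_equal(r$reward, -r$total_cost)
  }
  trace_path <- withr::local_tempfile(fileext = ".csv")
  write_run_trace(r, trace_path)
  expect_equal(nrow(read.csv(trace_path)), nrow(r$trace))
})
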