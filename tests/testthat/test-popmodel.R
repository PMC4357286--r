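# Literal loop oracle, independent of the package implementation.
loop_oracle <- function(inp) {
  lm_at <- function(k) switch(inp$growth,
    constant = inp$lz_minus_0,
    geometric = inp$lz_minus_0 * inp$fold^(k / inp$n_steps),
    linear = inp$lz_minus_0 * (1 + (inp$fold - 1) * k / inp$n_steps))
  lp <- inp$lz_plus_0
  for (k in 0:(inp$n_steps - 1)) lp <- lp + lm_at(k) * inp$dp
  lp
}

test_that("the extrapolation recurrence matches its printed one-step form", {
  one <- extrapolate(recurrence_input(6, 50, 0.035, 1))
  expect_equal(one$series$lz_plus[2], 6 + 50 * 0.035)   # 7.75
  expect_equal(one$series$lz_plus[2], 7.75)
  # dp = 0 freezes the Lz+ series
  frozen <- extrapolate(recurrence_input(6, 50, 0, 8))
  expect_true(all(frozen$series$lz_plus == 6))
  # eight constant steps accumulate linearly: 6 + 8 x 1.75
  eight <- extrapolate(recurrence_input(6, 50, 0.035, 8))
  expect_equal(eight$series$lz_plus[9], 20.0)
  expect_equal(eight$increase, 14.0)
})

test_that("closed form, recurrence, and loop oracle agree to 1e-9 relative", {
  cf1 <- closed_form_increase(recurrence_input(100, 1000, 0.02, 5,
                                               "geometric", fold = 1))
  expect_equal(cf1, 5 * 1000 * 0.02, tolerance = 1e-12)   # constant limit
  cf2 <- closed_form_increase(recurrence_input(0, 1000, 0.035, 8,
                                               "geometric", fold = 1.4))
  expect_lt(abs(cf2 - 325.9), 0.1)   # direct summation value
  set.seed(123)
  for (i in 1:100) {
    inp <- recurrence_input(
      lz_plus_0 = runif(1, 0, 500), lz_minus_0 = runif(1, 1, 5000),
      dp = runif(1, 0, 0.2), n_steps = sample(1:20, 1),
      growth = sample(c("constant", "geometric", "linear"), 1),
      fold = runif(1, 0.5, 3))
    ext <- extrapolate(inp)
    expect_lt(abs(ext$series$lz_plus[inp$n_steps + 1] - loop_oracle(inp)) /
                max(1, abs(loop_oracle(inp))), 1e-9)
    if (inp$growth == "geometric")
      expect_lt(abs(ext$increase - closed_form_increase(inp)) /
                  max(1e-12, closed_form_increase(inp)), 1e-9)
  }
  expect_error(closed_form_increase(recurrence_input(0, 10, 0.1, 2)),
               "geometric")
})

test_that("fold change and the sufficiency bound reproduce the headline arithmetic", {
  expect_equal(fold_change(c(100, 120, 140)), 1.4)
  expect_equal(fold_change(rep(37, 9)), 1.0)
  expect_error(fold_change(c(0, 10)), "zero start")
  # the measured 24-hr Lz+ increase is 256.4; with dp = 0.035 per 3-hr step
  # and 1.4x geometric plasmatocyte growth the extrapolation covers it for
  # any initial Lz- count at or above the analytic bound
  bound <- sufficient_lz_minus_bound(256.4, dp = 0.035, n_steps = 8,
                                     fold = 1.4)
  s_sum <- sum(1.4^((0:7) / 8))
  expect_equal(bound, 256.4 / (0.035 * s_sum), tolerance = 1e-12)
  at_bound <- consistency_report(256.4,
                                 recurrence_input(0, ceiling(bound), 0.035, 8,
                                                  "geometric", fold = 1.4))
  expect_true(at_bound$sufficient)
  below <- consistency_report(256.4,
                              recurrence_input(0, floor(bound) - 5, 0.035, 8,
                                               "geometric", fold = 1.4))
  expect_false(below$sufficient)
})

test_that("the extrapolated increase is monotone in dp, initial count, and fold", {
  inc <- function(dp, l0, f)
    extrapolate(recurrence_input(10, l0, dp, 8, "geometric", fold = f))$increase
  dps <- seq(0, 0.2, by = 0.05)
  expect_true(all(diff(vapply(dps, inc, numeric(1), l0 = 500, f = 1.4)) >= 0))
  l0s <- c(10, 100, 500, 2000)
  expect_true(all(diff(vapply(l0s, function(l) inc(0.035, l, 1.4),
                              numeric(1))) >= 0))
  folds <- c(0.8, 1, 1.4, 2)
  expect_true(all(diff(vapply(folds, function(f) inc(0.035, 500, f),
                              numeric(1))) >= 0))
})

test_that("the agent-based simulator reproduces the recurrence expectation", {
  # one 3-hr step: expected new Lz+ cells = lz_minus_0 x dp
  p <- sim_params()
  inds <- vapply(1:30, function(r) {
    sim <- simulate_cluster(p, 180, snapshot_interval = 180, seed = 1200 + r)
    sum(sim$log$kind == "INDUCTION" & sim$log$cell_id <= 50)
  }, numeric(1))
  expected <- extrapolate(recurrence_input(6, 50, 0.035, 1))$increase  # 1.75
  mc_se <- stats::sd(inds) / sqrt(length(inds))
  expect_lt(abs(mean(inds) - expected), 3 * mc_se + 0.2)
})
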