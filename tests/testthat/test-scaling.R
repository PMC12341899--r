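test_that("rmsf of iid series has exponent near 0.5 and rejects constants", {
  a <- vapply(1:10, function(i) {
    set.seed(400 + i)
    fit_scaling_exponent(rmsf_curve(rnorm(4099)), c(8, 512))$exponent
  }, numeric(1))
  expect_lt(abs(mean(a) - 0.5), 0.05)
  expect_error(rmsf_curve(rep(1, 200)), "degenerate")
  expect_error(rmsf_curve(rnorm(50)), ">= 64")
})

test_that("MSD separates ballistic from stationary motion", {
  tr <- gen_ballistic(walker_config("ballistic", speed_mean = 1.5))
  fit <- fit_scaling_exponent(msd_curve(tr, 1:410))
  expect_equal(fit$exponent, 2, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.999)
  still <- trajectory(rep(0, 100), rep(0, 100))
  expect_error(msd_curve(still), "degenerate")
})

test_that("DFA calibrates on white noise and Brownian paths", {
  g <- vapply(1:10, function(i) {
    set.seed(500 + i)
    w <- rnorm(4096)
    c(fit_scaling_exponent(dfa_curve(w, log_spaced_scales(8, 512, 25)))$exponent,
      fit_scaling_exponent(dfa_curve(cumsum(w),
                                     log_spaced_scales(8, 512, 25)))$exponent)
  }, numeric(2))
  expect_lt(abs(mean(g[1, ]) - 0.5), 0.05)
  expect_lt(abs(mean(g[2, ]) - 1.5), 0.1)
})

test_that("per-box polynomial detrending of matching order removes the trend", {
  # profile of a linear ramp is quadratic, so order-2 detrending zeroes it
  ramp <- 0.3 * (1:512) + 2
  f2 <- dfa_curve(ramp, detrend_order = 2)
  expect_lt(max(f2$values), 1e-9)
  # order-1 leaves the quadratic residual (slope ~ 2), the Brownian-class cap
  f1 <- fit_scaling_exponent(dfa_curve(ramp, detrend_order = 1))
  expect_gt(f1$exponent, 1.9)
  expect_error(dfa_curve(rnorm(100), box_sizes = c(8, 16, 60)), "length/4")
})

test_that("exact and noisy power laws are fitted as specified", {
  l <- log_spaced_scales(4, 400, 20)
  cv <- scaling_curve(l, 3 * l^0.75, kind = "msd")
  fit <- fit_scaling_exponent(cv)
  expect_equal(fit$exponent, 0.75, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$intercept, log10(3), tolerance = 1e-12)

  set.seed(31)
  noisy <- 3 * l^0.75 * exp(rnorm(length(l), 0, 0.05))
  nf <- fit_scaling_exponent(scaling_curve(l, noisy, kind = "msd"))
  # OLS on logs as the oracle, with its own standard error
  ly <- log10(noisy); lx <- log10(l)
  ols <- lm(ly ~ lx)
  expect_equal(nf$exponent, unname(coef(ols)[2]), tolerance = 1e-12)
  se <- summary(ols)$coefficients[2, 2]
  expect_lt(abs(nf$exponent - 0.75), 3 * se)

  expect_error(fit_scaling_exponent(scaling_curve(c(4, 8, 16), 1:3,
                                                  kind = "msd")),
               "4 curve points")
})

test_that("fitted exponents are invariant under a change of units", {
  tr <- make_persistent(13, n_frames = 2050)
  ss <- step_series(tr)$values
  tr2 <- trajectory(2 * tr$positions[, 1], 2 * tr$positions[, 2])
  f <- function(cv, ...) fit_scaling_exponent(cv, ...)$exponent
  expect_equal(f(rmsf_curve(ss)), f(rmsf_curve(2 * ss)), tolerance = 1e-10)
  expect_equal(f(msd_curve(tr)), f(msd_curve(tr2)), tolerance = 1e-10)
  expect_equal(f(dfa_curve(ss)), f(dfa_curve(2 * ss)), tolerance = 1e-10)
})

test_that("rmsf recovers the Hurst exponent of fGn and DFA its integral", {
  for (H in c(0.6, 0.9)) {
    a <- vapply(1:12, function(i)
      fit_scaling_exponent(rmsf_curve(fgn(4099, H, seed = 600 + i)),
                           c(8, 512))$exponent, numeric(1))
    expect_lt(abs(mean(a) - H), 0.05)
    g <- vapply(1:12, function(i)
      fit_scaling_exponent(dfa_curve(cumsum(fgn(4096, H, seed = 700 + i)),
                                     log_spaced_scales(8, 512, 25)))$exponent,
      numeric(1))
    expect_lt(abs(mean(g) - (H + 1)), 0.1)
  }
})

test_that("correlation time flags iid series and recovers walker persistence", {
  set.seed(41)
  ct <- correlation_time(rmsf_curve(rnorm(4099)))
  expect_true(ct$no_correlated_regime)
  expect_equal(ct$minutes, 50 * 0.5 / 60)

  cts <- vapply(1:10, function(i) {
    tr <- make_persistent(800 + i, tau = 300)
    correlation_time(rmsf_curve(step_series(tr)), dt = 0.5)$minutes
  }, numeric(1))
  expect_gt(median(cts), 2.5)   # within a factor of 2 of tau = 5 min
  expect_lt(median(cts), 10)
  # grid snapping: every estimate is a multiple of 25 s
  expect_true(all(abs(cts * 60 / 25 - round(cts * 60 / 25)) < 1e-9))
})

test_that("DFA regimes classify by input class with an uncorrelated band", {
  expect_equal(classify_dfa_regime(1.82, "brownian_like"), "persistent")
  expect_equal(classify_dfa_regime(0.48, "noise_like"), "uncorrelated")
  expect_equal(classify_dfa_regime(0.3, "noise_like"), "antipersistent")
  expect_equal(classify_dfa_regime(1.2, "brownian_like"), "antipersistent")
  expect_equal(classify_dfa_regime(2.5, "brownian_like"), "out_of_range")
  expect_equal(classify_dfa_regime(-0.1, "noise_like"), "out_of_range")
})
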