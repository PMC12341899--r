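test_that("ballistic walker moves at constant speed along the bias axis", {
  cfg <- walker_config("ballistic", speed_mean = 1.5, n_frames = 4100)
  tr <- gen_ballistic(cfg)
  steps <- step_series(tr)$values
  expect_equal(steps, rep(0.75, 4099))
  expect_equal(sum(steps), 3074.25)
  expect_equal(directionality_ratio(tr), 1)
  expect_warning(gen_ballistic(walker_config("ballistic", speed_mean = 0)),
                 "stationary")
})

test_that("stochastic generators are reproducible given a seed", {
  for (gen in list(function(s) gen_brownian(walker_config("brownian", seed = s)),
                   function(s) gen_persistent(
                     walker_config("persistent", n_frames = 500, seed = s)))) {
    a <- gen(99); b <- gen(99); c <- gen(100)
    expect_identical(a$positions, b$positions)
    expect_false(identical(a$positions, c$positions))
  }
  expect_identical(fgn(256, 0.7, seed = 3), fgn(256, 0.7, seed = 3))
})

test_that("fGn has the analytic autocovariance structure", {
  # H = 0.5 is white noise: all lag >= 1 autocorrelations vanish
  z <- fgn(8192, 0.5, seed = 21)
  for (k in 1:3)
    expect_lt(abs(cor(z[1:(8192 - k)], z[(1 + k):8192])), 3 / sqrt(8192))
  # H = 0.8: sample autocovariance tracks rho(k) within Monte-Carlo error
  z <- fgn(30000, 0.8, seed = 22)
  for (k in 1:4) {
    emp <- cor(z[1:(30000 - k)], z[(1 + k):30000])
    expect_lt(abs(emp - fgn_acov(k, 0.8)), 0.06)
  }
  expect_error(fgn(256, 1.2), "hurst")
  expect_error(walker_config("fgn_steps", hurst = 1.2), "hurst")
})

test_that("fGn step series are nonnegative with the contracted length", {
  cfg <- walker_config("fgn_steps", hurst = 0.75, n_frames = 4100, seed = 4)
  ss <- gen_fgn_steps(cfg)
  expect_length(ss$values, 4099)
  expect_true(all(ss$values >= 0))
  expect_error(gen_fgn_steps(walker_config("fgn_steps", n_frames = 50,
                                           seed = 1)), ">= 64")
})

test_that("unbiased persistent walkers have no preferred direction", {
  cs <- vapply(1:60, function(i) displacement_cosine(
    make_persistent(i, n_frames = 800)), numeric(1))
  expect_lt(abs(mean(cs)), 0.25)
  # sector occupancy uniform within multinomial sampling error
  trs <- lapply(61:220, function(i) make_persistent(i, n_frames = 300))
  h <- sector_histogram(trs)
  counts <- h / 100 * 160
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("strong bias toward +x drives the median cosine close to 1", {
  cs <- vapply(1:20, function(i) displacement_cosine(
    make_persistent(i + 300, n_frames = 2000, bias = 0.02)), numeric(1))
  expect_gt(median(cs), 0.9)
})

test_that("persistent walks are ballistic-like well below the persistence time", {
  b <- vapply(1:10, function(i) {
    tr <- make_persistent(i + 50, n_frames = 2050, tau = 300)
    fit_scaling_exponent(msd_curve(tr, 1:50))$exponent  # lags <= 25 s << 300 s
  }, numeric(1))
  expect_gt(mean(b), 1.5)
})

test_that("scenario cohorts reproduce the directional envelopes", {
  # Sc1: no stimulus, cohort median cosine near 0 (median of near-uniform
  # cosines is noisy, so a large cohort keeps this a ~3-sigma check)
  sc1 <- gen_cohort(scenario_preset("Sc1", n_frames = 1200), 200, seed = 5)
  cs1 <- vapply(sc1, displacement_cosine, numeric(1))
  expect_lt(abs(median(cs1)), 0.3)
  # Sc4: double stimulus splits the cohort roughly 58/42 toward the peptide
  sc4 <- gen_cohort(scenario_preset("Sc4", n_frames = 1200), 100, seed = 6)
  cs4 <- vapply(sc4, displacement_cosine, numeric(1))
  expect_gt(sum(cs4 < 0), 42)   # ~58 expected, 3 sigma ~ 15
  expect_lt(sum(cs4 < 0), 73)
  # single-walker cohorts work and are deterministic per seed
  one <- gen_cohort(scenario_preset("Sc2", n_frames = 300), 1, seed = 7)
  expect_length(one, 1)
  again <- gen_cohort(scenario_preset("Sc2", n_frames = 300), 1, seed = 7)
  expect_identical(one[[1]]$positions, again[[1]]$positions)
})

test_that("uncorrelated generators pass the same whiteness checks", {
  # fgn(H = 0.5) and Brownian step series: rmsf alpha and DFA gamma ~ 0.5
  stats <- vapply(1:25, function(i) {
    z <- fgn(2048, 0.5, seed = 1000 + i)
    tr <- gen_brownian(walker_config("brownian", n_frames = 2049,
                                     seed = 2000 + i))
    ss <- step_series(tr)$values
    c(fit_scaling_exponent(rmsf_curve(z))$exponent,
      fit_scaling_exponent(dfa_curve(z))$exponent,
      fit_scaling_exponent(rmsf_curve(ss))$exponent)
  }, numeric(3))
  m <- rowMeans(stats)
  se <- apply(stats, 1, sd) / sqrt(ncol(stats))
  expect_lt(abs(m[1] - 0.5), 3 * se[1] + 0.02)
  expect_lt(abs(m[2] - 0.5), 3 * se[2] + 0.02)
  expect_lt(abs(m[3] - 0.5), 3 * se[3] + 0.02)
})
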