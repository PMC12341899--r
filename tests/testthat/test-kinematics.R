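test_that("displacement cosine reads direction against the chamber axis", {
  fr <- stimulus_frame(c(1, 0))
  expect_equal(displacement_cosine(trajectory(c(0, 100), c(0, 0)), fr), 1)
  expect_equal(displacement_cosine(trajectory(c(0, -50), c(0, 0)), fr), -1)
  expect_equal(displacement_cosine(trajectory(c(0, 0), c(0, 30)), fr), 0)
  loop <- trajectory(c(0, 1, 0), c(0, 1, 0))
  expect_warning(cc <- displacement_cosine(loop, fr), "undefined")
  expect_true(is.na(cc))
})

test_that("cosine and sine of the displacement are consistent", {
  set.seed(81)
  for (i in 1:20) {
    tr <- trajectory(c(0, rnorm(1)), c(0, rnorm(1)))
    cc <- displacement_cosine(tr)
    ang <- displacement_angle(tr) * pi / 180
    expect_equal(cc^2 + sin(ang)^2, 1, tolerance = 1e-12)
    expect_equal(cos(ang), cc, tolerance = 1e-12)
  }
})

test_that("sector histogram uses half-open 45-degree bins", {
  centers <- (0:7) * 45 + 22.5
  trs <- lapply(centers * pi / 180, function(a)
    trajectory(c(0, cos(a)), c(0, sin(a))))
  h <- sector_histogram(trs)
  expect_equal(as.vector(h), rep(12.5, 8))
  # all due +x
  right <- lapply(1:5, function(i) trajectory(c(0, i), c(0, 0)))
  hr <- sector_histogram(right)
  expect_equal(unname(hr[1]), 100)
  # a boundary angle of exactly 45 degrees belongs to sector 1, not 0
  b45 <- trajectory(c(0, 1), c(0, 1))
  hb <- sector_histogram(list(b45))
  expect_equal(unname(hb[2]), 100)
  still <- trajectory(c(0, 0), c(0, 0))
  expect_error(suppressWarnings(sector_histogram(list(still))), "zero net")
})

test_that("intensity of response is the net displacement in millimetres", {
  expect_equal(intensity_of_response(trajectory(c(0, 3000), c(0, 4000))), 5)
  expect_equal(intensity_of_response(trajectory(c(0, 1, 0), c(0, 1, 0))), 0)
  bal <- gen_ballistic(walker_config("ballistic", speed_mean = 1.5))
  expect_equal(intensity_of_response(bal), 3.07425)  # 1.5 um/s x 2049.5 s
})

test_that("directionality ratio spans straight paths to closed loops", {
  expect_equal(directionality_ratio(trajectory(c(0, 1, 2, 3), rep(0, 4))), 1)
  expect_equal(directionality_ratio(
    trajectory(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))), 0)
  # right angle with equal legs
  expect_equal(directionality_ratio(trajectory(c(0, 1, 1), c(0, 0, 1))),
               sqrt(2) / 2)
  expect_warning(dr <- directionality_ratio(trajectory(c(0, 0), c(0, 0))),
                 "stationary")
  expect_true(is.na(dr))
})

test_that("DR never exceeds 1 on random paths (triangle inequality)", {
  set.seed(82)
  for (i in 1:30) {
    tr <- trajectory(cumsum(rnorm(50)), cumsum(rnorm(50)))
    expect_lte(directionality_ratio(tr), 1)
  }
})

test_that("average speed is total path length over duration", {
  bal <- gen_ballistic(walker_config("ballistic", speed_mean = 1.5))
  expect_equal(average_speed(bal), 1.5)
  expect_equal(average_speed(trajectory(rep(0, 10), rep(0, 10))), 0)
  tr <- make_persistent(83, n_frames = 300)
  ss <- step_series(tr)
  expect_equal(average_speed(tr),
               sum(ss$values) / ((n_frames(tr) - 1) * tr$dt))
})

test_that("kinematics are translation-invariant and rotation-equivariant", {
  set.seed(84)
  x <- cumsum(rnorm(80)); y <- cumsum(rnorm(80))
  tr <- trajectory(x, y)
  shifted <- trajectory(x + 123, y - 77)
  expect_equal(intensity_of_response(shifted), intensity_of_response(tr))
  expect_equal(directionality_ratio(shifted), directionality_ratio(tr))
  expect_equal(average_speed(shifted), average_speed(tr))
  expect_equal(displacement_cosine(shifted), displacement_cosine(tr))
  for (ang in c(0.7, 2.1)) {
    rot <- trajectory(cos(ang) * x - sin(ang) * y,
                      sin(ang) * x + cos(ang) * y)
    fr_rot <- stimulus_frame(c(cos(ang), sin(ang)))
    expect_equal(displacement_cosine(rot, fr_rot), displacement_cosine(tr),
                 tolerance = 1e-12)
  }
})

test_that("kinematic summary collects the per-trajectory descriptor row", {
  tr <- make_persistent(85, n_frames = 400)
  row <- kinematic_summary(tr)
  expect_named(row, c("track_id", "cell_type", "scenario", "cosine",
                      "angle_deg", "sector", "IR_mm", "DR", "AS_um_s"))
  expect_true(row$DR >= 0 && row$DR <= 1)
  expect_true(row$sector %in% 0:7)
})
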