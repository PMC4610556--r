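test_that("blink frequency is the closed-frame fraction", {
  expect_equal(blink_frequency(make_facial(600, eye_closed = TRUE)), 1)
  expect_equal(blink_frequency(make_facial(600, eye_closed = FALSE)), 0)
  f <- make_facial(60)
  f$eye_closed[1:15] <- TRUE
  expect_equal(blink_frequency(f), 0.25)
  expect_error(blink_frequency(f[0, ]), class = "drowsefuse_invalid_window")
})

test_that("eye-closed duration counts only sustained closure runs", {
  # entire window closed: one qualifying run
  expect_equal(eye_closed_duration(make_facial(600, eye_closed = TRUE)), 1)
  # one 1 s closure at 30 fps in 60 s: below the 2 s cutoff
  f <- make_facial(1800, fps = 30)
  f$eye_closed[100:129] <- TRUE
  expect_equal(eye_closed_duration(f), 0)
  # two separate 3 s closures at 10 fps: 60 of 600 frames
  g <- make_facial(600, fps = 10)
  g$eye_closed[101:130] <- TRUE
  g$eye_closed[401:430] <- TRUE
  expect_equal(eye_closed_duration(g), 0.1)
})

test_that("mean eye-opened level averages eyelid heights", {
  f <- make_facial(4)
  f$eyelid_h <- c(3, 4, 5, 8)
  expect_equal(mean_eye_opened_level(f), 5)
  expect_equal(mean_eye_opened_level(make_facial(10, eyelid_h = 12)), 12)
})

test_that("yawning frequency thresholds the mouth-opening ratio", {
  cfg <- feature_config(t_m = 0.6)
  expect_equal(yawning_frequency(make_facial(10, mouth_h = 40, mouth_w = 50),
                                 cfg), 1)
  expect_equal(yawning_frequency(make_facial(10, mouth_h = 20, mouth_w = 50),
                                 cfg), 0)
  # zero threshold flags every valid frame
  expect_equal(yawning_frequency(make_facial(10, mouth_h = 1, mouth_w = 50),
                                 feature_config(t_m = 0)), 1)
  # degenerate geometry frames are excluded with a warning
  f <- make_facial(4, mouth_h = 40, mouth_w = 50)
  f$mouth_w[2] <- 0
  expect_warning(yf <- yawning_frequency(f, cfg),
                 class = "drowsefuse_degenerate_geometry")
  expect_equal(yf, 1)
})

test_that("percentage of non-steering uses the angular-velocity band", {
  v <- make_vehicle(4, steer_rate = c(0.05, -0.2, 0, 0.3))
  expect_equal(percent_non_steering(v), 0.5)
  expect_equal(percent_non_steering(make_vehicle(10, steer_rate = 0)), 1)
  expect_equal(percent_non_steering(make_vehicle(10, steer_rate = 5)), 0)
  # falls back to differentiating the angle series: 1 deg per 0.1 s = 10 deg/s
  ramp <- make_vehicle(10)
  ramp$steer_angle <- seq_len(10)
  expect_equal(percent_non_steering(ramp), 0)
})

test_that("steering-angle and speed dispersions use the population form", {
  expect_equal(steering_angle_sd(make_vehicle(10, steer_angle = 3)), 0)
  expect_equal(steering_angle_sd(make_vehicle(2, steer_angle = c(0, 10))), 5)
  expect_equal(steering_angle_sd(make_vehicle(4, steer_angle = c(1, 2, 3, 4))),
               sqrt(1.25))
  expect_equal(speed_sd(make_vehicle(3, speed = 100)), 0)
  expect_equal(speed_sd(make_vehicle(2, speed = c(90, 110))), 10)
  expect_equal(speed_sd(make_vehicle(3, speed = c(80, 100, 120))),
               sqrt(800 / 3))
})

test_that("dispersion features are translation-invariant and scale-equivariant", {
  set.seed(12)
  for (i in 1:20) {
    x <- stats::rnorm(50, 10, 4)
    v <- make_vehicle(50)
    v$steer_angle <- x
    v$speed <- x
    base_a <- steering_angle_sd(v)
    base_s <- speed_sd(v)
    shift <- v
    shift$steer_angle <- x + 7
    shift$speed <- x + 7
    expect_equal(steering_angle_sd(shift), base_a, tolerance = 1e-12)
    expect_equal(speed_sd(shift), base_s, tolerance = 1e-12)
    scaled <- v
    scaled$steer_angle <- 3 * x
    scaled$speed <- 3 * x
    expect_equal(steering_angle_sd(scaled), 3 * base_a, tolerance = 1e-12)
    expect_equal(speed_sd(scaled), 3 * base_s, tolerance = 1e-12)
  }
})

test_that("lane deviation uses the slope-angle ratio rule", {
  # symmetric geometry: xi = 1, never deviating under the defaults
  expect_equal(lane_deviation_frequency(make_vehicle(10)), 0)
  # xi = 2 on every frame fires the left-deviation rule
  v <- make_vehicle(10, theta_l = pi / 2 - 0.4, theta_r = pi / 2 + 0.2)
  expect_equal(lane_deviation_frequency(v), 1)
  # right drift: xi below 1 / lambda_R
  vr <- make_vehicle(10, theta_l = pi / 2 - 0.1, theta_r = pi / 2 + 0.2)
  expect_equal(lane_deviation_frequency(vr), 1)
  # the literal one-sided rule misses the right drift
  expect_equal(lane_deviation_frequency(vr, feature_config(lane_rule = "literal")),
               0)
  # vertical right lane line is indeterminate and excluded
  vx <- make_vehicle(4, theta_l = pi / 2 - 0.4, theta_r = pi / 2 + 0.2)
  vx$theta_r[2] <- pi / 2
  expect_warning(fl <- lane_deviation_frequency(vx),
                 class = "drowsefuse_indeterminate_lane")
  expect_equal(fl, 1)
})

test_that("windowing drops incomplete windows and aligns the sub-window", {
  f <- make_facial(1200, fps = 10)   # 120 s
  v <- make_vehicle(1200, fps = 10)
  expect_equal(nrow(extract_features(f, v)), 2)
  expect_equal(nrow(extract_features(make_facial(590), make_vehicle(590))), 0)
  expect_error(extract_features(make_facial(100), make_vehicle(100, t0 = 1000)),
               class = "drowsefuse_invalid_input")
})

test_that("windowed features equal per-definition recomputation on random streams", {
  set.seed(13)
  cfg <- feature_config()
  for (rep in 1:30) {
    n <- 600
    f <- make_facial(n, fps = 10)
    f$eye_closed <- stats::runif(n) < 0.15
    f$eyelid_h <- stats::runif(n, 5, 15)
    f$mouth_h <- stats::runif(n, 5, 45)
    v <- make_vehicle(n, fps = 10)
    v$steer_angle <- cumsum(stats::rnorm(n))
    v$steer_rate <- stats::rnorm(n, 0, 0.3)
    v$theta_l <- pi / 2 - stats::runif(n, 0.05, 0.4)
    v$theta_r <- pi / 2 + 0.2
    v$speed <- stats::rnorm(n, 100, 5)
    fw <- extract_features(f, v, cfg)
    expect_equal(nrow(fw), 1)
    # independent recomputation straight from the definitions
    expect_equal(fw$bf, mean(f$eye_closed))
    runs <- rle(f$eye_closed)
    expect_equal(fw$ecd,
                 sum(runs$lengths[runs$values & runs$lengths >= 20]) / n)
    expect_gte(fw$bf, fw$ecd)
    expect_equal(fw$meol, mean(f$eyelid_h))
    expect_equal(fw$yf, mean(f$mouth_h / f$mouth_w >= cfg$t_m))
    sub <- v[v$t >= 50, ]
    expect_equal(fw$pns, mean(abs(sub$steer_rate) <= 0.1))
    expect_equal(fw$sdsa,
                 sqrt(mean((sub$steer_angle - mean(sub$steer_angle))^2)))
    xi <- (pi / 2 - v$theta_l) / (v$theta_r - pi / 2)
    expect_equal(fw$fald, mean(xi > 1.2 | xi < 1 / 1.2))
    expect_equal(fw$sdvs, sqrt(mean((sub$speed - mean(sub$speed))^2)))
    # every fraction-valued feature is a proper fraction
    expect_true(all(unlist(fw[c("bf", "ecd", "yf", "pns", "fald")]) >= 0))
    expect_true(all(unlist(fw[c("bf", "ecd", "yf", "pns", "fald")]) <= 1))
  }
})
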