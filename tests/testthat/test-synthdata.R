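test_that("haversine matches closed forms and rejects bad coordinates", {
  expect_equal(haversine_km(49.33, 119.95, 49.33, 119.95), 0)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371.393, tolerance = 1e-12)
  # small-angle arc length r * dphi
  expect_equal(haversine_km(0, 0, 1e-4, 0),
               6371.393 * 1e-4 * pi / 180, tolerance = 1e-9)
  expect_error(haversine_km(NA, 0, 0, 0), "non-finite")
  expect_error(haversine_km(95, 0, 0, 0), "out of range")
})

test_that("haversine is symmetric, triangle-inequal, and agrees with geosphere", {
  set.seed(7)
  n <- 300
  lat <- matrix(runif(3 * n, -90, 90), ncol = 3)
  lon <- matrix(runif(3 * n, -180, 180), ncol = 3)
  d12 <- haversine_km(lat[, 1], lon[, 1], lat[, 2], lon[, 2])
  d21 <- haversine_km(lat[, 2], lon[, 2], lat[, 1], lon[, 1])
  expect_equal(d12, d21, tolerance = 1e-12)
  d13 <- haversine_km(lat[, 1], lon[, 1], lat[, 3], lon[, 3])
  d23 <- haversine_km(lat[, 2], lon[, 2], lat[, 3], lon[, 3])
  expect_true(all(d13 <= d12 + d23 + 1e-9 * pmax(d13, 1)))
  skip_if_not_installed("geosphere")
  ref <- geosphere::distHaversine(cbind(lon[, 1], lat[, 1]),
                                  cbind(lon[, 2], lat[, 2]),
                                  r = 6371.393)
  expect_equal(d12, ref, tolerance = 1e-9)
})

test_that("assemble_frame averages IMU samples and appends displacement", {
  fix <- gps_fix(49.33, 119.95, 0)
  w <- sensor_window(matrix(2.5, 10, 9), fix, gps_fix(49.33, 119.95, 10))
  fr <- assemble_frame(w)
  expect_length(fr, 10)
  expect_equal(unname(fr), c(rep(2.5, 9), 0))
  # alternating +1/-1 averages to zero
  imu <- matrix(0, 10, 9); imu[, 4] <- rep(c(1, -1), 5)
  fr2 <- assemble_frame(sensor_window(imu, fix, gps_fix(49.33, 119.95, 10)))
  expect_equal(unname(fr2[4]), 0)
  # random window: means equal brute-force sums, displacement equals the
  # haversine of the two fixes
  set.seed(3)
  imu <- matrix(rnorm(90), 10, 9)
  f2 <- gps_fix(49.331, 119.951, 10)
  fr3 <- assemble_frame(sensor_window(imu, fix, f2))
  expect_equal(unname(fr3[1:9]), apply(imu, 2, function(v) sum(v) / 10))
  expect_equal(unname(fr3[10]),
               haversine_km(49.33, 119.95, 49.331, 119.951))
  expect_error(assemble_frame(sensor_window(matrix(0, 0, 9), fix, f2)),
               "no IMU samples")
})

test_that("generator emits the configured classes deterministically", {
  cfg <- generator_config(n_per_class = c(5, 0, 0, 0), seed = 9)
  ds <- generate_synthetic_herd(cfg)
  expect_equal(nrow(ds$frames), 5)
  expect_true(all(ds$frames$label == 0))
  cfg2 <- generator_config(n_per_class = c(30, 20, 25, 10), seed = 42)
  a <- generate_synthetic_herd(cfg2)
  b <- generate_synthetic_herd(cfg2)
  expect_identical(a$frames, b$frames)
  expect_equal(unname(class_counts(a)), c(30, 20, 25, 10))
  expect_error(generator_config(n_per_class = c(0, 0, 0, 0)), "zero")
})

test_that("a displacement-only stump separates walking; class means converge", {
  ds <- generate_synthetic_herd(generator_config(seed = 500))
  walking <- ds$frames$label == 3
  # best single displacement threshold found by brute force on the draws
  thr <- seq(0.004, 0.012, by = 0.0005)
  sens <- vapply(thr, function(t)
    sum(ds$frames$d > t & walking) / sum(walking), 0)
  spec_ <- vapply(thr, function(t)
    sum(ds$frames$d <= t & !walking) / sum(!walking), 0)
  best <- which.max(sens + spec_)
  expect_gt(sens[best], 0.95)
  expect_gt(spec_[best], 0.95)
  # empirical IMU means converge to the configured means (3 sigma at n = 5000)
  cfg <- generator_config(n_per_class = c(5000, 0, 0, 0), seed = 77)
  big <- generate_synthetic_herd(cfg)
  em <- cfg$classes$Grazing
  tot_sd <- sqrt(em$between_sd^2 + em$within_sd^2 / cfg$window_s)
  dev <- abs(colMeans(feature_matrix(big))[1:9] - em$imu_mean)
  expect_true(all(dev < 3 * tot_sd / sqrt(5000)))
})

test_that("frames and GPS CSV round-trip and validate", {
  ds <- generate_synthetic_herd(
    generator_config(n_per_class = c(8, 5, 4, 3), seed = 2))
  f <- tempfile(fileext = ".csv")
  write_frames_csv(ds, f)
  back <- read_frames_csv(f, class_names = ds$class_names)
  expect_equal(back$frames, ds$frames, tolerance = 1e-12)
  expect_identical(readLines(f, 1), "ax,ay,az,gx,gy,gz,mx,my,mz,d,label")
  g <- tempfile(fileext = ".csv")
  writeLines(c("t,lat,lon", "0,49.3,119.9", "10,49.31,119.91"), g)
  gps <- read_gps_csv(g)
  expect_equal(nrow(gps), 2)
  writeLines(c("t,lat,lon", "0,99,0"), g)
  expect_error(read_gps_csv(g), "out of range")
})

test_that("generator config round-trips through YAML with validation", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("n_per_class: [10, 10, 5, 5]", "scheme: 4", "seed: 3"), f)
  cfg <- read_generator_config(f)
  expect_equal(cfg$n_per_class, c(10L, 10L, 5L, 5L))
  writeLines(c("n_per_klass: [1, 2]"), f)
  expect_error(read_generator_config(f), "unknown generator config key")
})
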