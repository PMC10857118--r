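test_that("find_local_extrema: analytic sine maxima, plateaus, constants", {
  x <- sin(2 * pi * (0:999) / 100)
  expect_identical(find_local_extrema(x, "max", 50),
                   as.integer(seq(26, 926, by = 100)))
  expect_identical(find_local_extrema(rep(1, 100), "max"), integer(0))
  ## plateau counts once, at its first sample
  expect_identical(find_local_extrema(c(0, 1, 1, 1, 0), "max"), 2L)
  expect_identical(find_local_extrema(c(0, -1, -1, 0), "min"), 2L)
})

test_that("find_local_extrema separation pruning matches a brute-force oracle", {
  ## two close maxima: only the larger survives
  x <- rep(0, 60)
  x[20] <- 1
  x[30] <- 2
  expect_identical(find_local_extrema(x, "max", 30), 30L)
  set.seed(7)
  for (rep in 1:20) {
    y <- rnorm(80)
    for (mode in c("min", "max")) {
      got <- find_local_extrema(y, mode, 12)
      expect_identical(got, brute_extrema(y, mode, 12))
      if (length(got) > 1) expect_true(all(diff(got) >= 12))
    }
  }
})

test_that("detect_to finds the sub-threshold pitch-rate minima", {
  sim <- sim_noiseless(seed = 4)
  rec <- sim$recording
  to <- detect_to(rec$gyro_pitch, -0.5, min_separation = 30)
  ## one trough per stride plus the lead-in's virtual trough
  expect_length(to, sim$spec$n_strides + 1L)
  expect_lte(max(abs((to[-1] - 1) / 100 - sim$truth$to)), 0.02)
  expect_identical(detect_to(rep(0, 100), -0.5), integer(0))
  expect_identical(detect_to(rec$gyro_pitch, -10), integer(0))
  expect_error(detect_to(rec$gyro_pitch, 0.5), "negative")
})

test_that("ic_windows bracket each initial contact", {
  ## pure two-per-stride cosine over 3 strides of 1.2 s
  t <- (0:359) / 100
  az <- cos(4 * pi * t / 1.2)
  w <- ic_windows(az, 20)
  expect_true(nrow(w) >= 4)
  expect_true(all(w[, "start"] < w[, "end"]))
  for (t_ic in c(1.2, 2.4)) { # interior ICs
    i_ic <- round(t_ic * 100) + 1
    expect_equal(sum(w[, "start"] <= i_ic & i_ic < w[, "end"]), 1)
  }
  expect_identical(nrow(ic_windows(seq_len(100))), 0L)
})

test_that("detect_ic branch logic", {
  n <- 100
  acc_z <- rep(0, n)
  acc_z[33:37] <- c(1, 2, 3, 2, 1)   # peak 3.0 at 35
  acc_z[43:47] <- c(1, 2, 4, 2, 1)   # peak 4.0 at 45
  ## branch A: AccX gate at 40 -> earliest supra-threshold peak at/after 40
  acc_x <- rep(0, n)
  acc_x[40] <- 2
  got <- detect_ic(acc_x, acc_z, c(1L, 101L), th_acc_x = 1, th_acc_z = 1)
  expect_identical(as.integer(got), 45L)
  expect_identical(attr(got, "branch"), "A")
  ## branch B: no gate -> largest supra-threshold peak
  got <- detect_ic(rep(0, n), acc_z, c(1L, 101L), 1, 1)
  expect_identical(as.integer(got), 45L)
  expect_identical(attr(got, "branch"), "B")
  got <- detect_ic(rep(0, n), acc_z, c(1L, 101L), 1, 3.5)
  expect_identical(as.integer(got), 45L)
  ## flat signals: absent, not an error
  expect_true(is.na(detect_ic(rep(0, n), rep(0, n), c(1L, 101L), 1, 1)))
  expect_error(detect_ic(acc_x, acc_z, c(10L, 10L), 1, 1), "non-empty")
})

test_that("detect_oto takes the first peak; detect_oic the first descending zero", {
  x <- rep(0, 100)
  x[20] <- 1
  x[40] <- 2
  expect_identical(detect_oto(x, 1L, 5L, 90L), 20L)
  expect_true(is.na(detect_oto(seq(100, 1), 1L, 5L, 90L)))
  expect_error(detect_oto(x, 50L, 60L, 90L), "precede")
  gy <- sin(2 * pi * (0:199) / 100)
  oic <- detect_oic(gy, 11L, 150L)
  expect_equal((oic - 1) / 100, 0.5, tolerance = 0.015 / 0.5)
  expect_true(is.na(detect_oic(rep(1, 100), 11L, 90L)))
  expect_error(detect_oic(gy, 90L, 90L), "precede")
})

test_that("detect_events recovers all interior events on noiseless gait", {
  sim <- sim_noiseless(seed = 5)
  cyc <- detect_events(sim$recording)
  expect_s3_class(cyc, "gait_cycles")
  expect_identical(nrow(cyc), sim$spec$n_strides)
  expect_true(all(cyc$valid))
  m <- match_events(interior_events(cyc), sim$truth, tolerance = 0.05)
  expect_identical(nrow(m$spurious), 0L)
  ## every interior event within 2 samples of ground truth
  expect_lte(max(abs(m$pairs$error_s)), 0.02 + 1e-9)
  ## determinism
  expect_identical(detect_events(sim$recording), cyc)
})

test_that("every valid cycle is strictly ordered, across seeds and noise", {
  for (seed in 1:3) {
    for (nf in list(NULL, 0.1)) {
      sim <- simulate_gait(simulation_spec(n_strides = 10, seed = seed,
                                           noise_frac = nf))
      cyc <- detect_events(sim$recording)
      v <- cyc[cyc$valid, ]
      expect_true(all(v$ic < v$oto & v$oto < v$oic & v$oic < v$to &
                        v$to < v$next_ic))
    }
  }
})

test_that("periodic gait yields equally spaced initial contacts", {
  sim <- sim_noiseless(seed = 6, n_strides = 12, stride_sd = 0)
  cyc <- detect_events(sim$recording)
  spacing <- diff(cyc$ic[!cyc$edge])
  expect_true(all(abs(spacing - 120) <= 1))
})

test_that("white noise produces no valid cycles", {
  set.seed(99)
  mk <- function() rnorm(3000, 0, 0.3)
  rec <- imu_recording(mk(), mk(), mk(), mk(), mk(), mk(),
                       sample_rate = 100)
  cyc <- detect_events(rec)
  expect_identical(sum(cyc$valid), 0L)
})

test_that("too-short recordings are rejected", {
  sim <- sim_noiseless(seed = 7, n_strides = 20)
  short <- with(sim$recording, imu_recording(
    acc_ap[1:300], acc_ml[1:300], acc_v[1:300], gyro_roll[1:300],
    gyro_pitch[1:300], gyro_yaw[1:300], sample_rate = 100))
  expect_error(detect_events(short, detection_config(main_freq = 1.667)),
               "3 estimated strides")
})
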