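test_that("generate_timeline places events at exact phases when sd = 0", {
  spec <- simulation_spec(n_strides = 5, stride_mean = 1.0, stride_sd = 0,
                          seed = 1)
  tl <- generate_timeline(spec)
  expect_equal(tl$ic, 0:5, tolerance = 1e-12)
  expect_equal(tl$oto, 0:4 + 0.12, tolerance = 1e-12)
  expect_equal(tl$oic, 0:4 + 0.50, tolerance = 1e-12)
  expect_equal(tl$to, 0:4 + 0.62, tolerance = 1e-12)
  ## asymmetry shifts the opposite-initial-contact phase exactly
  tl2 <- generate_timeline(simulation_spec(n_strides = 5, stride_mean = 1,
                                           stride_sd = 0,
                                           asymmetry_shift = -0.03,
                                           seed = 1))
  expect_equal(tl2$oic, 0:4 + 0.47, tolerance = 1e-12)
})

test_that("timelines are seeded and truncated at half the mean stride", {
  spec <- simulation_spec(n_strides = 30, stride_mean = 1, stride_sd = 0.6,
                          seed = 5)
  t1 <- generate_timeline(spec)
  t2 <- generate_timeline(spec)
  expect_identical(t1$ic, t2$ic)
  expect_true(all(diff(t1$ic) >= 0.5))
})

test_that("noiseless gyro morphology anchors every detector rule", {
  for (seed in 1:3) {
    spec <- simulation_spec(n_strides = 8, seed = seed,
                            oto_phase = c(0.10, 0.12, 0.15)[seed],
                            oic_phase = c(0.45, 0.50, 0.52)[seed],
                            to_phase = c(0.60, 0.62, 0.66)[seed],
                            gyro_amp = c(1.5, 2, 3)[seed])
    sim <- simulate_gait(spec)
    g <- sim$recording$gyro_pitch
    fs <- spec$sample_rate
    tr <- sim$truth
    for (k in seq_len(spec$n_strides)) {
      i0 <- round(tr$ic[k] * fs) + 1
      i1 <- round(tr$ic[k + 1] * fs) + 1
      seg <- i0:i1
      ## unique minimum at toe off, within 1 sample
      expect_lte(abs((seg[which.min(g[seg])] - 1) / fs - tr$to[k]),
                 1 / fs + 1e-9)
      ## local max at opposite toe off
      expect_lte(abs((seg[which.max(g[seg])] - 1) / fs - tr$oto[k]),
                 1 / fs + 1e-9)
      ## unique descending zero at opposite initial contact
      z <- seg[-1][g[seg[-1] - 1] > 0 & g[seg[-1]] <= 0]
      expect_length(z, 1L)
      expect_lte(abs((z - 1) / fs - tr$oic[k]), 1 / fs + 1e-9)
    }
  }
})

test_that("gyro_amp = 0 silences the pitch channel", {
  sim <- simulate_gait(simulation_spec(n_strides = 4, gyro_amp = 0,
                                       seed = 2))
  expect_true(all(sim$recording$gyro_pitch == 0))
})

test_that("vertical acceleration is dominated by the step frequency", {
  spec <- simulation_spec(n_strides = 25, seed = 8)
  sim <- simulate_gait(spec)
  f <- estimate_main_frequency(sim$recording$acc_v, spec$sample_rate)
  expect_equal(f, 2 / spec$stride_mean, tolerance = 0.05 / 1.667)
})

test_that("impact pulses place the acceleration maximum at initial contact", {
  spec <- simulation_spec(n_strides = 8, seed = 9)
  sim <- simulate_gait(spec)
  fs <- spec$sample_rate
  az <- sim$recording$acc_v
  for (k in 2:(spec$n_strides - 1)) {
    ic <- sim$truth$ic[k]
    near <- round((ic + c(-0.3, 0.3)) * fs) + 1
    seg <- near[1]:near[2]
    t_max <- (seg[which.max(az[seg])] - 1) / fs
    expect_lte(abs(t_max - ic), spec$impact_width + 1e-9)
  }
  ## without pulses the signal is the pure two-per-stride oscillation
  pure <- simulate_gait(simulation_spec(n_strides = 8, impact_amp_ic = 0,
                                        impact_amp_oic = 0, seed = 9))
  expect_lte(max(abs(pure$recording$acc_v)), pure$spec$accz_amp + 1e-9)
})

test_that("simulation is reproducible and seed-dependent only in noise", {
  spec <- simulation_spec(n_strides = 6, stride_sd = 0, noise_frac = 0.1,
                          seed = 42)
  a <- simulate_gait(spec)
  b <- simulate_gait(spec)
  expect_identical(a$recording$acc_v, b$recording$acc_v)
  expect_identical(a$recording$gyro_pitch, b$recording$gyro_pitch)
  ## different seed, same deterministic component (sd = 0, no noise)
  c1 <- simulate_gait(simulation_spec(n_strides = 6, stride_sd = 0,
                                      seed = 1))
  c2 <- simulate_gait(simulation_spec(n_strides = 6, stride_sd = 0,
                                      seed = 2))
  expect_identical(c1$recording$acc_v, c2$recording$acc_v)
  ## noise realisations differ across seeds
  n1 <- simulate_gait(simulation_spec(n_strides = 6, stride_sd = 0,
                                      noise_frac = 0.1, seed = 1))
  n2 <- simulate_gait(simulation_spec(n_strides = 6, stride_sd = 0,
                                      noise_frac = 0.1, seed = 2))
  expect_false(identical(n1$recording$acc_v, n2$recording$acc_v))
})

test_that("noise_frac scales with the noiseless signal RMS", {
  sim <- simulate_gait(simulation_spec(n_strides = 20, noise_frac = 0.1,
                                       seed = 3))
  clean <- simulate_gait(simulation_spec(n_strides = 20, seed = 3))
  expect_equal(unname(sim$noise_sd["acc"]),
               0.1 * sqrt(mean(clean$recording$acc_v^2)), tolerance = 1e-9)
  resid <- sim$recording$acc_ml      # noise-only channel
  expect_equal(stats::sd(resid), sim$noise_sd[["acc"]], tolerance = 0.1)
})

test_that("spec validation rejects inconsistent phases", {
  expect_error(simulation_spec(oto_phase = 0.6, to_phase = 0.5), "phase")
  expect_error(simulation_spec(oic_phase = 0.5, asymmetry_shift = 0.2,
                               to_phase = 0.62), "phase")
  expect_error(simulation_spec(stride_mean = -1), "stride")
})

test_that("a short simulation still carries a full stride of truth", {
  sim <- simulate_gait(simulation_spec(n_strides = 1, stride_sd = 0,
                                       seed = 4))
  expect_length(sim$truth$ic, 2L)
  expect_length(sim$truth$to, 1L)
  expect_gte(sim$recording$n_samples,
             sim$spec$stride_mean * sim$spec$sample_rate)
})
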