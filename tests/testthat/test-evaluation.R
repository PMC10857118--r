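## a deterministic 5-stride reference, 1 s cycles
ref5 <- function(cycle = 1.0) {
  n <- 5
  ics <- (0:n) * cycle
  ground_truth(ic = ics, oto = ics[1:n] + 0.12 * cycle,
               oic = ics[1:n] + 0.50 * cycle,
               to = ics[1:n] + 0.62 * cycle)
}

test_that("identical event lists match perfectly with zero error", {
  r <- ref5()
  m <- match_events(truth_events(r), r)
  expect_identical(nrow(m$missed), 0L)
  expect_identical(nrow(m$spurious), 0L)
  expect_identical(nrow(m$pairs), 21L)
  expect_true(all(m$pairs$error_s == 0))
})

test_that("a uniform +30 ms shift matches everywhere with +30 ms error", {
  r <- ref5()
  det <- truth_events(r)
  det$time_s <- det$time_s + 0.03
  m <- match_events(det, r, tolerance = 0.5)
  expect_identical(nrow(m$missed), 0L)
  expect_equal(m$pairs$error_s, rep(0.03, nrow(m$pairs)), tolerance = 1e-9)
})

test_that("an extra event is spurious and leaves other matches unchanged", {
  r <- ref5()
  det <- truth_events(r)
  m0 <- match_events(det, r, tolerance = 0.1)
  det2 <- rbind(det, data.frame(event = "IC", time_s = 2.5))
  m1 <- match_events(det2, r, tolerance = 0.1)
  expect_identical(nrow(m1$spurious), 1L)
  expect_equal(m1$spurious$time_s, 2.5)
  expect_identical(m0$pairs, m1$pairs)
})

test_that("matching is invariant to a global time translation", {
  r <- ref5()
  det <- truth_events(r)
  det$time_s <- det$time_s + 0.013
  m0 <- match_events(det, r, tolerance = 0.1)
  r2 <- ground_truth(r$ic + 100, r$oto + 100, r$oic + 100, r$to + 100)
  det2 <- det
  det2$time_s <- det2$time_s + 100
  m1 <- match_events(det2, r2, tolerance = 0.1)
  expect_equal(m1$pairs$error_s, m0$pairs$error_s, tolerance = 1e-9)
})

test_that("matched + missed accounts for every reference event", {
  set.seed(31)
  sim <- simulate_gait(canonical_noisy_spec(31))
  m <- match_events(detect_events(sim$recording), sim$truth,
                    tolerance = 0.05)
  for (kind in c("IC", "OTO", "OIC", "TO")) {
    n_ref <- length(sim$truth[[tolower(kind)]])
    expect_identical(nrow(m$pairs[m$pairs$event == kind, ]) +
                       nrow(m$missed[m$missed$event == kind, ]),
                     n_ref)
  }
})

test_that("event_errors computes Eq-style errors and rates", {
  ## 10 ms late on a 1 s cycle -> +10 ms, +1 %GC
  r <- ref5()
  det <- data.frame(event = "IC", time_s = 1.01)
  rep1 <- event_errors(match_events(det, r, tolerance = 0.4), r)
  ic <- rep1$summary[rep1$summary$event == "IC", ]
  expect_equal(ic$mean_ms, 10, tolerance = 1e-6)
  expect_equal(ic$mean_pct_gc, 1.0, tolerance = 1e-6)
  ## 28 ms early on a 1.4 s cycle -> -28 ms, -2 %GC (2.8 frames @ 100 Hz)
  r14 <- ref5(cycle = 1.4)
  det <- data.frame(event = "TO", time_s = 0.62 * 1.4 - 0.028)
  rep2 <- event_errors(match_events(det, r14, tolerance = 0.4), r14)
  to <- rep2$summary[rep2$summary$event == "TO", ]
  expect_equal(to$mean_ms, -28, tolerance = 1e-6)
  expect_equal(to$mean_pct_gc, -2.0, tolerance = 1e-6)
})

test_that("the error rate is inversely proportional to cycle duration", {
  for (cycle in c(1.0, 2.0)) {
    r <- ref5(cycle)
    det <- data.frame(event = "IC", time_s = cycle + 0.01)
    rp <- event_errors(match_events(det, r, tolerance = 0.4), r)
    got <- rp$summary$mean_pct_gc[rp$summary$event == "IC"]
    expect_equal(got, 1.0 / cycle, tolerance = 1e-6)
  }
})

test_that("3x IQR outliers are flagged", {
  r <- ref5()
  off <- 1 / 1024                       # binary-exact small offset
  det <- data.frame(event = "IC", time_s = r$ic[1:5] + c(rep(off, 4), 0.1))
  rp <- event_errors(match_events(det, r, tolerance = 0.4), r)
  expect_identical(which(rp$pairs$outlier), 5L)
  expect_identical(rp$summary$n_outliers[rp$summary$event == "IC"], 1L)
})

test_that("parameter_errors is calculated minus measured", {
  calc <- cycle_parameters(0, 0.118, 0.50, 0.616, 1.0)
  meas <- cycle_parameters(0, 0.120, 0.50, 0.630, 1.0)
  pe <- parameter_errors(calc, meas)
  expect_equal(pe$summary$mean[pe$summary$parameter == "stance_pct"],
               61.6 - 63.0, tolerance = 1e-9)
  ## identical tables -> all-zero errors
  pe0 <- parameter_errors(meas, meas)
  expect_true(all(pe0$summary$mean == 0))
  expect_true(all(pe0$summary$sd == 0))
  ## misaligned tables are refused
  two <- rbind(meas, meas)
  expect_error(parameter_errors(calc, two), "misaligned")
})

test_that("error_rate_frames reproduces the frame-bound arithmetic", {
  expect_equal(error_rate_frames(2, 1.4, 100), 2.8)
  expect_equal(error_rate_frames(1, 1.4, 100), 1.4)
})

test_that("ground_truth validates ordering", {
  expect_error(ground_truth(c(0, 1, 0.5), c(0.1, 1.1), c(0.5, 1.5),
                            c(0.6, 1.6)), "ascending")
})
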