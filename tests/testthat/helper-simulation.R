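## shared fixtures: everything is generated in code, nothing on disk

sim_noiseless <- function(seed = 1, n_strides = 20, stride_sd = 0.05, ...) {
  simulate_gait(simulation_spec(n_strides = n_strides,
                                stride_sd = stride_sd, seed = seed, ...))
}

## the canonical noisy regime: 50 strides of 1.2 +/- 0.05 s with white
## noise at 10% of the noiseless signal RMS
canonical_noisy_spec <- function(seed) {
  simulation_spec(n_strides = 50, stride_mean = 1.2, stride_sd = 0.05,
                  noise_frac = 0.1, seed = seed)
}

## detected events of valid interior cycles as a plain event table
interior_events <- function(cycles) {
  e <- events_long(cycles, only_valid = TRUE, include_edge = FALSE)
  data.frame(event = e$event, time_s = e$time_s)
}

truth_events <- function(truth) {
  data.frame(
    event = rep(c("IC", "OTO", "OIC", "TO"),
                c(length(truth$ic), length(truth$oto),
                  length(truth$oic), length(truth$to))),
    time_s = c(truth$ic, truth$oto, truth$oic, truth$to))
}

## O(n^2) reference implementation of the extremum rules, used as an
## independent oracle for find_local_extrema
brute_extrema <- function(x, mode, sep) {
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1L
    if (j < n) {
      up <- x[i] > x[i - 1] && x[i] > x[j + 1]
      dn <- x[i] < x[i - 1] && x[i] < x[j + 1]
      if ((mode == "max" && up) || (mode == "min" && dn))
        cand <- c(cand, i)
    }
    i <- j + 1L
  }
  keep <- integer(0)
  ord <- order(if (mode == "max") -x[cand] else x[cand], cand)
  for (j in ord) {
    if (!length(keep) || all(abs(cand[j] - keep) >= sep))
      keep <- c(keep, cand[j])
  }
  sort(keep)
}
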