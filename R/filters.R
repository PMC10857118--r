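## IIR filter design and zero-phase application.
##
## No signal-processing package is assumed: the second-order Butterworth
## designs used here (low-pass and band-pass via the standard analog
## prototype -> frequency transform -> bilinear transform route) are small
## enough to carry directly, and the implementation is validated against
## an independent frequency-response oracle in the test suite.

## polynomial coefficients (descending powers) from complex roots
poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

## digital Butterworth design; returns list(b, a).
## `type = "bandpass"` with prototype order 2 yields a 4th-order filter,
## the usual meaning of "second-order Butterworth band-pass".
butter_design <- function(order, sample_rate, low = NULL, high = NULL,
                          type = c("low", "bandpass")) {
  type <- match.arg(type)
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # LHP prototype poles
  warp <- function(f) 2 * sample_rate * tan(pi * f / sample_rate)
  if (type == "low") {
    wc <- warp(high)
    p <- p * wc
    z <- complex(0)
    gain <- wc^order
  } else {
    w1 <- warp(low)
    w2 <- warp(high)
    bw <- w2 - w1
    w0 <- sqrt(w1 * w2)
    a <- p * bw / 2
    p <- c(a + sqrt(a^2 - w0^2), a - sqrt(a^2 - w0^2))
    z <- rep(0 + 0i, order)
    gain <- bw^order
  }
  fs2 <- 2 * sample_rate
  gain_d <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  list(b = Re(poly_from_roots(zd)) * gain_d,
       a = Re(poly_from_roots(pd)))
}

## direct-form II transposed single-pass filter
lfilter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2)
      for (j in 1:(n - 2)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

## steady-state DF2T state for a unit-step input; scaled by the first
## sample it suppresses the start-up transient of each pass
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  A <- diag(n - 1)
  for (i in seq_len(n - 1)) A[i, 1] <- A[i, 1] + a[i + 1]
  if (n > 2) for (i in 1:(n - 2)) A[i, i + 1] <- A[i, i + 1] - 1
  solve(A, b[-1] - a[-1] * b[1])
}

## forward-backward (zero-phase) filtering with odd extension at the ends;
## default pad of 3x the filter order matches common practice
filtfilt <- function(b, a, x,
                     padlen = 3 * (max(length(a), length(b)) - 1)) {
  nx <- length(x)
  padlen <- min(padlen, nx - 1)
  ext <- if (padlen > 0) {
    c(2 * x[1] - x[(padlen + 1):2], x,
      2 * x[nx] - x[(nx - 1):(nx - padlen)])
  } else x
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  if (padlen > 0) y[(padlen + 1):(padlen + nx)] else y
}
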