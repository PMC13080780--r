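# Zero-phase application of symmetric (linear-phase) FIR kernels.
#
# A symmetric FIR has a pure linear phase; applying it once and removing the
# (L-1)/2-sample group delay is an exact zero-phase filter at half the cost
# of forward-backward filtering. Edges are reflection-padded to suppress
# transients.

fir_zerophase <- function(h, x) {
  h <- as.numeric(unclass(h))
  L <- length(h)
  d <- (L - 1) %/% 2
  n <- length(x)
  pad <- min(L, n - 1)
  # mirror-reflect the edges (without repeating the edge sample)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  m <- stats::nextn(length(xp) + L - 1)  # FFT-friendly length
  X <- stats::fft(c(xp, numeric(m - length(xp))))
  H <- stats::fft(c(h, numeric(m - L)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / m
  y[(pad + d + 1):(pad + d + n)]
}

# Mean and SD over the first dimension of a trials x channels x samples
# array, without apply() overhead. Returns list(mean, sd) of ch x samp.
trialwise_stats <- function(d) {
  n <- dim(d)[1]
  m <- colMeans(d)
  if (n >= 2) {
    ss <- colSums(d^2)
    v <- (ss - n * m^2) / (n - 1)
    v[v < 0] <- 0
    list(mean = m, sd = sqrt(v), n = n)
  } else {
    list(mean = m, sd = matrix(0, dim(d)[2], dim(d)[3]), n = n)
  }
}
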