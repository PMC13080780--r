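# Minimal periodized Haar discrete wavelet transform used by the motion
# despiking step (no wavelet library ships with the R dependency set).

haar_dwt <- function(x, levels) {
  n <- length(x)
  stopifnot(n %% 2^levels == 0)
  details <- vector("list", levels)
  approx <- x
  for (j in seq_len(levels)) {
    even <- approx[seq(2, length(approx), by = 2)]
    odd <- approx[seq(1, length(approx), by = 2)]
    details[[j]] <- (odd - even) / sqrt(2)
    approx <- (odd + even) / sqrt(2)
  }
  list(approx = approx, details = details)
}

haar_idwt <- function(w) {
  approx <- w$approx
  for (j in rev(seq_along(w$details))) {
    d <- w$details[[j]]
    odd <- (approx + d) / sqrt(2)
    even <- (approx - d) / sqrt(2)
    out <- numeric(2 * length(approx))
    out[seq(1, length(out), by = 2)] <- odd
    out[seq(2, length(out), by = 2)] <- even
    approx <- out
  }
  approx
}

# Zero detail coefficients outside the Tukey fences (k * IQR beyond the
# quartiles) at every level, then reconstruct. Pads symmetrically to a
# multiple of 2^levels.
wavelet_despike <- function(x, levels = 4, k = 1.5) {
  n <- length(x)
  block <- 2^levels
  pad <- (block - n %% block) %% block
  xp <- if (pad) c(x, rev(x)[seq_len(pad)]) else x
  w <- haar_dwt(xp, levels)
  for (j in seq_len(levels)) {
    d <- w$details[[j]]
    q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    out_of_fence <- d < q[1] - k * iqr | d > q[2] + k * iqr
    d[out_of_fence] <- 0
    w$details[[j]] <- d
  }
  haar_idwt(w)[seq_len(n)]
}
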