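#' @keywords internal
"_PACKAGE"

# Internal validation helpers -------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, positive = FALSE, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a finite numeric scalar")
  if (positive && x <= 0) stop_field(field, "must be > 0")
  if (x < min) stop_field(field, sprintf("must be >= %s", min))
  if (x > max) stop_field(field, sprintf("must be <= %s", max))
  invisible(x)
}

#' Derive a child RNG seed from a master seed
#'
#' A single master seed fans out to per-participant (or per-purpose) child
#' seeds by a fixed affine rule modulo 2^31 - 1, so any participant of a
#' cohort can be regenerated in isolation.
#'
#' @param master_seed Integer master seed.
#' @param index Non-negative integer stream index (participant number, etc.).
#' @return An integer seed strictly below 2^31.
#' @export
child_seed <- function(master_seed, index) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- (as.numeric(master_seed) %% m) * 48271 + as.numeric(index) * 16807 + 1
  as.integer(s %% m)
}

# Moment-matched lognormal parameters for a target mean/sd on the natural scale
lognormal_params <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# Pointwise SEM across the rows of a matrix (participants/trials x samples)
col_sem <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(NA_real_, ncol(m)))
  apply(m, 2L, stats::sd) / sqrt(n)
}
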