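#' Power of the stimulus-modulation F-test at a given SNR
#'
#' The one-way F-statistic for detecting any variation in expected response
#' across m stimuli with n repeats,
#' \deqn{F = \frac{\frac{n}{m-1}\sum_i(\bar Y_{i\cdot}-\bar Y)^2}
#'   {\frac{1}{n(m-1)}\cdot\frac{n}{m}\sum_i\sum_j(Y_{ij}-\bar Y_{i\cdot})^2},}
#' follows a noncentral F distribution with (m - 1, m(n - 1)) degrees of
#' freedom and noncentrality \eqn{m\,n\,SNR}.  Power is the upper-tail
#' probability of that distribution at the central-F critical value of a
#' level-`alpha` test.  At `snr = 0` the power equals `alpha` exactly.
#'
#' @param snr Nonnegative signal-to-noise ratio (dynamic range over
#'   trial-to-trial variance).
#' @param m Number of stimuli (>= 2).
#' @param n Number of repeats (>= 2).
#' @param alpha Test level, default 0.01.
#' @return Power in \[0, 1\]; vectorized over `snr`.
#' @export
f_test_power <- function(snr, m, n, alpha = 0.01) {
  stopifnot(m >= 2, n >= 2, alpha > 0, alpha < 1, all(snr >= 0))
  df1 <- m - 1
  df2 <- m * (n - 1)
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = m * n * snr, lower.tail = FALSE)
}

#' Minimal SNR for reliable detection of tuning
#'
#' Solves `f_test_power(snr, m, n, alpha) = beta` for the smallest SNR at
#' which a level-`alpha` F-test for stimulus modulation reaches power
#' `beta`.  Power is strictly increasing in SNR, so the root is unique; it
#' is found by bracketed root-finding on \[1e-6, 1e3\] with bracket
#' expansion if needed.  With the defaults (alpha = 0.01, beta = 0.99) this
#' gives the SNR a recording must exceed before its tuning curve can be
#' considered reliably measurable for the given design.
#'
#' @param m Number of stimuli.
#' @param n Number of repeats.
#' @param alpha Test level, default 0.01.
#' @param beta Target power, default 0.99.
#' @return The minimal SNR (scalar).
#' @examples
#' min_snr_for_power(m = 8, n = 10)   # about 0.5
#' min_snr_for_power(m = 350, n = 5)  # about 0.1
#' @export
min_snr_for_power <- function(m, n, alpha = 0.01, beta = 0.99) {
  stopifnot(beta > alpha, beta < 1)
  f <- function(s) f_test_power(s, m, n, alpha) - beta
  lo <- 1e-6; hi <- 1e3
  while (f(hi) < 0 && hi < 1e9) hi <- hi * 10
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Map of minimal SNR over a grid of experimental designs
#'
#' Element-wise [min_snr_for_power()] over all combinations of stimulus
#' counts and repeat counts, for planning how to split a trial budget
#' between more stimuli and more repeats.
#'
#' @param m_grid Integer vector of stimulus counts (>= 2).
#' @param n_grid Integer vector of repeat counts (>= 2).
#' @inheritParams min_snr_for_power
#' @return Numeric matrix (length(m_grid) x length(n_grid)) of minimal
#'   SNRs, with dimnames giving the grids.
#' @export
snr_threshold_map <- function(m_grid, n_grid, alpha = 0.01, beta = 0.99) {
  stopifnot(all(m_grid >= 2), all(n_grid >= 2))
  out <- outer(m_grid, n_grid,
               Vectorize(function(m, n) min_snr_for_power(m, n, alpha, beta)))
  dimnames(out) <- list(m = as.character(m_grid), n = as.character(n_grid))
  out
}

#' Rescale SNR to a common spike-counting window
#'
#' For square-root stabilized Poisson spike counts accumulated over a
#' window, the signal variance of the stabilized tuning curve grows
#' proportionally with window duration while the stabilized noise variance
#' stays constant, so under a constant-firing-rate assumption SNR scales
#' linearly with the counting window:
#' `snr_out = snr * target_s / window_s`.  The constant-rate assumption is
#' optimistic for transient responses -- rates that decay after stimulus
#' onset make extrapolation to longer windows an overestimate.
#'
#' @param snr Measured SNR.
#' @param window_s Duration (seconds) of the counting window used.
#' @param target_s Duration to normalize to, default 1 second.
#' @return Rescaled SNR.
#' @export
snr_time_normalize <- function(snr, window_s, target_s = 1) {
  if (window_s <= 0 || target_s <= 0)
    stop("window durations must be positive", call. = FALSE)
  snr * target_s / window_s
}
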