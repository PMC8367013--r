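## Reference implementations of previously published noise-ceiling
## estimators of the noise-free model-to-neuron correlation, for side-by-side
## comparison with the corrected estimator.  All assume a variance-stabilized
## m x n response matrix.  Estimators that can misbehave on low-SNR data
## (negative ceilings or normalizers) return their raw value with a warning
## rather than clipping, so pathologies stay visible.

flag_value <- function(value, flagged, msg) {
  if (flagged) warning(msg, call. = FALSE)
  value
}

#' Haefner-Cumming style noncentral-F unbiased fit estimator
#'
#' Divides the residual and total sums of squares of the trial averages by
#' an estimate of the variance of the sample mean, recognizes both ratios
#' as noncentral F variates, and shifts/scales them to be unbiased before
#' reforming 1 - SSres/SStot:
#' \deqn{\Upsilon = 1 - \frac{\sum_i(\bar Y_{i\cdot}-\hat\nu_i)^2/\hat v -
#'   \frac{m(n-1)}{m(n-1)-2}(m-d)}{\sum_i(\bar Y_{i\cdot}-\bar Y)^2/\hat v -
#'   \frac{m(n-1)}{m(n-1)-2}(m-1)}}
#' where \eqn{\hat v} estimates the variance of the sample mean.  For that
#' F-distribution construction to be dimensionally consistent, \eqn{\hat v}
#' must be the variance of the per-stimulus *mean*, i.e. \eqn{s^2/n}, which
#' is the default here.  As \eqn{m(n-1) \to \infty} the correction factor
#' tends to 1 and the estimator converges to [r2_er_linear()] on the same
#' data.
#'
#' @param Y Response matrix.
#' @param fitted Least-squares fitted predictions (see [fit_predictions()])
#'   with `dof` set to the number of fitted coefficients d.
#' @param noise_mean_variance Estimated variance of the per-stimulus sample
#'   mean; defaults to the pooled sample variance divided by n.
#' @return Scalar estimate.
#' @export
upsilon <- function(Y, fitted, noise_mean_variance = NULL) {
  Y <- as_response_matrix(Y)
  fitted <- as_predictions(fitted)
  check_lengths(Y, fitted)
  m <- nrow(Y); n <- ncol(Y); d <- fitted$dof
  dfree <- m * (n - 1)
  if (dfree <= 2)
    stop("upsilon needs m(n-1) > 2 noise degrees of freedom; have m(n-1) = ",
         dfree, call. = FALSE)
  if (is.null(noise_mean_variance))
    noise_mean_variance <- pooled_sample_variance(Y)$sigma2 / n
  ybar <- rowMeans(Y)
  ss_res <- sum((ybar - fitted$nu)^2)
  ss_tot <- sum((ybar - mean(ybar))^2)
  k <- dfree / (dfree - 2)
  ## printed form multiplied through by the variance estimate, so the
  ## zero-noise limit (plain 1 - SSres/SStot) is handled exactly
  v <- noise_mean_variance
  1 - (ss_res - k * (m - d) * v) / (ss_tot - k * (m - 1) * v)
}

signal_power <- function(Y) {
  ## Sahani-Linden 'signal power': unbiased estimate of the variance of the
  ## expected responses, from the gap between the variance of trial means
  ## and the average per-trial variance across stimuli.
  m <- nrow(Y); n <- ncol(Y)
  if (n < 2L) stop("signal power needs n >= 2 repeats", call. = FALSE)
  ybar <- rowMeans(Y)
  v_means <- sum((ybar - mean(ybar))^2) / (m - 1)
  per_trial <- apply(Y, 2L, function(col) sum((col - mean(col))^2) / (m - 1))
  (n * v_means - mean(per_trial)) / (n - 1)
}

#' Normalized signal power explained
#'
#' Ratio of (variance of trial means minus residual variance of the fit) to
#' the signal-power estimate of the variance of the expected responses:
#' \deqn{SPE_{norm} = \frac{\frac{1}{m-1}\sum_i(\bar Y_{i\cdot}-\bar Y)^2 -
#'   \frac{1}{m-1}\sum_i(\bar Y_{i\cdot}-\hat\nu_i)^2}{\widehat{SP}}.}
#' The signal power denominator uses the per-trial (1/n-weighted) second
#' term, matching the reference implementation's code.  Numerically
#' equivalent to [cc_norm_sp2()] for least-squares fitted predictions.
#'
#' @inheritParams upsilon
#' @return Scalar estimate; a warning is raised when the signal-power
#'   denominator is nonpositive (the value is still returned).
#' @export
spe_norm <- function(Y, fitted) {
  Y <- as_response_matrix(Y)
  fitted <- as_predictions(fitted)
  check_lengths(Y, fitted)
  m <- nrow(Y)
  ybar <- rowMeans(Y)
  num <- (sum((ybar - mean(ybar))^2) - sum((ybar - fitted$nu)^2)) / (m - 1)
  sp <- signal_power(Y)
  flag_value(num / sp, sp <= 0,
             "signal-power denominator is nonpositive; SPE_norm unreliable")
}

#' Squared noise-corrected correlation with signal-power ceiling
#'
#' The Schoppe et al. normalized correlation coefficient, squared:
#' covariance of trial means with the fitted predictions, normalized by the
#' square root of signal power times prediction variance,
#' \eqn{CC_{norm} = \mathrm{Cov}(\bar Y, \hat\nu)\,/\,
#' \sqrt{\widehat{SP}\cdot\mathrm{Var}(\hat\nu)}}.  Shares its ceiling with
#' [spe_norm()] and is numerically identical to it for least-squares fits.
#'
#' @inheritParams upsilon
#' @return Scalar estimate (warning on nonpositive signal power).
#' @export
cc_norm_sp2 <- function(Y, fitted) {
  Y <- as_response_matrix(Y)
  fitted <- as_predictions(fitted)
  check_lengths(Y, fitted)
  ybar <- rowMeans(Y)
  sp <- signal_power(Y)
  cc2 <- cov(ybar, fitted$nu)^2 / (sp * var(fitted$nu))
  flag_value(cc2, sp <= 0,
             "signal-power ceiling is nonpositive; CC^2_norm-SP unreliable")
}

#' Fraction of explainable variance explained
#'
#' Trial-level mean squared prediction error over trial-level total
#' variance, each reduced by the trial-to-trial variance estimate, the
#' ratio subtracted from one:
#' \deqn{FEVE = 1 - \frac{\frac{1}{mn}\sum_{ij}(Y_{ij}-\hat\nu_i)^2 -
#'   \hat\sigma^2}{\frac{1}{mn}\sum_{ij}(Y_{ij}-\bar Y)^2 - \hat\sigma^2}.}
#'
#' @inheritParams upsilon
#' @param noise Optional `"noise_estimate"` or number; defaults to the
#'   pooled sample variance.
#' @return Scalar estimate (warning when the corrected denominator is
#'   nonpositive).
#' @export
feve <- function(Y, fitted, noise = NULL) {
  Y <- as_response_matrix(Y)
  fitted <- as_predictions(fitted)
  check_lengths(Y, fitted)
  noise <- resolve_noise(Y, noise)
  mn <- length(Y)
  mse <- sum((Y - fitted$nu)^2) / mn       # nu recycles down columns: rows are stimuli
  tv <- sum((Y - mean(Y))^2) / mn
  den <- tv - noise$sigma2
  flag_value(1 - (mse - noise$sigma2) / den, den <= 0,
             "corrected total variance is nonpositive; FEVE unreliable")
}

#' Naive r^2 normalized by estimated explainable fraction of variance
#'
#' Divides the naive squared correlation by an estimate of the fraction of
#' variance in the trial averages *not* due to trial-to-trial noise:
#' \eqn{\hat r^2 / (1 - SE^2/SS_{total})} with \eqn{SE^2 = s^2/n} the
#' estimated variance of the sample mean and \eqn{SS_{total}} the variance
#' of the trial-averaged responses (m - 1 denominator).  Known to
#' overestimate the noise-free correlation at low SNR.
#'
#' @param Y Response matrix with n >= 2 repeats.
#' @param preds Raw predictions (vector or [predictions()]).
#' @return Scalar estimate (warning when the normalizer is nonpositive).
#' @export
pc_ratio <- function(Y, preds) {
  Y <- as_response_matrix(Y)
  preds <- as_predictions(preds)
  check_lengths(Y, preds)
  n <- ncol(Y)
  se2 <- pooled_sample_variance(Y)$sigma2 / n
  ybar <- rowMeans(Y)
  ss_tot <- var(ybar)
  normalizer <- 1 - se2 / ss_tot
  flag_value(naive_r2(ybar, preds) / normalizer, normalizer <= 0,
             "explainable-variance normalizer is nonpositive; ratio unreliable")
}

#' Resampling-based noise-ceiling estimators
#'
#' Three estimators that normalize the naive squared correlation by a
#' resampled estimate of the best correlation achievable given trial
#' noise:
#' \describe{
#'   \item{`cc_norm_split2`}{Split-half ceiling: trials are split into two
#'     disjoint halves of floor(n/2) (any odd trial dropped at random per
#'     resample); the correlation r between half-mean tuning curves is
#'     averaged across resamples and extrapolated to the full trial count
#'     by the Spearman-Brown formula, giving the squared ceiling
#'     \eqn{CC^2_{max} = 2\bar r/(1+\bar r)}; the naive r^2 is divided by
#'     it.}
#'   \item{`r2_norm_split_sb`}{Same split-half machinery, but the
#'     Spearman-Brown corrected *correlation* \eqn{2\bar r/(1+\bar r)} is
#'     itself squared before normalizing the naive r^2, i.e. the ceiling
#'     treats the corrected correlation as an r rather than an r^2.  This
#'     reading makes the method overestimate, reproducing its published
#'     behavior.}
#'   \item{`cc_norm_pb`}{Parametric-bootstrap ceiling: `resamples` Gaussian
#'     surrogate data sets are simulated with per-stimulus means equal to
#'     the observed trial means and pooled sample variance; the ceiling is
#'     the average correlation of surrogate trial-averages with the
#'     observed trial means, and the naive r^2 is divided by its square.}
#' }
#'
#' @param Y Response matrix with n >= 2 repeats.
#' @param preds Raw predictions (vector or [predictions()]).
#' @param method One of `"cc_norm_split2"`, `"r2_norm_split_sb"`,
#'   `"cc_norm_pb"`.
#' @param resamples Number of resamples (>= 1), default 100.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return List with `method`, `value`, `ceiling`, `resamples`, `seed`.
#' @export
resampled_ceiling <- function(Y, preds,
                              method = c("cc_norm_split2", "r2_norm_split_sb",
                                         "cc_norm_pb"),
                              resamples = 100L, seed = 1L) {
  method <- match.arg(method)
  Y <- as_response_matrix(Y)
  preds <- as_predictions(preds)
  check_lengths(Y, preds)
  m <- nrow(Y); n <- ncol(Y)
  if (n < 2L) stop(method, " needs n >= 2 repeats", call. = FALSE)
  if (resamples < 1L) stop("resamples must be >= 1", call. = FALSE)
  ybar <- rowMeans(Y)
  r2n <- naive_r2(ybar, preds)
  ceiling_val <- with_seed(seed, {
    if (method == "cc_norm_pb") {
      s2 <- pooled_sample_variance(Y)$sigma2
      ccs <- vapply(seq_len(resamples), function(b) {
        Yb <- matrix(rnorm(m * n, mean = ybar, sd = sqrt(s2)), nrow = m)
        suppressWarnings(cor(rowMeans(Yb), ybar))
      }, numeric(1))
      mean(ccs, na.rm = TRUE)^2
    } else {
      half <- n %/% 2L
      rs <- vapply(seq_len(resamples), function(b) {
        idx <- sample.int(n)
        h1 <- rowMeans(Y[, idx[seq_len(half)], drop = FALSE])
        h2 <- rowMeans(Y[, idx[half + seq_len(half)], drop = FALSE])
        suppressWarnings(cor(h1, h2))
      }, numeric(1))
      rbar <- mean(rs, na.rm = TRUE)
      sb <- 2 * rbar / (1 + rbar)       # Spearman-Brown half -> full
      if (method == "cc_norm_split2") sb else sb^2
    }
  })
  if (is.na(ceiling_val)) ceiling_val <- 1  # degenerate zero-noise halves
  value <- flag_value(r2n / ceiling_val, is.finite(ceiling_val) && ceiling_val <= 0,
                      paste0(method, ": nonpositive ceiling; value unreliable"))
  list(method = method, value = value, ceiling = ceiling_val,
       resamples = as.integer(resamples), seed = as.integer(seed))
}

#' Run every estimator of the noise-free correlation on one data set
#'
#' Convenience driver for side-by-side comparison: applies the corrected
#' estimator, the naive estimator, and all prior noise-ceiling estimators
#' to the same response matrix and predictions.  Per-method errors are
#' captured in the output rather than aborting the run.
#'
#' @param Y Response matrix.
#' @param preds Raw predictions (vector or [predictions()]); least-squares
#'   fitted values are computed internally for the methods that need them.
#' @param methods Character vector of method names, or `"all"`.
#' @param resamples Resamples for the resampling-based methods.
#' @param seed Integer seed for the resampling-based methods.
#' @return Data frame with columns `method`, `value`, `resamples`, `seed`,
#'   `error`.
#' @examples
#' Y <- response_matrix(rbind(c(1, 3), c(2, 4), c(5, 7)))
#' compare_estimators(Y, c(0, 1, 2), seed = 1)
#' @export
compare_estimators <- function(Y, preds, methods = "all", resamples = 100L,
                               seed = 1L) {
  Y <- as_response_matrix(Y)
  preds <- as_predictions(preds)
  all_methods <- names(estimator_registry())
  all_methods <- setdiff(all_methods, "snr_hat")
  if (identical(methods, "all")) methods <- all_methods
  stopifnot(all(methods %in% all_methods))
  fns <- estimator_registry(resamples = resamples, seed = seed)
  resampled <- c("cc_norm_split2", "r2_norm_split_sb", "cc_norm_pb")
  rows <- lapply(methods, function(mth) {
    res <- tryCatch(
      list(value = suppressWarnings(fns[[mth]](Y, preds$nu)), error = NA_character_),
      error = function(e) list(value = NA_real_, error = conditionMessage(e)))
    data.frame(method = mth, value = res$value,
               resamples = if (mth %in% resampled) as.integer(resamples) else 0L,
               seed = if (mth %in% resampled) as.integer(seed) else NA_integer_,
               error = res$error, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
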