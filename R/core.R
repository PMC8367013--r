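#' Construct and validate a response matrix
#'
#' A response matrix holds variance-stabilized responses \eqn{Y_{i,j}} of one
#' neuron to \eqn{m} stimuli (rows) over \eqn{n} repeated trials (columns).
#' All downstream estimators assume trial-to-trial variance is constant
#' across stimuli, which a variance-stabilizing transform
#' (see [apply_stabilizer()]) is meant to guarantee.  Data must be
#' rectangular: every stimulus needs the same number of repeats.  Recordings
#' with unequal repeats must be subset to a common repeat count first.
#'
#' @param values Numeric matrix (or object coercible to one), stimuli in
#'   rows, repeats in columns.  At least 2 rows, 1 column, all entries finite.
#' @return The validated matrix with class `"response_matrix"`.
#' @examples
#' Y <- response_matrix(rbind(c(1, 3), c(2, 4), c(5, 7)))
#' nrow(Y) # m = 3 stimuli
#' @export
response_matrix <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("response matrix must be numeric", call. = FALSE)
  if (nrow(values) < 2L)
    stop("need at least m = 2 stimuli (rows), got ", nrow(values), call. = FALSE)
  if (ncol(values) < 1L)
    stop("need at least n = 1 repeat (column)", call. = FALSE)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite response at stimulus ", bad[1L], ", repeat ", bad[2L],
         "; response matrices must be rectangular with no missing cells",
         call. = FALSE)
  }
  structure(values, class = c("response_matrix", class(values)))
}

as_response_matrix <- function(Y) {
  if (inherits(Y, "response_matrix")) Y else response_matrix(Y)
}

#' Model predictions for a tuning curve
#'
#' @param nu Numeric vector of length m: the model's predicted expected
#'   response to each stimulus.  Must show some variation across stimuli.
#' @param dof Degrees of freedom `d` of the linear fit that produced `nu`.
#'   Use 1 for raw single-covariate predictions (the default) and 2 for an
#'   intercept-plus-slope least-squares fit; see [r2_er_linear()].
#' @return Object of class `"predictions"` with fields `nu` and `dof`.
#' @examples
#' predictions(c(0, 1, 2))
#' @export
predictions <- function(nu, dof = 1L) {
  nu <- as.numeric(nu)
  if (any(!is.finite(nu))) stop("predictions must be finite", call. = FALSE)
  if (sum((nu - mean(nu))^2) <= 0)
    stop("model predictions are constant; their variance must be positive",
         call. = FALSE)
  dof <- as.integer(dof)
  if (dof < 1L) stop("dof must be a positive integer", call. = FALSE)
  structure(list(nu = nu, dof = dof), class = "predictions")
}

as_predictions <- function(preds) {
  if (inherits(preds, "predictions")) preds else predictions(preds)
}

check_lengths <- function(Y, preds) {
  if (length(preds$nu) != nrow(Y))
    stop("length of predictions (", length(preds$nu),
         ") does not match number of stimuli (", nrow(Y), ")", call. = FALSE)
}

#' Trial-to-trial noise variance estimate
#'
#' Wraps an estimate of the stabilized trial-to-trial variance
#' \eqn{\sigma^2}.  Usually obtained from the data with
#' [pooled_sample_variance()]; for single-repeat designs (n = 1) an assumed
#' value can be supplied instead -- for square-root transformed Poisson
#' counts the stabilized variance is approximately 1/4.
#'
#' @param sigma2 Nonnegative noise variance.
#' @param source Either `"sample"` (estimated from repeats) or `"assumed"`.
#' @return Object of class `"noise_estimate"`.
#' @seealso [pooled_sample_variance()], [assumed_noise()]
#' @export
noise_estimate <- function(sigma2, source = c("sample", "assumed")) {
  source <- match.arg(source)
  sigma2 <- as.numeric(sigma2)
  if (length(sigma2) != 1L || !is.finite(sigma2) || sigma2 < 0)
    stop("sigma2 must be a single nonnegative number", call. = FALSE)
  structure(list(sigma2 = sigma2, source = source), class = "noise_estimate")
}

#' @rdname noise_estimate
#' @details `assumed_noise()` is a convenience constructor for the assumed
#'   case; called with no argument it returns the square-root-Poisson default
#'   of 1/4.
#' @export
assumed_noise <- function(sigma2 = 0.25) noise_estimate(sigma2, "assumed")

#' Pooled unbiased sample variance of trial-to-trial noise
#'
#' Per-stimulus unbiased sample variances
#' \eqn{s_i^2 = \frac{1}{n-1}\sum_j (Y_{i,j}-\bar Y_{i\cdot})^2}
#' averaged over stimuli: \eqn{s^2 = \frac{1}{m}\sum_i s_i^2}.  This is the
#' default plug-in for \eqn{\hat\sigma^2} in all corrected estimators.
#'
#' @param Y Response matrix with n >= 2 repeats.
#' @return A `"noise_estimate"` with `source = "sample"`.
#' @examples
#' pooled_sample_variance(response_matrix(rbind(c(1, 3), c(2, 4), c(5, 7))))
#' @export
pooled_sample_variance <- function(Y) {
  Y <- as_response_matrix(Y)
  if (ncol(Y) < 2L)
    stop("pooled sample variance needs n >= 2 repeats; with n = 1 supply an ",
         "assumed noise variance instead, e.g. assumed_noise(0.25) for ",
         "square-root transformed Poisson counts", call. = FALSE)
  s2 <- mean(apply(Y, 1L, var))
  noise_estimate(s2, "sample")
}

resolve_noise <- function(Y, noise) {
  if (is.null(noise)) return(pooled_sample_variance(Y))
  if (is.numeric(noise)) return(noise_estimate(noise, "assumed"))
  stopifnot(inherits(noise, "noise_estimate"))
  noise
}

#' Unbiased dynamic range of a tuning curve
#'
#' The dynamic range \eqn{d^2 = \frac{1}{m}\sum_i(\mu_i-\bar\mu)^2} measures
#' how strongly the expected response varies across stimuli.  The naive
#' plug-in using trial averages is inflated by noise; the corrected
#' estimator subtracts the expected inflation:
#' \deqn{\hat d^2_{ER} = \frac{1}{m}\left(\sum_i (\bar Y_{i\cdot} - \bar
#'   Y_{\cdot\cdot})^2 - (m-1)\frac{\hat\sigma^2}{n}\right).}
#' The estimate may legitimately be negative for weakly tuned neurons.
#'
#' @param Y Response matrix.
#' @param noise A `"noise_estimate"`, a bare nonnegative number (treated as
#'   assumed), or `NULL` to use [pooled_sample_variance()].
#' @return Scalar estimate of the dynamic range.
#' @export
dynamic_range_hat <- function(Y, noise = NULL) {
  Y <- as_response_matrix(Y)
  noise <- resolve_noise(Y, noise)
  m <- nrow(Y); n <- ncol(Y)
  ybar <- rowMeans(Y)
  (sum((ybar - mean(ybar))^2) - (m - 1) * noise$sigma2 / n) / m
}

#' Unbiased signal-to-noise ratio of a recording
#'
#' SNR of a tuning curve is defined as dynamic range over trial-to-trial
#' variance, \eqn{SNR = d^2/\sigma^2}; the estimator is
#' \eqn{\widehat{SNR} = \hat d^2_{ER} / \hat\sigma^2} with the
#' noise-corrected dynamic range in the numerator.  Because the correction
#' is unbiased the estimate can be negative for untuned neurons; negative
#' values are returned as-is (truncation would reintroduce bias).
#'
#' @inheritParams dynamic_range_hat
#' @return Object of class `"snr_estimate"`: list with `snr_hat`,
#'   `d2_er_hat`, `sigma2_hat`.
#' @seealso [min_snr_for_power()] for interpreting the value as F-test power.
#' @examples
#' snr_hat(response_matrix(rbind(c(1, 3), c(2, 4), c(5, 7))))
#' @export
snr_hat <- function(Y, noise = NULL) {
  Y <- as_response_matrix(Y)
  noise <- resolve_noise(Y, noise)
  if (noise$sigma2 <= 0)
    stop("SNR is undefined for zero noise variance", call. = FALSE)
  d2 <- dynamic_range_hat(Y, noise)
  structure(list(snr_hat = d2 / noise$sigma2, d2_er_hat = d2,
                 sigma2_hat = noise$sigma2),
            class = "snr_estimate")
}

#' Naive squared correlation between trial averages and predictions
#'
#' The classical estimator: squared Pearson correlation between the
#' trial-averaged responses \eqn{\bar Y_{i\cdot}} and the model predictions
#' \eqn{\nu_i}.  Always in \[0, 1\] but biased downward as an estimate of the
#' noise-free correlation whenever trial-to-trial variance is nonzero.
#'
#' @param ybar Numeric vector of per-stimulus trial averages (or a response
#'   matrix, in which case row means are taken).
#' @param preds A [predictions()] object or numeric vector.
#' @return Scalar in \[0, 1\].
#' @export
naive_r2 <- function(ybar, preds) {
  if (is.matrix(ybar) || inherits(ybar, "response_matrix"))
    ybar <- rowMeans(ybar)
  preds <- as_predictions(preds)
  if (length(preds$nu) != length(ybar))
    stop("length of predictions does not match number of stimuli", call. = FALSE)
  if (var(ybar) <= 0)
    stop("trial-averaged responses are constant; correlation undefined",
         call. = FALSE)
  cor(ybar, preds$nu)^2
}

#' Bias-corrected estimator of the noise-free squared correlation
#'
#' Estimates \eqn{r^2_{ER}}, the squared correlation between the model
#' predictions and the *expected* responses \eqn{\mu_i}, by subtracting
#' unbiased estimates of the noise contribution from the numerator and
#' denominator of the naive squared correlation separately:
#' \deqn{\hat r^2_{ER} = \frac{\left(\sum_i(\nu_i-\bar\nu)(\bar Y_{i\cdot}
#'  -\bar Y)\right)^2 - \frac{\hat\sigma^2}{n}\sum_i(\nu_i-\bar\nu)^2}
#'  {\sum_i(\nu_i-\bar\nu)^2\sum_i(\bar Y_{i\cdot}-\bar Y)^2 -
#'   (m-1)\frac{\hat\sigma^2}{n}\sum_i(\nu_i-\bar\nu)^2}.}
#' Both correction terms follow from the noncentral chi-squared sampling
#' distributions of the two sums of squares.  The ratio of two unbiased
#' quantities is only approximately unbiased, but it is consistent in the
#' number of stimuli m, unlike the naive estimator.
#'
#' The estimate is deliberately *not* truncated to \[0, 1\]: values above 1
#' occur about half the time when the true correlation is 1, and truncating
#' them would bias the mean downward.  Internally the predictions are
#' rescaled to unit centered sum of squares, which leaves the value
#' invariant.
#'
#' @param Y Response matrix (m stimuli x n repeats), m >= 3.
#' @param preds A [predictions()] object or numeric vector of length m.
#' @param noise A `"noise_estimate"`, a bare number (assumed variance), or
#'   `NULL` to use the pooled sample variance (requires n >= 2).
#' @return Object of class `"estimate_result"`: list with `r2_er`,
#'   `r2_naive`, `numerator`, `denominator`, `sigma2_used`, `unstable`
#'   (`TRUE` when the corrected denominator is <= 0, as happens for very
#'   low-SNR data; the raw ratio is still reported).
#' @examples
#' Y <- response_matrix(rbind(c(1, 3), c(2, 4), c(5, 7)))
#' fit <- r2_er(Y, c(0, 1, 2))
#' fit$r2_er    # 1.05
#' fit$r2_naive # 12/13
#' @export
r2_er <- function(Y, preds, noise = NULL) {
  Y <- as_response_matrix(Y)
  preds <- as_predictions(preds)
  check_lengths(Y, preds)
  if (nrow(Y) < 3L)
    stop("the corrected estimator needs m >= 3 stimuli", call. = FALSE)
  noise <- resolve_noise(Y, noise)
  m <- nrow(Y); n <- ncol(Y)
  ybar <- rowMeans(Y)
  nu <- preds$nu - mean(preds$nu)
  ss_nu <- sum(nu^2)
  nu <- nu / sqrt(ss_nu)              # unit scale; the ratio is invariant
  yc <- ybar - mean(ybar)
  corr <- noise$sigma2 / n            # variance of the sample mean
  num <- sum(nu * yc)^2 - corr        # sum(nu^2) == 1 after rescale
  den <- sum(yc^2) - (m - 1) * corr
  unstable <- den <= 0
  structure(list(
    r2_er = if (den != 0) num / den else NaN,
    r2_naive = naive_r2(ybar, preds),
    numerator = num * ss_nu,          # back on the raw-predictions scale
    denominator = den * ss_nu,
    sigma2_used = noise$sigma2,
    unstable = unstable
  ), class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("corrected r^2_ER = %.4f (naive r^2 = %.4f)\n",
              x$r2_er, x$r2_naive))
  cat(sprintf("  numerator %.4g / denominator %.4g, sigma2 = %.4g%s\n",
              x$numerator, x$denominator, x$sigma2_used,
              if (x$unstable) "  [UNSTABLE: denominator <= 0]" else ""))
  invisible(x)
}

#' Corrected fraction of variance explained by a fitted linear model
#'
#' Generalization of [r2_er()] to least-squares fitted values
#' \eqn{\hat\nu_i} from a linear model with `d` coefficients:
#' \deqn{\hat r^2_{ER} = 1 - \frac{\sum_i(\bar Y_{i\cdot}-\hat\nu_i)^2 -
#'   (m-d)\frac{\hat\sigma^2}{n}}{\sum_i(\bar Y_{i\cdot}-\bar Y)^2 -
#'   (m-1)\frac{\hat\sigma^2}{n}}.}
#' The residual and total sums of squares are noncentral chi-squared with
#' m - d and m - 1 degrees of freedom; subtracting their noise expectations
#' makes both unbiased.  When `d = 2` and the fitted values come from
#' regressing the trial averages on a single covariate with intercept, the
#' result is algebraically identical to [r2_er()].
#'
#' @param ybar Vector of per-stimulus trial averages (or a response matrix).
#' @param fitted A [predictions()] object whose `nu` are least-squares
#'   fitted values and whose `dof` is the number of fitted coefficients d,
#'   with 1 <= d < m.
#' @param noise A `"noise_estimate"` or bare number.
#' @param n Number of repeats behind each trial average.
#' @return Scalar corrected fraction of variance explained.
#' @export
r2_er_linear <- function(ybar, fitted, noise, n) {
  if (is.matrix(ybar) || inherits(ybar, "response_matrix")) {
    if (missing(n)) n <- ncol(ybar)
    ybar <- rowMeans(ybar)
  }
  fitted <- as_predictions(fitted)
  if (length(fitted$nu) != length(ybar))
    stop("length of fitted values does not match number of stimuli", call. = FALSE)
  m <- length(ybar)
  d <- fitted$dof
  if (d >= m)
    stop("model degrees of freedom d = ", d, " leave no residual degrees of ",
         "freedom for m = ", m, " stimuli", call. = FALSE)
  if (is.numeric(noise)) noise <- noise_estimate(noise, "assumed")
  corr <- noise$sigma2 / n
  ss_res <- sum((ybar - fitted$nu)^2)
  ss_tot <- sum((ybar - mean(ybar))^2)
  1 - (ss_res - (m - d) * corr) / (ss_tot - (m - 1) * corr)
}

#' Least-squares fit of model predictions to trial averages
#'
#' Regresses the trial-averaged responses on the raw predictions with an
#' intercept, returning the fitted values as a [predictions()] object with
#' `dof = 2`.  Several noise-ceiling estimators in the literature require
#' predictions on the scale of the data; this is the standard way to put
#' them there.
#'
#' @param ybar Vector of trial averages (or a response matrix).
#' @param preds Raw predictions (vector or [predictions()]).
#' @return A [predictions()] object of fitted values with `dof = 2`.
#' @export
fit_predictions <- function(ybar, preds) {
  if (is.matrix(ybar) || inherits(ybar, "response_matrix"))
    ybar <- rowMeans(ybar)
  preds <- as_predictions(preds)
  if (length(preds$nu) != length(ybar))
    stop("length of predictions does not match number of stimuli", call. = FALSE)
  nu <- preds$nu
  slope <- sum((nu - mean(nu)) * (ybar - mean(ybar))) / sum((nu - mean(nu))^2)
  intercept <- mean(ybar) - slope * mean(nu)
  predictions(intercept + slope * nu, dof = 2L)
}
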