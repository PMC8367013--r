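## Seed plumbing: every stochastic entry point takes an integer seed and
## leaves the caller's RNG state untouched.  Replicate k of a run gets its
## own substream seed derived from the master seed, so serial and chunked
## execution of a sweep agree replicate-for-replicate.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

substream_seed <- function(seed, k) {
  ## LCG-style mix, kept inside 32-bit signed integer range
  as.integer((as.double(seed) %% 2147483647 * 48271 + k * 16807) %% 2147483629) + 1L
}

#' Configuration of the sinusoidal-tuning generative model
#'
#' The synthetic-data engine draws stabilized responses
#' \eqn{Y_{i,j} \sim N(\mu_i, \sigma^2)} around a sinusoidal tuning curve
#' \eqn{\mu_i = a + b\,\sin((i-1)2\pi/m + \theta)} while the model predicts
#' \eqn{\nu_i = \sin((i-1)2\pi/m)}.  Over a full cycle the phase offset
#' \eqn{\theta} sets the squared correlation between tuning curve and model
#' exactly: \eqn{r^2_{ER} = \cos^2\theta}.  The amplitude b is solved from
#' the realized discrete sum so that the dynamic range constraint
#' \eqn{\frac{1}{m}\sum_i(\mu_i - \bar\mu)^2 = d^2} holds exactly for any m,
#' making the nominal SNR exact rather than approximate.
#'
#' Only the triplet (d2, sigma2) -- equivalently SNR = d2/sigma2 -- the
#' correlation, m and n matter for the estimators; the sinusoidal shape is
#' an arbitrary but convenient choice.
#'
#' @param m Number of stimuli (>= 3).
#' @param n Number of repeats per stimulus.
#' @param sigma2 Trial-to-trial variance on the stabilized scale.
#' @param d2 Dynamic range of the tuning curve; give exactly one of `d2`
#'   and `snr` (`d2 = snr * sigma2`).
#' @param snr Signal-to-noise ratio, alternative to `d2`.
#' @param r2_er_true True noise-free squared correlation, in \[0, 1\].
#' @param a Baseline response.  Defaults to 0 in `"gaussian"` mode; in
#'   `"poisson_sqrt"` mode it defaults to the smallest value keeping every
#'   \eqn{\mu_i \ge 0.5} (i.e. Poisson rates of at least 0.25 per window).
#' @param mode `"gaussian"` for normal noise on the stabilized scale, or
#'   `"poisson_sqrt"` for Poisson counts with rates \eqn{\mu_i^2} followed
#'   by a square-root transform.
#' @param seed Integer seed for [simulate_responses()].
#' @return Object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(m = 362, n = 4, sigma2 = 0.25, snr = 0.5, r2_er_true = 1)
#' @export
sim_config <- function(m, n, sigma2, d2 = NULL, snr = NULL, r2_er_true,
                       a = NULL, mode = c("gaussian", "poisson_sqrt"),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (m < 3L) stop("need m >= 3 stimuli", call. = FALSE)
  if (n < 1L) stop("need n >= 1 repeats", call. = FALSE)
  if (!is.finite(sigma2) || sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (is.null(d2) == is.null(snr))
    stop("give exactly one of d2 and snr", call. = FALSE)
  if (is.null(d2)) d2 <- snr * sigma2
  if (d2 < 0) stop("dynamic range d2 must be >= 0", call. = FALSE)
  if (r2_er_true < 0 || r2_er_true > 1)
    stop("r2_er_true must lie in [0, 1]", call. = FALSE)
  structure(list(m = as.integer(m), n = as.integer(n), sigma2 = sigma2,
                 d2 = d2, snr = d2 / max(sigma2, .Machine$double.eps),
                 r2_er_true = r2_er_true, a = a, mode = mode,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Tuning curve and model predictions for a simulation configuration
#'
#' Builds the expected responses \eqn{\mu} and the model predictions
#' \eqn{\nu} of the sinusoidal generative model.  The phase is
#' \eqn{\theta = \arccos\sqrt{r^2_{ER}}} and the amplitude is solved so the
#' realized discrete dynamic range equals `d2` exactly.
#'
#' @param config A [sim_config()].
#' @return List with numeric vectors `mu` and `nu` (length m) and the
#'   resolved baseline `a`.
#' @examples
#' tc <- make_tuning(sim_config(8, 4, 0.25, snr = 2, r2_er_true = 0.5))
#' cor(tc$mu, tc$nu)^2  # 0.5
#' @export
make_tuning <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m
  phase <- (seq_len(m) - 1) * 2 * pi / m
  theta <- acos(sqrt(config$r2_er_true))
  nu <- sin(phase)
  shape <- sin(phase + theta)
  ssq <- sum((shape - mean(shape))^2)
  b <- if (config$d2 > 0) sqrt(config$d2 * m / ssq) else 0
  a <- config$a
  if (is.null(a))
    a <- if (config$mode == "poisson_sqrt") 0.5 + b * max(0, -min(shape)) else 0
  mu <- a + b * shape
  list(mu = mu, nu = nu, a = a)
}

#' Draw a synthetic response matrix
#'
#' Simulates one m x n response matrix from the generative model in
#' `config`.  In `"gaussian"` mode draws are i.i.d. normal on the
#' stabilized scale; in `"poisson_sqrt"` mode spike counts are drawn
#' Poisson with rates \eqn{\mu_i^2} and square-root transformed, which
#' yields an approximately constant variance of 1/4 (so `sigma2 = 0.25` is
#' the matching configuration on the stabilized scale).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to the seed stored in the config.
#' @return A [response_matrix()] with attributes `mu`, `nu` and `config`
#'   recording the ground truth (used by parameter-recovery tests).
#' @export
simulate_responses <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  tc <- make_tuning(config)
  m <- config$m; n <- config$n
  vals <- with_seed(seed, {
    if (config$mode == "gaussian") {
      matrix(rnorm(m * n, mean = tc$mu, sd = sqrt(config$sigma2)), nrow = m)
    } else {
      if (any(tc$mu < 0))
        stop("poisson_sqrt mode needs all expected stabilized responses ",
             "mu_i >= 0; raise the baseline a", call. = FALSE)
      sqrt(matrix(rpois(m * n, lambda = tc$mu^2), nrow = m))
    }
  })
  Y <- response_matrix(vals)
  attr(Y, "mu") <- tc$mu
  attr(Y, "nu") <- tc$nu
  attr(Y, "config") <- config
  Y
}

## Registry mapping estimator names to closures Y, nu -> value.  Used by
## sim_sweep() and compare_estimators().
estimator_registry <- function(resamples = 100L, seed = 1L) {
  list(
    r2_naive = function(Y, nu) naive_r2(Y, nu),
    r2_er = function(Y, nu) r2_er(Y, nu)$r2_er,
    upsilon = function(Y, nu) upsilon(Y, fit_predictions(Y, nu)),
    spe_norm = function(Y, nu) spe_norm(Y, fit_predictions(Y, nu)),
    cc_norm_sp2 = function(Y, nu) cc_norm_sp2(Y, fit_predictions(Y, nu)),
    feve = function(Y, nu) feve(Y, fit_predictions(Y, nu)),
    cc_norm_split2 = function(Y, nu)
      resampled_ceiling(Y, nu, "cc_norm_split2", resamples, seed)$value,
    r2_norm_split_sb = function(Y, nu)
      resampled_ceiling(Y, nu, "r2_norm_split_sb", resamples, seed)$value,
    cc_norm_pb = function(Y, nu)
      resampled_ceiling(Y, nu, "cc_norm_pb", resamples, seed)$value,
    pc_ratio = function(Y, nu) pc_ratio(Y, nu),
    snr_hat = function(Y, nu) snr_hat(Y)$snr_hat
  )
}

#' Simulation sweep over configurations and estimators
#'
#' Runs `reps` independent replicates of each configuration, applies each
#' requested estimator to every replicate, and summarizes the sampling
#' distribution per (configuration, estimator) cell.  Fully reproducible:
#' replicate k of configuration j always uses the same derived substream
#' seed regardless of evaluation order.
#'
#' @param configs A [sim_config()] or list of them.
#' @param estimators Character vector of estimator names; any of
#'   `"r2_naive"`, `"r2_er"`, `"upsilon"`, `"spe_norm"`, `"cc_norm_sp2"`,
#'   `"feve"`, `"cc_norm_split2"`, `"r2_norm_split_sb"`, `"cc_norm_pb"`,
#'   `"pc_ratio"`, `"snr_hat"`.
#' @param reps Number of replicates per configuration.
#' @param seed Master integer seed.
#' @param resamples Resamples for the split/parametric-bootstrap ceiling
#'   estimators.
#' @param keep_draws If `TRUE`, attach the per-replicate estimates as
#'   attribute `"draws"` (a list of matrices, one per configuration).
#' @return Data frame with one row per (configuration, estimator):
#'   columns `config`, `m`, `n`, `sigma2`, `snr`, `r2_er_true`,
#'   `estimator`, `mean`, `sd`, `q05`, `q95`, `mse`, `n_failed`.
#' @examples
#' cfg <- sim_config(20, 4, 0.25, snr = 1, r2_er_true = 0.75)
#' sim_sweep(cfg, c("r2_naive", "r2_er"), reps = 20, seed = 7)
#' @export
sim_sweep <- function(configs, estimators = c("r2_naive", "r2_er"),
                      reps = 100L, seed = 1L, resamples = 100L,
                      keep_draws = FALSE) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  rows <- list()
  draws_by_config <- list()
  for (j in seq_along(configs)) {
    cfg <- configs[[j]]
    est <- matrix(NA_real_, nrow = reps, ncol = length(estimators),
                  dimnames = list(NULL, estimators))
    for (k in seq_len(reps)) {
      sk <- substream_seed(seed, (j - 1L) * reps + k)
      Y <- simulate_responses(cfg, seed = sk)
      nu <- attr(Y, "nu")
      fns <- estimator_registry(resamples = resamples, seed = sk)
      for (e in estimators) {
        est[k, e] <- tryCatch(fns[[e]](Y, nu), error = function(err) NA_real_)
      }
    }
    for (e in estimators) {
      x <- est[, e]
      ok <- x[is.finite(x)]
      qs <- if (length(ok)) quantile(ok, c(0.05, 0.95), names = FALSE)
            else c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        config = j, m = cfg$m, n = cfg$n, sigma2 = cfg$sigma2,
        snr = cfg$snr, r2_er_true = cfg$r2_er_true, estimator = e,
        mean = if (length(ok)) mean(ok) else NA_real_,
        sd = if (length(ok) > 1) sd(ok) else NA_real_,
        q05 = qs[1], q95 = qs[2],
        mse = if (length(ok)) mean((ok - cfg$r2_er_true)^2) else NA_real_,
        n_failed = sum(!is.finite(x)),
        stringsAsFactors = FALSE)
    }
    if (keep_draws) draws_by_config[[j]] <- est
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_draws) attr(out, "draws") <- draws_by_config
  out
}
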