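test_that("pooled sample variance averages per-stimulus unbiased variances", {
  expect_equal(pooled_sample_variance(toy_Y())$sigma2, 2)
  expect_equal(pooled_sample_variance(rbind(c(0, 2), c(5, 5)))$sigma2, 1)
  expect_equal(pooled_sample_variance(matrix(3, 4, 5))$sigma2, 0)
  expect_error(pooled_sample_variance(matrix(1:3, 3, 1)), "n >= 2")
})

test_that("corrected dynamic range and SNR match hand values on the toy matrix", {
  Y <- toy_Y()
  expect_equal(dynamic_range_hat(Y), 20 / 9)
  s <- snr_hat(Y)
  expect_equal(s$snr_hat, 10 / 9)
  expect_equal(s$d2_er_hat / s$sigma2_hat, s$snr_hat)
  expect_error(snr_hat(matrix(3, 4, 5)), "undefined")
})

test_that("corrected dynamic range is unbiased in simulation", {
  set.seed(7)
  m <- 50; n <- 4; sigma2 <- 0.25; d2 <- 0.25
  mu <- make_tuning(sim_config(m, n, sigma2, d2 = d2, r2_er_true = 1))$mu
  ests <- vapply(1:1500, function(k) {
    Y <- matrix(rnorm(m * n, mu, sqrt(sigma2)), m)
    dynamic_range_hat(Y)
  }, numeric(1))
  expect_lt(abs(mean(ests) - d2), 3 * sd(ests) / sqrt(length(ests)))
  # untuned neuron: estimate centered at zero
  ests0 <- vapply(1:1500, function(k)
    dynamic_range_hat(matrix(rnorm(m * n, 1, sqrt(sigma2)), m)), numeric(1))
  expect_lt(abs(mean(ests0)), 3 * sd(ests0) / sqrt(length(ests0)))
})

test_that("naive r^2 reproduces hand values and rejects degenerate input", {
  expect_equal(naive_r2(c(2, 3, 6), c(0, 1, 2)), 12 / 13)
  expect_equal(naive_r2(c(1, 4, 2, 8), c(1, 4, 2, 8)), 1)
  expect_equal(naive_r2(c(1, -2, 1), c(-1, 0, 1)), 0)
  expect_error(naive_r2(c(2, 2, 2), c(0, 1, 2)), "constant")
  expect_error(predictions(c(1, 1, 1)), "constant")
})

test_that("corrected estimator matches the toy hand evaluation exactly", {
  fit <- r2_er(toy_Y(), toy_nu())
  expect_equal(fit$r2_er, 1.05)
  expect_equal(fit$r2_naive, 12 / 13)
  expect_equal(fit$numerator, 14)
  expect_equal(fit$denominator, 40 / 3)
  expect_equal(fit$sigma2_used, 2)
  expect_false(fit$unstable)
})

test_that("zero assumed noise collapses the corrected estimator to the naive one", {
  inst <- with_seed_local(11, random_instance())
  fit <- r2_er(inst$Y, inst$nu, noise = assumed_noise(0))
  expect_equal(fit$r2_er, fit$r2_naive, tolerance = 1e-12)
})

test_that("the corrected estimator is invariant to affine rescaling of predictions", {
  inst <- with_seed_local(12, random_instance())
  f1 <- r2_er(inst$Y, inst$nu)
  f2 <- r2_er(inst$Y, 5 - 3.7 * inst$nu)
  expect_equal(f1$r2_er, f2$r2_er, tolerance = 1e-12)
})

test_that("single-repeat designs need an assumed noise variance", {
  Y <- matrix(c(1, 2, 5), 3, 1)
  expect_error(r2_er(Y, c(0, 1, 2)), "assumed")
  fit <- r2_er(Y, c(0, 1, 2), noise = assumed_noise(0.25))
  expect_equal(fit$sigma2_used, 0.25)
})

test_that("nonpositive corrected denominator is flagged unstable, not fatal", {
  # huge assumed noise forces the denominator negative
  fit <- r2_er(toy_Y(), toy_nu(), noise = assumed_noise(50))
  expect_true(fit$unstable)
  expect_true(is.finite(fit$r2_er))
})

test_that("linear-model form matches the single-covariate form at d = 2", {
  Y <- toy_Y()
  f <- fit_predictions(Y, toy_nu())
  expect_equal(r2_er_linear(Y, f, pooled_sample_variance(Y), 2), 1.05)
  set.seed(21)
  for (k in 1:100) {
    inst <- random_instance(m = sample(5:30, 1), n = sample(2:6, 1))
    noise <- pooled_sample_variance(inst$Y)
    a <- r2_er(inst$Y, inst$nu, noise)$r2_er
    b <- r2_er_linear(inst$Y, fit_predictions(inst$Y, inst$nu), noise,
                      ncol(inst$Y))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("linear-model form collapses to 1 - SSres/SStot at zero noise", {
  inst <- with_seed_local(31, random_instance())
  ybar <- rowMeans(inst$Y)
  f <- fit_predictions(ybar, inst$nu)
  got <- r2_er_linear(ybar, f, noise_estimate(0, "assumed"), ncol(inst$Y))
  expect_equal(got, 1 - sum((ybar - f$nu)^2) / sum((ybar - mean(ybar))^2),
               tolerance = 1e-12)
  expect_error(r2_er_linear(ybar, predictions(inst$nu, dof = 10),
                            assumed_noise(), 4), "residual degrees")
})

test_that("numerator and denominator corrections are unbiased (Monte Carlo)", {
  set.seed(42)
  m <- 12; n <- 3; sigma2 <- 0.5
  mu <- sin(seq_len(m)); nu <- cos(seq_len(m))
  target_num <- sum((nu - mean(nu)) * (mu - mean(mu)))^2
  target_den <- sum((nu - mean(nu))^2) * sum((mu - mean(mu))^2)
  sims <- t(vapply(1:10000, function(k) {
    Y <- matrix(rnorm(m * n, mu, sqrt(sigma2)), m)
    fit <- r2_er(Y, nu)
    c(fit$numerator, fit$denominator)
  }, numeric(2)))
  se_num <- sd(sims[, 1]) / sqrt(nrow(sims))
  se_den <- sd(sims[, 2]) / sqrt(nrow(sims))
  expect_lt(abs(mean(sims[, 1]) - target_num), 3 * se_num)
  expect_lt(abs(mean(sims[, 2]) - target_den), 3 * se_den)
})

test_that("mean naive r^2 follows the ratio-of-expectations approximation", {
  # moderate-SNR regime where the approximation is stated to hold
  cfg <- sim_config(362, 4, 0.25, snr = 0.25, r2_er_true = 0.75)
  sw <- sim_sweep(cfg, "r2_naive", reps = 400, seed = 77)
  tc <- make_tuning(cfg)
  ssm <- sum((tc$mu - mean(tc$mu))^2)
  ssn <- sum((tc$nu - mean(tc$nu))^2)
  cv <- sum((tc$nu - mean(tc$nu)) * (tc$mu - mean(tc$mu)))^2
  corr <- cfg$sigma2 / cfg$n
  approx <- (cv + corr * ssn) / (ssn * ssm + corr * (cfg$m - 1) * ssn)
  expect_lt(abs(sw$mean - approx), 0.02)
})

test_that("corrected estimator is consistent in m while the naive one is not", {
  ests <- c("r2_naive", "r2_er")
  sw_small <- sim_sweep(sim_config(50, 4, 0.25, snr = 0.5, r2_er_true = 0.75),
                        ests, reps = 400, seed = 5)
  sw_big <- sim_sweep(sim_config(2000, 4, 0.25, snr = 0.5, r2_er_true = 0.75),
                      ests, reps = 150, seed = 6)
  bias <- function(sw, e) abs(sw$mean[sw$estimator == e] - 0.75)
  expect_lt(bias(sw_big, "r2_er"), bias(sw_small, "r2_er"))
  expect_gt(bias(sw_big, "r2_naive"), 0.1)   # persistent naive bias
  expect_lt(bias(sw_big, "r2_er"), 0.02)
})
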