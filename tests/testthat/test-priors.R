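test_that("upsilon matches the hand evaluation and its degrees-of-freedom guard", {
  Y <- toy_Y()
  f <- fit_predictions(Y, toy_nu())
  # variance of the sample mean = s^2/n = 1 for the toy matrix
  expect_equal(upsilon(Y, f), 1 - (2 / 3 - 3) / (26 / 3 - 6))  # = 1.875
  expect_equal(upsilon(Y, f), 1.875)
  expect_error(upsilon(rbind(c(1, 2), c(3, 4)), predictions(c(0, 1), 1)),
               "m\\(n-1\\)")
})

test_that("upsilon converges to the chi-squared form as noise dof grow", {
  inst <- with_seed_local(5, random_instance(m = 500, n = 10))
  f <- fit_predictions(inst$Y, inst$nu)
  u <- upsilon(inst$Y, f)
  r <- r2_er_linear(inst$Y, f, pooled_sample_variance(inst$Y), 10)
  expect_lt(abs(u - r), 1e-3)
})

test_that("normalized signal power explained matches the hand evaluation", {
  Y <- toy_Y()
  f <- fit_predictions(Y, toy_nu())
  expect_equal(spe_norm(Y, f), 12 / 13)
})

test_that("SPE_norm and CC^2_norm-SP are numerically identical", {
  set.seed(8)
  for (k in 1:100) {
    inst <- random_instance(m = sample(5:25, 1), n = sample(2:6, 1))
    if (naive_r2(inst$Y, inst$nu) < 1e-3) next  # cancellation-degenerate
    f <- fit_predictions(inst$Y, inst$nu)
    expect_equal(spe_norm(inst$Y, f), cc_norm_sp2(inst$Y, f),
                 tolerance = 1e-10)
  }
})

test_that("zero-noise data gives ceiling 1 for all ceiling-based methods", {
  mu <- c(1, 3, 2, 5, 4, 6)
  Y <- response_matrix(cbind(mu, mu, mu, mu))   # identical repeats
  nu <- c(0.9, 3.2, 1.8, 5.1, 4.2, 5.9)
  r2n <- naive_r2(Y, nu)
  for (mth in c("cc_norm_split2", "r2_norm_split_sb", "cc_norm_pb")) {
    rep <- resampled_ceiling(Y, nu, mth, resamples = 20, seed = 4)
    expect_equal(rep$value, r2n, tolerance = 1e-10)
  }
  expect_equal(pc_ratio(Y, nu), r2n, tolerance = 1e-12)
  # zero noise: FEVE reduces to the plain trial-level fraction of variance
  f <- fit_predictions(Y, nu)
  expect_equal(feve(Y, f),
               1 - sum((Y - f$nu)^2) / sum((Y - mean(Y))^2), tolerance = 1e-12)
})

test_that("zero-noise perfect model scores 1 under every estimator", {
  mu <- sin(seq_len(12))
  Y <- response_matrix(cbind(mu, mu, mu, mu))
  tab <- compare_estimators(Y, mu, seed = 2)
  expect_true(all(is.na(tab$error)))
  expect_equal(tab$value, rep(1, nrow(tab)), tolerance = 1e-8)
})

test_that("resampled ceilings are deterministic given the seed", {
  inst <- with_seed_local(77, random_instance(m = 20, n = 6))
  a <- resampled_ceiling(inst$Y, inst$nu, "cc_norm_split2", 50, seed = 5)
  b <- resampled_ceiling(inst$Y, inst$nu, "cc_norm_split2", 50, seed = 5)
  c <- resampled_ceiling(inst$Y, inst$nu, "cc_norm_split2", 50, seed = 6)
  expect_identical(a$value, b$value)
  expect_false(identical(a$value, c$value))
  expect_error(resampled_ceiling(matrix(1:3, 3, 1), c(0, 1, 2),
                                 "cc_norm_split2"), "n >= 2")
})

test_that("the comparison table collects per-method failures without aborting", {
  tab <- compare_estimators(toy_Y(), toy_nu(), seed = 1)
  expect_equal(tab$value[tab$method == "r2_naive"], 12 / 13)
  expect_equal(tab$value[tab$method == "r2_er"], 1.05)
  expect_equal(tab$value[tab$method == "spe_norm"], 12 / 13)
  # upsilon needs m(n-1) > 2; for the toy matrix m(n-1) = 3 so it runs
  expect_equal(tab$value[tab$method == "upsilon"], 1.875)
  expect_true(all(tab$resamples[tab$method %in%
    c("cc_norm_split2", "r2_norm_split_sb", "cc_norm_pb")] > 0))
  expect_true(all(tab$resamples[tab$method %in% c("r2_er", "spe_norm")] == 0))
})
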