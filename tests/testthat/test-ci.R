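make_draws <- function(sigma2, d2) {
  structure(list(sigma2 = sigma2, d2 = d2, chain_length = length(sigma2),
                 accept_rate = 1), class = "posterior_draws")
}

test_that("sufficient statistics match hand values and their expectations", {
  st <- sufficient_stats(toy_Y())
  expect_equal(st$s_hat2, 2)
  expect_equal(st$d_hat2, 13 / 3)
  st0 <- sufficient_stats(matrix(5, 4, 3))
  expect_equal(c(st0$s_hat2, st0$d_hat2), c(0, 0))

  set.seed(3)
  m <- 30; n <- 4; sigma2 <- 0.25; d2 <- 0.25
  mu <- make_tuning(sim_config(m, n, sigma2, d2 = d2, r2_er_true = 1))$mu
  sims <- t(vapply(1:2000, function(k) {
    st <- sufficient_stats(matrix(rnorm(m * n, mu, sqrt(sigma2)), m))
    c(st$s_hat2, st$d_hat2)
  }, numeric(2)))
  expect_lt(abs(mean(sims[, 1]) - sigma2), 3 * sd(sims[, 1]) / sqrt(2000))
  # E[d_hat2] = m d^2/(m-1) + sigma^2/n exactly (the m-1 denominator
  # inflates the m-normalized dynamic range)
  expect_lt(abs(mean(sims[, 2]) - (m * d2 / (m - 1) + sigma2 / n)),
            3 * sd(sims[, 2]) / sqrt(2000))
})

test_that("the posterior concentrates on the estimates when data are informative", {
  Y <- simulate_responses(sim_config(200, 50, 0.25, d2 = 0.25,
                                     r2_er_true = 0.5, seed = 10))
  st <- sufficient_stats(Y)
  dr <- posterior_draws(st$s_hat2, st$d_hat2, 200, 50, n_draws = 3000, seed = 2)
  expect_lt(abs(mean(dr$sigma2) - st$s_hat2) / st$s_hat2, 0.05)
  expect_gt(dr$accept_rate, 0.05)
  expect_true(all(dr$sigma2 > 0) && all(dr$d2 >= 0))
  expect_error(posterior_draws(0, 1, 10, 4), "improper")
})

test_that("corrected-ratio chain matches a dense grid evaluation of the posterior", {
  Y <- simulate_responses(sim_config(40, 4, 0.25, d2 = 0.25,
                                     r2_er_true = 0.5, seed = 11))
  st <- sufficient_stats(Y)
  ll <- function(s2, d2)
    r2er:::loglik_stats(s2, d2, st$s_hat2, st$d_hat2, 40, 4)
  nb <- 12L; fine <- 10L
  es <- seq(st$s_hat2 * 0.45, st$s_hat2 * 2.2, length.out = nb * fine)
  ed <- seq(0, st$d_hat2 * 3.5, length.out = nb * fine)
  L <- outer(es, ed, Vectorize(function(a, b) exp(ll(a, b))))
  agg <- function(M) {
    o <- matrix(0, nb, nb)
    for (i in 1:nb) for (j in 1:nb)
      o[i, j] <- sum(M[((i - 1) * fine + 1):(i * fine),
                       ((j - 1) * fine + 1):(j * fine)])
    o
  }
  P <- agg(L); P <- P / sum(P)
  edges_s <- seq(min(es), max(es), length.out = nb + 1)
  edges_d <- seq(min(ed), max(ed), length.out = nb + 1)
  tv_of <- function(dr) {
    stopifnot(mean(dr$sigma2 >= min(es) & dr$sigma2 <= max(es) &
                     dr$d2 <= max(ed)) > 0.999)
    bs <- pmin(pmax(findInterval(dr$sigma2, edges_s, all.inside = TRUE), 1), nb)
    bd <- pmin(pmax(findInterval(dr$d2, edges_d, all.inside = TRUE), 1), nb)
    H <- matrix(0, nb, nb)
    for (k in seq_along(bs)) H[bs[k], bd[k]] <- H[bs[k], bd[k]] + 1
    0.5 * sum(abs(H / sum(H) - P))
  }
  tv_corrected <- tv_of(posterior_draws(st$s_hat2, st$d_hat2, 40, 4,
                                        n_draws = 5000, seed = 2,
                                        corrected = TRUE))
  expect_lt(tv_corrected, 0.1)
  # the plain likelihood-ratio rule targets a proposal-weighted distribution;
  # its deviation from the exact posterior is visible on the same grid
  tv_plain <- tv_of(posterior_draws(st$s_hat2, st$d_hat2, 40, 4,
                                    n_draws = 5000, seed = 2))
  expect_gt(tv_plain, tv_corrected)
})

test_that("the estimator distribution collapses to the candidate at zero noise", {
  dr <- make_draws(rep(1e-10, 100), rep(0.25, 100))
  for (cand in c(0.2, 0.7, 1)) {
    x <- sample_estimator_given_r2(cand, dr, m = 30, n = 4, N = 200, seed = 1)
    expect_lt(max(abs(x - cand)), 1e-3)
  }
})

test_that("the sampled CDF at the observed value decreases in the candidate", {
  Y <- simulate_responses(sim_config(40, 4, 0.25, d2 = 0.25,
                                     r2_er_true = 0.5, seed = 12))
  st <- sufficient_stats(Y)
  dr <- posterior_draws(st$s_hat2, st$d_hat2, 40, 4, n_draws = 2000, seed = 3)
  obs <- r2_er(Y, attr(Y, "nu"))$r2_er
  cands <- seq(0, 1, by = 0.125)
  Fs <- vapply(cands, function(cand)
    mean(sample_estimator_given_r2(cand, dr, 40, 4, N = 2500,
                                   seed = 40 + round(100 * cand)) <= obs),
    numeric(1))
  # allow tiny Monte-Carlo wiggles but require an overall decreasing profile
  expect_true(all(diff(Fs) < 0.03))
  expect_gt(Fs[1], Fs[length(Fs)])
})

test_that("ECCI is deterministic, ordered, and refuses improper posteriors", {
  Y <- simulate_responses(sim_config(40, 4, 0.25, d2 = 0.25,
                                     r2_er_true = 0.75, seed = 13))
  nu <- attr(Y, "nu")
  ci1 <- ecci(Y, nu, seed = 5, n_samples = 800, chain_length = 1000)
  ci2 <- ecci(Y, nu, seed = 5, n_samples = 800, chain_length = 1000)
  expect_identical(ci1[c("low", "high")], ci2[c("low", "high")])
  expect_lte(ci1$low, ci1$high)
  expect_gte(ci1$low, 0); expect_lte(ci1$high, 1)
  expect_false(ci1$empty)
  expect_error(ecci(matrix(rep(1:5, 3), 5, 3), c(1, 2, 3, 4, 5)),
               "improper|identical")
})

test_that("ECCI endpoints are monotone in the observed estimate", {
  Y <- simulate_responses(sim_config(40, 4, 0.25, d2 = 0.25,
                                     r2_er_true = 0.5, seed = 14))
  st <- sufficient_stats(Y)
  dr <- posterior_draws(st$s_hat2, st$d_hat2, 40, 4, n_draws = 2000, seed = 6)
  cis <- lapply(c(0.3, 0.6, 0.9), function(obs)
    r2er:::ecci_from_draws(obs, dr, 40, 4, alpha = 0.8, seed = 7,
                           n_samples = 1500, max_splits = 60))
  lows <- vapply(cis, `[[`, numeric(1), "low")
  highs <- vapply(cis, `[[`, numeric(1), "high")
  expect_true(all(diff(lows) > -0.02))
  expect_true(all(diff(highs) > -0.02))
})

test_that("bootstrap intervals are deterministic and handle zero-noise data", {
  mu <- sin(seq_len(20))
  Yz <- response_matrix(cbind(mu, mu, mu, mu))
  for (mth in c("npboot", "pboot", "bca")) {
    ci <- bootstrap_ci(Yz, mu, method = mth, B = 150, seed = 3)
    expect_equal(ci$low, ci$high)
    expect_equal(ci$low, 1, tolerance = 1e-8)
  }
  Y <- simulate_responses(sim_config(30, 4, 0.25, d2 = 0.25,
                                     r2_er_true = 0.75, seed = 15))
  a <- bootstrap_ci(Y, attr(Y, "nu"), "pboot", B = 200, seed = 9)
  b <- bootstrap_ci(Y, attr(Y, "nu"), "pboot", B = 200, seed = 9)
  expect_identical(a[c("low", "high")], b[c("low", "high")])
  expect_lte(a$low, a$high)
  expect_gte(a$low, 0); expect_lte(a$high, 1)
})
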