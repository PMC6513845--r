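test_that("moment matching solves the lognormal identities and round-trips", {
  # mean 2, sd 2: sigma^2 = log 2, mu = log(2) - log(2)/2 (closed-form identities)
  s <- lognormal_from_moments(2, 2)
  expect_equal(s$sdlog^2, log(2))
  expect_equal(s$meanlog, log(2) / 2)
  # degenerate point mass
  s0 <- lognormal_from_moments(2, 0)
  expect_equal(s0$sdlog, 0)
  expect_equal(s0$meanlog, log(2))
  # round trip on arbitrary (m, s): analytic moments recover inputs
  for (ms in list(c(2.8, 2.8), c(0.5, 0.1), c(17.8, 15.8))) {
    sp <- lognormal_from_moments(ms[1], ms[2])
    expect_equal(dist_mean(sp), ms[1], tolerance = 1e-12)
    expect_equal(dist_sd(sp), ms[2], tolerance = 1e-12)
  }
  expect_error(lognormal_from_moments(-1, 1), "positive")
})

test_that("GM/GSD parameterization is exact and rejects gsd < 1", {
  s <- lognormal_from_gm_gsd(3.14, 1.80)
  expect_equal(s$meanlog, log(3.14))
  expect_equal(s$sdlog, log(1.80))
  expect_equal(dist_gm(s), 3.14)
  expect_equal(dist_gsd(s), 1.80)
  # gsd 1: point mass at gm
  expect_equal(dist_sample(lognormal_from_gm_gsd(5, 1), 4, seed = 1), rep(5, 4))
  expect_error(lognormal_from_gm_gsd(3, 0.9), ">= 1")
})

test_that("sampling is seed-reproducible and honors truncation bounds", {
  sp <- norm_spec(5.9, 2.6, lower = 0, upper = 24)
  a <- dist_sample(sp, 1000, seed = 11)
  b <- dist_sample(sp, 1000, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, dist_sample(sp, 1000, seed = 12)))
  # exhaustive scan of a large truncated draw
  big <- dist_sample(norm_spec(12, 15, lower = 0, upper = 24), 1e5, seed = 3)
  expect_gte(min(big), 0)
  expect_lte(max(big), 24)
  tl <- dist_sample(lnorm_spec(0, 1, upper = 2), 1e4, seed = 4)
  expect_lte(max(tl), 2)
  # sigma-0 specs are point masses
  expect_equal(dist_sample(lnorm_spec(log(3), 0), 5, seed = 1), rep(3, 5))
  expect_equal(dist_sample(norm_spec(7, 0), 5, seed = 1), rep(7, 5))
})

test_that("sample moments converge to the analytic moments", {
  sp <- lognormal_from_moments(2.8, 2.8)
  x <- dist_sample(sp, 1e5, seed = 21)
  se <- dist_sd(sp) / sqrt(length(x))
  expect_lt(abs(mean(x) - dist_mean(sp)), 3 * se)
  # truncated normal: sample mean matches the closed-form truncated mean
  tn <- norm_spec(5.9, 2.6, lower = 0, upper = 24)
  y <- dist_sample(tn, 1e5, seed = 22)
  expect_lt(abs(mean(y) - dist_mean(tn)), 3 * dist_sd(tn) / sqrt(length(y)))
})

test_that("quantiles are monotone, match closed forms, and validate p", {
  expect_equal(dist_quantile(lnorm_spec(0, 1), 0.5), 1) # median = e^mu
  expect_equal(dist_quantile(norm_spec(0, 1), 0.975), 1.959964, tolerance = 1e-6)
  p <- seq(0.05, 0.95, by = 0.05)
  q <- dist_quantile(lnorm_spec(0.5, 0.7, upper = 3), p)
  expect_true(all(diff(q) > 0))
  expect_lte(max(q), 3)
  expect_error(dist_quantile(lnorm_spec(0, 1), 1), "inside")
  expect_error(dist_quantile(lnorm_spec(0, 1), 0), "inside")
  # percentile estimator converges on the closed-form quantile
  x <- dist_sample(lnorm_spec(1, 0.6), 1e5, seed = 31)
  expect_equal(
    quantile(x, 0.95, type = 7, names = FALSE),
    dist_quantile(lnorm_spec(1, 0.6), 0.95),
    tolerance = 0.02
  )
})

test_that("Latin hypercube draws place exactly one point per stratum", {
  sp <- unif_spec(2, 4)
  for (n in c(1, 7, 100)) {
    x <- lhs_uniform(sp, n, seed = 5)
    expect_length(x, n)
    stratum <- floor((x - 2) / (2 / n))
    expect_setequal(stratum, 0:(n - 1))
  }
  x <- lhs_uniform(sp, 100, seed = 6)
  # mean within the exact stratum-midpoint bound: each draw is within
  # half a stratum width of its midpoint, so |mean - 3| <= 0.01
  expect_lte(abs(mean(x) - 3), 2 / 100)
  expect_identical(lhs_uniform(sp, 50, seed = 9), lhs_uniform(sp, 50, seed = 9))
})

test_that("products of independent lognormals match the closed form", {
  # mu_prod = mu1 + mu2, sigma_prod = sqrt(s1^2 + s2^2); sampled 95th of the
  # product agrees with the closed-form quantile at Monte-Carlo accuracy
  a <- lnorm_spec(0.3, 0.5)
  b <- lnorm_spec(-0.2, 0.8)
  x <- dist_sample(a, 1e5, seed = 41) * dist_sample(b, 1e5, seed = 42)
  closed <- dist_quantile(lnorm_spec(0.1, sqrt(0.5^2 + 0.8^2)), 0.95)
  expect_equal(quantile(x, 0.95, type = 7, names = FALSE), closed, tolerance = 0.02)
})

test_that("log-scale MLE fit recovers generating parameters", {
  gen <- lognormal_from_gm_gsd(2.5, 1.6)
  fit <- fit_lognormal(dist_sample(gen, 1e4, seed = 51))
  expect_equal(dist_gm(fit), 2.5, tolerance = 0.05)
  expect_equal(dist_gsd(fit), 1.6, tolerance = 0.05)
  expect_error(fit_lognormal(c(1, -2, 3)), "positive")
})
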