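test_that("DI reduces to the scalar formula for point inputs", {
  # 2.4 ng/m3 * 10 m3/day * 12 h / 24 h = 12.0 ng/day
  sim <- simulate_di(2.4, point_group(ir = 10, et = 12), n = 50, seed = 1)
  expect_equal(tidy(sim)$di, rep(12, 50))
  # full-day exposure limit: DI = TEQ_draw * IR exactly
  teq <- lognormal_from_moments(2.8, 2.8)
  sim24 <- simulate_di(teq, point_group(ir = 10, et = 24), n = 500, seed = 2)
  expect_equal(tidy(sim24)$di, tidy(sim24)$teq * 10)
})

test_that("sampled DI median converges to the scaled lognormal median", {
  teq <- lnorm_spec(log(2.5), 0.6)
  grp <- point_group(ir = 16, et = 4)
  sim <- simulate_di(teq, grp, n = 1e5, seed = 3)
  closed <- exp(log(2.5)) * 16 * 4 / 24
  expect_equal(glance(sim)$median, closed, tolerance = 0.02)
})

test_that("ILCR with all inputs degenerate equals the hand-computed scalar", {
  sim <- simulate_ilcr(1, point_group(), n = 100, seed = 1)
  # independent single-line arithmetic: TEQ 1000 pg/m3, IR 10, CF 1e-9,
  # ED 70 y, ET 24 h/d, EF 365 d/y, CSF 3.14, BW 60 kg, AT 70*365*24 h
  expected <- (1000 * 10 * 1e-9 * 70 * 24 * 365) * 3.14 / (60 * 70 * 365 * 24)
  expect_equal(tidy(sim)$ilcr, rep(expected, 100), tolerance = 1e-14)
  # linearity in TEQ; reciprocal linearity in BW
  double_teq <- simulate_ilcr(2, point_group(), n = 100, seed = 1)
  expect_equal(tidy(double_teq)$ilcr, 2 * tidy(sim)$ilcr)
  double_bw <- simulate_ilcr(1, point_group(bw = 120), n = 100, seed = 1)
  expect_equal(tidy(double_bw)$ilcr, tidy(sim)$ilcr / 2)
})

test_that("with only TEQ stochastic the 95th ILCR matches the closed form", {
  teq <- lognormal_from_moments(2.8, 2.8)
  grp <- point_group(ir = 16.5, et = 3.4, ed = 30, bw = 60.5)
  sim <- simulate_ilcr(teq, grp, n = 1e5, seed = 4)
  const <- scalar_ilcr(1, ir = 16.5, et = 3.4, ed = 30, bw = 60.5)
  expect_equal(
    percentile_95(sim),
    const * dist_quantile(teq, 0.95),
    tolerance = 0.02
  )
})

test_that("the 95th percentile uses the type-7 quantile rule", {
  sim <- structure(
    list(samples = tibble::tibble(ilcr = as.numeric(1:100)), type = "ilcr"),
    class = "risk_sim"
  )
  # type-7 by hand: h = 99*0.95 + 1 = 95.05 -> x[95] + 0.05*(x[96]-x[95])
  expect_equal(percentile_95(sim), 95.05)
  const <- structure(
    list(samples = tibble::tibble(ilcr = rep(3.3, 10)), type = "ilcr"),
    class = "risk_sim"
  )
  expect_equal(percentile_95(const), 3.3)
  empty <- structure(
    list(samples = tibble::tibble(ilcr = numeric(0)), type = "ilcr"),
    class = "risk_sim"
  )
  expect_error(percentile_95(empty), "at least two")
})

test_that("risk bands split at 1e-6 and 1e-4 with boundaries in 'potential'", {
  expect_equal(as.character(classify_risk(4.8e-7)), "acceptable")
  expect_equal(as.character(classify_risk(1e-5)), "potential")
  expect_equal(as.character(classify_risk(2e-4)), "concern")
  expect_equal(as.character(classify_risk(c(1e-6, 1e-4))), rep("potential", 2))
  expect_error(classify_risk(-1e-7), "non-negative")
})

test_that("the 95th ILCR is monotone in each exposure factor (paired seeds)", {
  teq <- lognormal_from_moments(2.8, 2.8)
  base_args <- list(
    ir = 16, et = 4, bw = 60, ed = 30, ef = 300, csf = 3.14,
    at_hours = 70 * 365 * 24
  )
  p95_of <- function(args, teq_spec = teq) {
    grp <- do.call(point_group, args)
    percentile_95(simulate_ilcr(teq_spec, grp, n = 2000, seed = 10))
  }
  base <- p95_of(base_args)
  up <- function(name, f = 1.5) {
    args <- base_args
    args[[name]] <- args[[name]] * f
    p95_of(args)
  }
  for (v in c("ir", "ed", "csf")) expect_gte(up(v), base)
  expect_gte(up("ef", 1.2), base)
  expect_gte(up("et", 1.2), base)
  expect_lte(up("bw", 2), base)
  expect_lte(up("at_hours", 2), base)
  # scaling the TEQ spec up never lowers the 95th
  teq_up <- lnorm_spec(teq$meanlog + log(2), teq$sdlog)
  expect_gte(p95_of(base_args, teq_up), base)
})

test_that("DI and ILCR share draws: perfect rank correlation when CSF/BW fixed", {
  teq <- lognormal_from_moments(2.8, 2.8)
  grp <- population_group("HZ", "adult", "total",
    ir = 16, et = norm_spec(4, 2, 0, 24), bw = 60, ed = 30, csf = 3.14
  )
  di <- simulate_di(teq, grp, n = 3000, seed = 17)
  il <- simulate_ilcr(teq, grp, n = 3000, seed = 17)
  expect_equal(tidy(di)$teq, tidy(il)$teq)
  expect_equal(tidy(di)$et, tidy(il)$et)
  expect_equal(cor(rank(tidy(di)$di), rank(tidy(il)$ilcr)), 1)
})

test_that("seasonal TEQ ordering propagates to median DI", {
  specs <- list(
    winter = lnorm_spec(log(4.4), 0.4),
    spring = lnorm_spec(log(1.7), 0.4),
    autumn = lnorm_spec(log(1.6), 0.4),
    summer = lnorm_spec(log(1.4), 0.4)
  )
  grp <- population_group("HZ", "adult", "total",
    ir = 16, et = norm_spec(4, 2, 0, 24), bw = 60, ed = 30
  )
  med <- vapply(
    specs,
    function(s) glance(simulate_di(s, grp, n = 2000, seed = 19))$median,
    numeric(1)
  )
  expect_gt(med[["winter"]], max(med[c("spring", "autumn")]))
  expect_gt(min(med[c("spring", "autumn")]), med[["summer"]])
})

test_that("population groups validate their exposure factors", {
  expect_error(point_group(ir = -1), "ir")
  expect_error(point_group(et = 25), "\\(0, 24\\]")
  expect_error(point_group(ef = 400), "366")
  expect_error(
    population_group("HZ", "adult", "total",
      ir = 16, et = 4, bw = norm_spec(60, 5), ed = 30
    ),
    "point body weight"
  )
  # years -> hours conversion is explicit
  grp <- point_group()
  expect_equal(grp$at_hours, 70 * 365 * 24)
  grp2 <- population_group("HZ", "adult", "total",
    ir = 16, et = 4, bw = 60, ed = 30, at_years = 25
  )
  expect_equal(grp2$at_hours, 25 * 365 * 24)
})
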