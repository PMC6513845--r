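test_that("TEQ follows the TEF-weighted sum definition", {
  # BaP alone at 1 ng/m3 defines one BaP-equivalent unit
  expect_equal(compute_teq(tiny_table(c(BaP = 1)))$teq_ng_m3, 1)
  expect_equal(compute_teq(tiny_table(c(BaP = 0, Chr = 0)))$teq_ng_m3, 0)
  # hand-summed: 2*1 + 10*0.1 + 1*1 = 4 with a test TEF table where DBA = 1
  tefs <- default_tef_table(dba_tef = 1)
  teq <- compute_teq(tiny_table(c(BaP = 2, BaA = 10, DBA = 1)), tefs)
  expect_equal(teq$teq_ng_m3, 4)
  # missing TEF errors naming the congener
  expect_error(
    compute_teq(tiny_table(c(BaP = 1, Nap = 1)), tefs[tefs$congener != "Nap", ]),
    "Nap"
  )
})

test_that("the TEF table is validated: positive values, TEF(BaP) = 1", {
  tefs <- default_tef_table()
  expect_equal(nrow(tefs), 16)
  expect_equal(tefs$tef[tefs$congener == "BaP"], 1)
  bad <- dplyr::mutate(tefs, tef = dplyr::if_else(congener == "BaP", 0.5, tef))
  expect_error(compute_teq(tiny_table(c(BaP = 1)), bad), "TEF\\(BaP\\)")
  expect_equal(default_tef_table(dba_tef = 5)$tef[14], 5)
})

test_that("TEQ is linear and bounded by TEF extremes times total mass", {
  withr::local_seed(8)
  conc_a <- stats::setNames(runif(16, 0.1, 2), pah_congeners()$congener)
  conc_b <- stats::setNames(runif(16, 0.1, 2), pah_congeners()$congener)
  teq_of <- function(conc) compute_teq(tiny_table(conc))$teq_ng_m3
  expect_equal(teq_of(2 * conc_a + 3 * conc_b), 2 * teq_of(conc_a) + 3 * teq_of(conc_b))
  tefs <- default_tef_table()
  expect_lte(teq_of(conc_a), max(tefs$tef) * sum(conc_a))
  expect_gte(teq_of(conc_a), min(tefs$tef) * sum(conc_a))
})

test_that("swapping TEF schemes rescales congener-wise (explicit-loop oracle)", {
  withr::local_seed(9)
  conc <- stats::setNames(runif(16, 0.1, 2), pah_congeners()$congener)
  tab <- tiny_table(conc)
  alt <- dplyr::mutate(
    default_tef_table(),
    tef = dplyr::if_else(congener == "BaP", 1, tef * 2.5)
  )
  oracle <- 0
  for (i in seq_len(nrow(alt))) {
    oracle <- oracle + conc[[alt$congener[i]]] * alt$tef[i]
  }
  expect_equal(compute_teq(tab, alt)$teq_ng_m3, oracle)
})

test_that("TEQ group summaries use mean and n-1 SD", {
  mk <- function(vals) {
    congener_table(tibble::tibble(
      sample_id = paste0("s", seq_along(vals)), city = "HZ",
      date = as.Date("2015-06-15"), congener = "BaP", conc_ng_m3 = vals
    ))
  }
  s <- summarize_teq(compute_teq(mk(c(1, 3))), by = "annual")
  expect_equal(s$mean_teq, 2)
  expect_equal(s$sd_teq, sqrt(2))
  s2 <- summarize_teq(compute_teq(mk(rep(2.5, 4))), by = "annual")
  expect_equal(s2$mean_teq, 2.5)
  expect_equal(s2$sd_teq, 0)
})

test_that("ring-class shares are complementary and match trivial mixtures", {
  only_bap <- ring_class_fractions(tiny_table(c(BaP = 1)))
  expect_equal(only_bap$high_ring_share, 1)
  half <- ring_class_fractions(tiny_table(c(Nap = 1, BaP = 1)))
  expect_equal(half$high_ring_share, 0.5)
  expect_equal(half$low_ring_share + half$high_ring_share, 1)
})

test_that("diagnostic ratios come from group means with declared degeneracies", {
  tab <- tiny_table(c(Fle = 2, Pyr = 2, BaP = 1, Chr = 1, BghiP = 0))
  r <- diagnostic_ratios(tab)
  val <- function(which) r$value[r$ratio == which]
  expect_equal(val("Fle/Pyr"), 1)
  expect_equal(val("BaP/(BaP+Chr)"), 0.5)
  expect_true(is.na(val("BaP/BghiP"))) # zero denominator: undefined, no error
  # group means, not means of per-sample ratios
  tab2 <- congener_table(tibble::tibble(
    sample_id = rep(c("a", "b"), each = 2), city = "HZ",
    date = as.Date("2015-06-15"),
    congener = rep(c("Fle", "Pyr"), 2), conc_ng_m3 = c(1, 4, 3, 4)
  ))
  expect_equal(
    diagnostic_ratios(tab2)$value[diagnostic_ratios(tab2)$ratio == "Fle/Pyr"],
    mean(c(1, 3)) / mean(c(4, 4))
  )
})

test_that("source classification votes by majority with mixed/unclassified rules", {
  thresholds <- default_ratio_thresholds()
  mk_ratios <- function(v) {
    tibble::tibble(
      city = "X",
      ratio = c("Fle/Pyr", "BaP/BghiP", "BaP/(BaP+Chr)"),
      value = v
    )
  }
  # all three inside gasoline intervals
  all_gas <- classify_source(mk_ratios(c(0.8, 0.4, 0.6)), thresholds)
  expect_equal(unique(all_gas$consensus), "gasoline emission")
  # 2-vs-1 split -> majority
  split21 <- classify_source(mk_ratios(c(1.2, 0.7, 0.6)), thresholds)
  expect_equal(unique(split21$consensus), "coal combustion")
  # 3-way split -> mixed
  split3 <- classify_source(mk_ratios(c(0.8, 0.7, 0.4)), thresholds)
  expect_equal(unique(split3$consensus), "mixed")
  # value outside every interval -> unclassified
  neg <- classify_source(
    tibble::tibble(city = "X", ratio = "Fle/Pyr", value = -1), thresholds
  )
  expect_equal(neg$source, "unclassified")
  expect_error(
    classify_source(mk_ratios(c(0.8, 0.7, 0.4)), dplyr::mutate(thresholds, hi = lo)),
    "lo < hi"
  )
})
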