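mkFracTab <- function(cd4, lck = NULL, rep = 1L) {
  tab <- data.frame(replicate = rep, fraction = 1:10, channel = "CD4",
                    gmfi = cd4)
  if (!is.null(lck))
    tab <- rbind(tab, data.frame(replicate = rep, fraction = 1:10,
                                 channel = "Lck", gmfi = lck))
  tab
}

test_that("fraction background subtraction anchors fraction 1 at zero", {
  tab <- mkFracTab(seq(5, 50, by = 5))
  out <- backgroundSubtractFractions(tab)
  expect_equal(out$gmfi, seq(0, 45, by = 5))

  # all-equal channel collapses to zero
  out2 <- backgroundSubtractFractions(mkFracTab(rep(7, 10)))
  expect_true(all(out2$gmfi == 0))

  # sub-background values clamp to zero and are flagged
  tab3 <- mkFracTab(c(10, 3, rep(20, 8)))
  out3 <- backgroundSubtractFractions(tab3)
  expect_equal(out3$gmfi[out3$fraction == 2], 0)
  expect_equal(attr(out3, "clamped"), 1L)
})

test_that("percent of total sums to 100, is scale invariant, flags zero totals", {
  tab <- mkFracTab(c(0, rep(9, 9)))
  pct <- percentOfTotal(tab)
  expect_equal(sum(pct$pct), 100, tolerance = 1e-6)
  expect_equal(pct$pct[pct$fraction == 5], 100 / 9, tolerance = 1e-9)

  single <- mkFracTab(c(0, 0, 50, rep(0, 7)))
  pctS <- percentOfTotal(single)
  expect_equal(pctS$pct[pctS$fraction == 3], 100)

  doubled <- mkFracTab(2 * c(0, rep(9, 9)))
  expect_equal(percentOfTotal(doubled)$pct, pct$pct)

  zero <- mkFracTab(rep(0, 10))
  pz <- percentOfTotal(zero)
  expect_true(all(is.nan(pz$pct)))
  expect_equal(attr(pz, "zero_total"), "1")
})

test_that("channel normalization follows the percent-weighted ratio formula", {
  cd4 <- c(0, 10, 10, 10, 10, 0, 0, 0, 0, 0)
  lck <- c(0, 5, 20, 0, 10, 0, 0, 0, 0, 0)
  tab <- mkFracTab(cd4, lck)
  nm <- normalizeChannel(tab, "Lck")
  # fraction 3: 20 / 10 * 25 = 50
  expect_equal(nm$norm[nm$fraction == 3], 50)
  # channel identical to CD4 reproduces the percent curve
  tab2 <- mkFracTab(cd4, cd4)
  nm2 <- normalizeChannel(tab2, "Lck")
  pct <- percentOfTotal(tab2)
  expect_equal(nm2$norm, pct$pct * (cd4 > 0), tolerance = 1e-9)
  # zero channel gives a zero vector
  nm3 <- normalizeChannel(mkFracTab(cd4, rep(0, 10)), "Lck")
  expect_true(all(nm3$norm == 0))
})

test_that("fraction AUC matches closed forms and is additive and linear", {
  v <- c(0, 0, 1, 1, 0, 0, 0, 0, 0, 0)
  a <- fractionAuc(v)
  expect_equal(unname(a["auc_drm"]), 2.0)
  expect_equal(unname(a["auc_dsm"]), 0.0)

  vc <- rep(3, 10)
  expect_equal(unname(fractionAuc(vc)["auc_dsm"]), 4 * 3)
  expect_equal(unname(fractionAuc(rep(0, 10))), c(0, 0))

  # additivity over contiguous windows and linearity in values
  set.seed(2); w <- runif(10)
  full <- EvoMotif:::trapezoid(1:10, w)
  parts <- fractionAuc(w, drmRange = 1:6, dsmRange = 6:10)
  expect_equal(unname(sum(parts)), full, tolerance = 1e-12)
  expect_equal(unname(fractionAuc(2 * w)), unname(2 * fractionAuc(w)),
               tolerance = 1e-12)
})

test_that("dose-response summary computes AUC on log10 dose and sensitivity at 41 nM", {
  doses <- 30000 / 3^(0:6)
  expect_equal(round(min(doses)), 41)  # the low-dose sensitivity point
  tab <- expand.grid(dose_nM = doses, replicate = 1:3)
  tab$response <- 500
  s <- doseResponseSummary(tab)
  expect_equal(s$auc, 500 * 6 * log10(3), tolerance = 1e-9)
  expect_equal(s$sensitivity, 500)
  expect_equal(s$sensitivity_dose_nM, 30000 / 3^6)

  tab0 <- transform(tab, response = 0)
  s0 <- doseResponseSummary(tab0)
  expect_equal(s0$auc, 0)
  expect_equal(s0$sensitivity, 0)

  expect_warning(doseResponseSummary(data.frame(dose_nM = 100,
                                                replicate = 1,
                                                response = 5)), "AUC")
})

test_that("endocytosis deltas subtract stimulated values from the unstimulated mean", {
  expect_equal(endocytosisDelta(c(100, 100, 100), 60), 40)
  expect_equal(endocytosisDelta(c(80, 90, 100), c(90, 90)), c(0, 0))
  expect_equal(endocytosisDelta(c(50), 70), -20)
})

test_that("responder analysis reproduces the hand-worked histogram example", {
  edges <- c(0, 50, 150)
  h0 <- data.frame(bin_left = edges[-3], bin_right = edges[-1],
                   count = c(10000, 0))
  h1 <- data.frame(bin_left = edges[-3], bin_right = edges[-1],
                   count = c(7000, 3000))
  rs <- responderAnalysis(h0, h1, smoothK = 1)
  expect_equal(rs$n_responders, 3000)
  expect_equal(rs$pct_responders, 30.0)
  expect_equal(rs$responder_mean_intensity, 100)

  # identical histograms: no responders
  rs0 <- responderAnalysis(h0, h0)
  expect_equal(rs0$n_responders, 0)
  expect_equal(rs0$pct_responders, 0)
  expect_true(is.na(rs0$responder_mean_intensity))

  # invariant to adding identical counts to both histograms
  h0b <- transform(h0, count = count + 500)
  h1b <- transform(h1, count = count + 500)
  rsb <- responderAnalysis(h0b, h1b)
  expect_equal(rsb$n_responders, rs$n_responders)

  expect_error(responderAnalysis(h0, transform(h1, bin_left = bin_left + 1)),
               "binning error")
})
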