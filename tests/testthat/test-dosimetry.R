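# Gamma index and dose difference: analytic cases, exhaustive-search oracle,
# criterion nesting.

seededDosePair <- function(seed, n = 32, shiftMm = 0.4, scale = 1.01,
                           noiseFrac = 0.01) {
  ct <- generateAnatomy(tinyPhantomCfg(seed = seed, n = as.integer(n)), 0)
  generateDosePair(ct, list(shiftMm = shiftMm, scale = scale,
                            noiseFrac = noiseFrac), seed = seed)
}

test_that("gamma analytic cases behave as the criteria dictate", {
  dp <- seededDosePair(1, shiftMm = 0, scale = 1, noiseFrac = 0)
  g <- gammaMap(dp$reference, dp$evaluated, GammaCriteria(1, 1))
  expect_equal(max(g, na.rm = TRUE), 0)
  expect_equal(gammaPassRate(g), 1.0)

  # uniform 0.5% scaling passes 1%/1mm everywhere under global normalisation
  dpS <- seededDosePair(2, shiftMm = 0, scale = 1.005, noiseFrac = 0)
  gS <- gammaMap(dpS$reference, dpS$evaluated, GammaCriteria(1, 1))
  expect_lte(max(gS, na.rm = TRUE), 0.5 + 1e-9)
  expect_equal(gammaPassRate(gS), 1.0)

  # half-spacing shift at 1%/1mm: distance term alone stays at 0.5
  dpT <- seededDosePair(3, shiftMm = 0.5, scale = 1, noiseFrac = 0)
  gT <- gammaMap(dpT$reference, dpT$evaluated, GammaCriteria(1, 1))
  expect_equal(gammaPassRate(gT), 1.0)

  expect_error(gammaMap(dp$reference,
                        DoseGrid(dp$evaluated@values[1:16, 1:16]),
                        GammaCriteria()), "shape")
})

test_that("gamma map equals the exhaustive fine-grid oracle", {
  for (s in 1:5) {
    dp <- seededDosePair(100 + s)
    for (crit in list(GammaCriteria(1, 1), GammaCriteria(2, 2))) {
      g <- gammaMap(dp$reference, dp$evaluated, crit)
      o <- oracleGammaMap(dp$reference@values, dp$evaluated@values,
                          dp$reference@spacing, crit@doseDiffPct,
                          crit@dtaMm, crit@doseCutoffPct)
      expect_identical(is.na(g), is.na(o))
      expect_lt(max(abs(g - o), na.rm = TRUE), 1e-6)
      expect_equal(gammaPassRate(g), gammaPassRate(o))
    }
  }
})

test_that("uniform 2% scaling fails exactly where DTA cannot compensate", {
  # on a flat field there is no gradient for the DTA to exploit: a 2% offset
  # fails the 1% criterion at every point
  flat <- DoseGrid(matrix(1, 24, 24), role = "reference")
  ev <- DoseGrid(matrix(1.02, 24, 24), role = "evaluated")
  g <- gammaMap(flat, ev, GammaCriteria(1, 1))
  expect_equal(gammaPassRate(g), 0)
  expect_equal(min(g, na.rm = TRUE), 2, tolerance = 1e-9)

  # on a lobed field the same scaling is partially rescued near gradients;
  # the fast path must still agree with the exhaustive oracle, and points
  # below half the maximum pass on the dose term alone
  dp <- seededDosePair(7, shiftMm = 0, scale = 1.02, noiseFrac = 0)
  g2 <- gammaMap(dp$reference, dp$evaluated, GammaCriteria(1, 1))
  o <- oracleGammaMap(dp$reference@values, dp$evaluated@values,
                      dp$reference@spacing, 1, 1, 10)
  expect_lt(max(abs(g2 - o), na.rm = TRUE), 1e-6)
  lowHalf <- !is.na(g2) &
    dp$reference@values < 0.49 * max(dp$reference@values)
  expect_true(all(g2[lowHalf] <= 1))
})

test_that("criteria nest: 2%/2mm passes at least as often as 1%/1mm", {
  for (s in 1:5) {
    dp <- seededDosePair(200 + s, shiftMm = 0.6, scale = 1.012,
                         noiseFrac = 0.02)
    p11 <- gammaPassRate(gammaMap(dp$reference, dp$evaluated,
                                  GammaCriteria(1, 1)))
    p22 <- gammaPassRate(gammaMap(dp$reference, dp$evaluated,
                                  GammaCriteria(2, 2)))
    expect_gte(p22, p11)
  }
})

test_that("translation on a flat-gradient field passes within the DTA", {
  # linear ramp along rows, shifted by exactly the DTA
  n <- 40
  ramp <- matrix(rep(seq(0.2, 1, length.out = n), each = n), n, n,
                 byrow = TRUE)
  ref <- DoseGrid(ramp, role = "reference")
  shifted <- cbind(ramp[, 1], ramp[, -n])   # shift by one column (1 mm)
  ev <- DoseGrid(shifted, role = "evaluated")
  g <- gammaMap(ref, ev, GammaCriteria(1, 1))
  inner <- g[, 3:(n - 2)]
  expect_true(all(inner[!is.na(inner)] <= 1 + 1e-9))
})

test_that("dose difference matches its closed form and oracle", {
  dp <- seededDosePair(9, shiftMm = 0, scale = 1, noiseFrac = 0)
  expect_equal(doseDifference(dp$reference, dp$reference), 0)

  refv <- dp$reference@values
  ev <- DoseGrid(refv + 0.01 * max(refv), role = "evaluated")
  expect_equal(doseDifference(dp$reference, ev), 0.01, tolerance = 1e-12)

  dpN <- seededDosePair(10)
  sel <- refvN <- dpN$reference@values
  sel <- refvN >= 0.1 * max(refvN)
  acc <- 0; cnt <- 0
  for (i in seq_len(nrow(refvN))) for (j in seq_len(ncol(refvN))) {
    if (!sel[i, j]) next
    acc <- acc + abs(dpN$evaluated@values[i, j] - refvN[i, j])
    cnt <- cnt + 1
  }
  expect_equal(doseDifference(dpN$reference, dpN$evaluated),
               acc / cnt / max(refvN))
  expect_error(doseDifference(dpN$reference, dpN$evaluated,
                              cutoffPct = 1e6), "cutoff")
})
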