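# Head-phantom simulator: determinism, anatomy structure, artifact model.

test_that("anatomy generation is deterministic and head-like", {
  cfg <- tinyPhantomCfg(seed = 7L)
  a <- generateAnatomy(cfg, 0)
  b <- generateAnatomy(cfg, 0)
  expect_identical(a@values, b@values)

  v <- a@values
  # background is air by construction
  expect_true(all(v[1, ] == -1000))
  expect_true(all(v[, 1] == -1000))
  expect_true(all(v[nrow(v), ] == -1000))

  # at least two histogram modes separated by > 500 HU (air vs soft tissue)
  h <- hist(v, breaks = seq(-1024, 3072, by = 64), plot = FALSE)
  cnt <- h$counts
  peaks <- which(cnt > c(-1, head(cnt, -1)) & cnt >= c(tail(cnt, -1), -1) &
                   cnt > 0.005 * length(v))
  expect_gte(length(peaks), 2)
  expect_gt(diff(range(h$mids[peaks])), 500)

  # different cases differ
  expect_gt(maeHU(generateAnatomy(cfg, 1), a), 0)
  expect_error(generateAnatomy(cfg, cfg@nCases), "caseIndex")
})

test_that("CBCT corruption has the contracted artifact structure", {
  cfg0 <- tinyPhantomCfg(artifact = list(biasAmplitude = 0, scatterFraction = 0,
                                         noiseSigma = 0, huShift = 0))
  ct <- generateAnatomy(cfg0, 0)
  # identity limit: all amplitudes zero
  expect_equal(corruptToCBCT(ct, cfg0, seed = 3)@values, ct@values)

  # pure-noise moment check on a seeded draw over a 270x270 slice
  cfgN <- PhantomConfig(imageSize = 270L, seed = 5L, nCases = 1L,
                        artifact = list(biasAmplitude = 0,
                                        scatterFraction = 0,
                                        noiseSigma = 20, huShift = 0))
  ct270 <- generateAnatomy(cfgN, 0)
  cb <- corruptToCBCT(ct270, cfgN, seed = 9)
  resid <- cb@values - ct270@values
  inside <- ct270@values > -900            # avoid the clip at the air floor
  expect_gt(sd(resid[inside]), 18)
  expect_lt(sd(resid[inside]), 22)

  # bias alone already separates the images
  cfgB <- tinyPhantomCfg(artifact = list(biasAmplitude = 40,
                                         scatterFraction = 0,
                                         noiseSigma = 0, huShift = 0))
  expect_gt(maeHU(corruptToCBCT(ct, cfgB, seed = 3), ct), 0)

  # corruption never moves anatomy: cross-correlation peak at zero lag
  cfg <- tinyPhantomCfg()
  ct2 <- generateAnatomy(cfg, 1)
  cb2 <- corruptToCBCT(ct2, cfg, seed = 4)
  expect_equal(unname(sctforge:::.ccfPeak(ct2@values, cb2@values)), c(0L, 0L))
})

test_that("artifact magnitude is monotone in each amplitude", {
  base <- list(biasAmplitude = 30, biasScale = 24, scatterFraction = 0.02,
               noiseSigma = 8, huShift = 5)
  for (knob in c("biasAmplitude", "scatterFraction", "noiseSigma")) {
    lo <- base; hi <- base
    hi[[knob]] <- base[[knob]] * 3
    maeLo <- maeHo <- numeric(10)
    for (s in 1:10) {
      cfgL <- tinyPhantomCfg(seed = 100L + s, artifact = lo)
      cfgH <- tinyPhantomCfg(seed = 100L + s, artifact = hi)
      ct <- generateAnatomy(cfgL, 0)
      maeLo[s] <- maeHU(corruptToCBCT(ct, cfgL, seed = s), ct)
      maeHo[s] <- maeHU(corruptToCBCT(ct, cfgH, seed = s), ct)
    }
    expect_gte(mean(maeHo), mean(maeLo))
  }
})

test_that("dataset generation is reproducible and split is disjoint", {
  cfg <- tinyPhantomCfg(nCases = 13L)
  d1 <- generatePhantomDataset(cfg)
  d2 <- generatePhantomDataset(cfg)
  expect_identical(lapply(d1$samples, function(s) s@cbct@values),
                   lapply(d2$samples, function(s) s@cbct@values))
  man <- d1$manifest
  expect_setequal(man$split, c("train", "valid", "test"))
  expect_equal(anyDuplicated(man$caseId), 0L)
  expect_equal(nrow(man), 13)
})

test_that("dose-pair surrogate honours its perturbation contract", {
  ct <- featureRichSlice(seed = 3L, n = 64L)
  dp0 <- generateDosePair(ct, list(shiftMm = 0, scale = 1, noiseFrac = 0),
                          seed = 5)
  expect_equal(dp0$reference@values, dp0$evaluated@values)
  expect_equal(max(dp0$reference@values), 1)

  dpS <- generateDosePair(ct, list(shiftMm = 0, scale = 1.005,
                                   noiseFrac = 0), seed = 5)
  expect_equal(max(abs(dpS$evaluated@values - dpS$reference@values)) /
                 max(dpS$reference@values), 0.005, tolerance = 1e-12)

  expect_error(generateDosePair(ct, list(shiftMm = 1000), seed = 5),
               "extent")
})
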