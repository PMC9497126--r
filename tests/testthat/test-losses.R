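# Loss functions: closed forms, oracles, gradient checks.

test_that("L1 loss matches hand-computed values and a double-loop oracle", {
  expect_equal(l1Loss(matrix(1:4, 2), matrix(1:4, 2)), 0)
  x <- matrix(0, 2, 2)
  gx <- matrix(c(1, -1, 2, 0), 2, 2)
  expect_equal(l1Loss(x, gx), 1.0)

  set.seed(21)
  a <- matrix(rnorm(15 * 11), 15, 11)
  b <- matrix(rnorm(15 * 11), 15, 11)
  acc <- 0
  for (i in 1:15) for (j in 1:11) acc <- acc + abs(a[i, j] - b[i, j])
  expect_equal(l1Loss(a, b), acc / (15 * 11))
  expect_error(l1Loss(a, b[1:10, ]), "shape")

  # triangle-type bound on random triples
  for (k in 1:5) {
    x1 <- matrix(rnorm(36), 6); x2 <- matrix(rnorm(36), 6)
    x3 <- matrix(rnorm(36), 6)
    expect_lte(l1Loss(x1, x3), l1Loss(x1, x2) + l1Loss(x2, x3) + 1e-12)
  }
})

test_that("SSIM matches its closed forms and explicit moment evaluation", {
  img <- featureRichSlice(seed = 2L, n = 64L)@values
  expect_equal(ssimValue(img, img, list(dataRange = 3000)), 1.0)

  # constant images: sigma terms cancel, closed form remains
  a <- 0.4; b <- -0.2
  c1 <- (0.01 * 2)^2
  expect_equal(ssimValue(matrix(a, 9, 9), matrix(b, 9, 9),
                         list(window = "global")),
               (2 * a * b + c1) / (a^2 + b^2 + c1), tolerance = 1e-9)
  expect_equal(ssimValue(matrix(a, 9, 9), matrix(b, 9, 9),
                         list(window = "gaussian")),
               (2 * a * b + c1) / (a^2 + b^2 + c1), tolerance = 1e-9)

  # global window equals direct evaluation from raw moments
  set.seed(4)
  x <- matrix(rnorm(40 * 40, 0, 0.3), 40)
  p <- x + matrix(rnorm(40 * 40, 0, 0.1), 40)
  mx <- mean(x); mp <- mean(p)
  vx <- mean((x - mx)^2); vp <- mean((p - mp)^2)
  cxp <- mean((x - mx) * (p - mp))
  c2 <- (0.03 * 2)^2
  direct <- ((2 * mx * mp + c1) * (2 * cxp + c2)) /
    ((mx^2 + mp^2 + c1) * (vx + vp + c2))
  expect_equal(ssimValue(x, p, list(window = "global")), direct,
               tolerance = 1e-12)

  # symmetry and upper bound
  expect_equal(ssimValue(x, p), ssimValue(p, x))
  expect_lte(ssimValue(x, p), 1)
  expect_error(ssimValue(x, p, list(k1 = -1)), "positive")
})

test_that("SSIM loss decreases along a blend path toward the target", {
  x <- normalizeHU(featureRichSlice(seed = 5L, n = 64L)@values)
  set.seed(6)
  g0 <- x + matrix(rnorm(length(x), 0, 0.2), nrow(x))
  alphas <- seq(0, 1, length.out = 6)
  losses <- vapply(alphas, function(a)
    ssimLoss(x, (1 - a) * g0 + a * x), numeric(1))
  expect_equal(ssimLoss(x, x), 0, tolerance = 1e-9)
  expect_true(all(diff(losses) < 0))
})

test_that("perceptual loss is a reproducible symmetric feature distance", {
  E1 <- buildFeatureExtractor(seed = 99L)
  E2 <- buildFeatureExtractor(seed = 99L)
  expect_identical(E1$stages, E2$stages)
  expect_equal(E1$provenance, "seeded-random")

  x <- normalizeHU(featureRichSlice(seed = 8L, n = 64L)@values)
  set.seed(9)
  p <- x + matrix(rnorm(length(x), 0, 0.1), nrow(x))
  expect_equal(perceptualLoss(x, x, E1), 0)
  lp <- perceptualLoss(x, p, E1)
  expect_gt(lp, 0)
  expect_equal(perceptualLoss(p, x, E1), lp)
  expect_equal(perceptualLoss(x, p, E2), lp)
  # uniform offsets still pass the extractor: value computable and finite
  expect_true(is.finite(perceptualLoss(x, x + 0.05, E1)))
  expect_error(perceptualLoss(x, p, E1, layers = 9L), "layer")
})

test_that("combined loss reduces to its components and vanishes on equality", {
  x <- normalizeHU(featureRichSlice(seed = 3L, n = 64L)@values)
  set.seed(10)
  p <- x + matrix(rnorm(length(x), 0, 0.05), nrow(x))
  E <- defaultFeatureExtractor()
  for (tag in c("L1", "LP", "LS", "LPS")) {
    cl <- combinedLoss(x, x, LossConfig(tag), E)
    expect_lt(abs(cl$total), 1e-6)
  }
  l1only <- combinedLoss(x, p, LossConfig("L1"), E)
  expect_equal(l1only$total, l1Loss(x, p))
  lps <- combinedLoss(x, p, LossConfig("LPS"), E)
  expect_equal(lps$total,
               sum(lps$components[c("l1", "ssim", "perceptual")]))
  expect_error(LossConfig(useL1 = FALSE, useSSIM = FALSE,
                          usePerceptual = FALSE), "at least one")
})

test_that("training-loss gradients match finite differences", {
  set.seed(12)
  d <- c(16, 16, 1, 2)
  x <- array(rnorm(prod(d), 0, 0.3), d)
  p <- array(rnorm(prod(d), 0, 0.3), d)
  E <- defaultFeatureExtractor()
  eps <- 1e-5

  sg <- sctforge:::.ssimGlobalLossGrad(x, p, list())
  pg <- sctforge:::.perceptualLossGrad(x, p, E, c(1L, 2L))
  for (k in sample(prod(d), 4)) {
    pp <- p; pp[k] <- pp[k] + eps
    pm <- p; pm[k] <- pm[k] - eps
    numS <- (sctforge:::.ssimGlobalLossGrad(x, pp, list())$loss -
               sctforge:::.ssimGlobalLossGrad(x, pm, list())$loss) / (2 * eps)
    expect_equal(sg$grad[k], numS, tolerance = 1e-4)
    numP <- (sctforge:::.perceptualLossGrad(x, pp, E, c(1L, 2L))$loss -
               sctforge:::.perceptualLossGrad(x, pm, E, c(1L, 2L))$loss) /
      (2 * eps)
    expect_equal(pg$grad[k], numP, tolerance = 1e-4)
  }
})
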