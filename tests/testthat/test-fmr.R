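# Nonlinear scale space, detection, binary descriptors, Hamming matching,
# and the feature mapping ratio.

test_that("scale space fixes constants, conserves mass, preserves edges", {
  cfg <- ScaleSpaceConfig()
  # constant image is a diffusion fixed point
  const <- matrix(100, 48, 48)
  sp <- buildScaleSpace(const, cfg)
  for (L in sp$levels) expect_lt(max(abs(L - L[1, 1])), 1e-9)

  img <- featureRichSlice(seed = 5L, n = 64L)@values
  sp2 <- buildScaleSpace(img, cfg)
  # per-step conservation implies per-level conservation of the total sum
  s0 <- sum(sp2$levels[[1]])
  for (L in sp2$levels[-1])
    expect_lt(abs(sum(L) - s0) / abs(s0), 1e-3)

  # step edge survives nonlinear diffusion better than gaussian blur of
  # equivalent scale
  step <- matrix(0, 64, 64)
  step[, 33:64] <- 200
  spe <- buildScaleSpace(step, cfg)
  lastSigma <- tail(sp2$sigmas, 1)
  gauss <- sctforge:::.gblur(sctforge:::.to8bit(step), lastSigma)
  edgeGrad <- function(m) max(abs(m[32, 33] - m[32, 32]))
  nlLast <- tail(spe$levels, 1)[[1]]
  expect_gt(edgeGrad(nlLast) / edgeGrad(gauss), 1)

  expect_error(buildScaleSpace(matrix(0, 8, 8), cfg), "small")
})

test_that("detection finds blobs and respects thresholds", {
  cfg <- ScaleSpaceConfig()
  # constant image: no keypoints
  spc <- buildScaleSpace(matrix(5, 64, 64), cfg)
  expect_equal(nrow(detectFeatures(spc, cfg)), 0)

  # single bright gaussian blob on a flat background
  n <- 64
  blob <- 400 * exp(-(outer((1:n - 32)^2, (1:n - 32)^2, "+")) / (2 * 3^2))
  spb <- buildScaleSpace(blob, cfg)
  kp <- detectFeatures(spb, cfg)
  expect_gte(nrow(kp), 1)
  dists <- sqrt((kp$row - 32)^2 + (kp$col - 32)^2)
  expect_lte(min(dists), 2)

  # infinite threshold: nothing survives
  cfgInf <- ScaleSpaceConfig(detectionThreshold = Inf)
  expect_equal(nrow(detectFeatures(spb, cfgInf)), 0)
})

test_that("descriptors are offset invariant and complement under inversion", {
  img <- featureRichSlice(seed = 12L, n = 128L)@values
  cfg <- ScaleSpaceConfig()
  f1 <- extractFeatures(img, cfg)
  expect_gt(nrow(keypoints(f1)), 0)

  # global additive offset: identical keypoints and descriptors
  f2 <- extractFeatures(img + 100, cfg)
  expect_identical(descriptors(f1), descriptors(f2))

  # contrast inversion: same keypoints, complemented bits
  f3 <- extractFeatures(-img, cfg)
  expect_equal(nrow(keypoints(f3)), nrow(keypoints(f1)))
  common <- merge(cbind(keypoints(f1), i1 = seq_len(nrow(keypoints(f1)))),
                  cbind(keypoints(f3)[c("row", "col", "level")],
                        i3 = seq_len(nrow(keypoints(f3)))),
                  by = c("row", "col", "level"))
  expect_gt(nrow(common), 0)
  d1 <- descriptors(f1)[common$i1, , drop = FALSE]
  d3 <- descriptors(f3)[common$i3, , drop = FALSE]
  expect_true(mean(d1 != d3) > 0.99)
})

test_that("matcher agrees with the exhaustive oracle and honours bounds", {
  set.seed(33)
  for (rep in 1:4) {
    nA <- sample(20:60, 1); nB <- sample(20:60, 1)
    A <- matrix(rbinom(nA * 64, 1, 0.5), nA, 64)
    B <- matrix(rbinom(nB * 64, 1, 0.5), nB, 64)
    # plant some true correspondences
    B[1:10, ] <- A[1:10, ]
    fa <- new("FeatureSet",
              keypoints = data.frame(row = seq_len(nA), col = 1,
                                     scale = 1, response = 1, level = 2L),
              descriptors = A)
    fb <- new("FeatureSet",
              keypoints = data.frame(row = seq_len(nB), col = 1,
                                     scale = 1, response = 1, level = 2L),
              descriptors = B)
    mr <- matchBruteForce(fa, fb, threshold = 0.4)
    or <- oracleMatch(A, B, threshold = 0.4)
    expect_equal(mr@pairs$indexA, or$indexA)
    expect_equal(mr@pairs$indexB, or$indexB)
    expect_equal(mr@pairs$distance, or$distance)
    expect_lte(nrow(mr@pairs), min(nA, nB))
  }

  # identical sets: all self-matches at distance zero
  A <- matrix(rbinom(30 * 64, 1, 0.5), 30, 64)
  fa <- new("FeatureSet",
            keypoints = data.frame(row = 1:30, col = 1, scale = 1,
                                   response = 1, level = 2L),
            descriptors = A)
  self <- matchBruteForce(fa, fa)
  expect_equal(nrow(self@pairs), 30)
  expect_true(all(self@pairs$distance == 0))

  # a descriptor and its complement are at normalized distance 1 and can
  # never be accepted under the 0.8 threshold
  f1 <- new("FeatureSet",
            keypoints = data.frame(row = 1L, col = 1, scale = 1,
                                   response = 1, level = 2L),
            descriptors = A[1, , drop = FALSE])
  f1c <- new("FeatureSet", keypoints = keypoints(f1),
             descriptors = 1L - A[1, , drop = FALSE])
  expect_equal(nrow(matchBruteForce(f1, f1c, threshold = 0.8)@pairs), 0)
  expect_equal(sum(A[1, ] != (1 - A[1, ])) / ncol(A), 1)
  # in a full complemented set no accepted pair links a row to its own
  # complement, and every accepted distance respects the threshold
  fb <- new("FeatureSet", keypoints = keypoints(fa),
            descriptors = 1L - A)
  mc <- matchBruteForce(fa, fb, threshold = 0.8)
  expect_false(any(mc@pairs$indexA == mc@pairs$indexB))
  expect_true(all(mc@pairs$distance < 0.8))
})

test_that("FMR is 1 on identical images and degrades with noise", {
  img <- featureRichSlice(seed = 14L, n = 128L)
  r <- fmr(img, img)
  expect_equal(r$fmr, 1.0)
  expect_gt(r$nDetectedA, 0)

  # bounded on perturbed pairs
  set.seed(35)
  for (k in 1:5) {
    noisy <- ImageSlice(pmin(pmax(img@values +
                                    matrix(rnorm(length(img@values), 0, 40),
                                           128), -1024), 3071),
                        img@spacing, "SCT")
    v <- fmr(img, noisy)$fmr
    expect_gte(v, 0); expect_lte(v, 1)
  }

  # mean FMR non-increasing with noise level (reduced seeded sweep)
  sigmas <- c(0, 10, 30, 60)
  means <- sapply(sigmas, function(sg) {
    mean(sapply(1:4, function(s) {
      base <- featureRichSlice(seed = 40L + s, n = 128L)
      if (sg == 0) return(fmr(base, base)$fmr)
      set.seed(1000 + s)
      noisy <- ImageSlice(pmin(pmax(base@values +
                                      matrix(rnorm(128 * 128, 0, sg), 128),
                                    -1024), 3071), base@spacing, "SCT")
      fmr(base, noisy)$fmr
    }))
  })
  expect_true(all(diff(means) <= 0))
})
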