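# Network engine: kernel oracles, shape contracts, architecture structure,
# end-to-end gradient correctness.

test_that("convolution kernels match naive loop oracles", {
  set.seed(31)
  H <- 6; W <- 5; Cin <- 2; Cout <- 3; N <- 2
  x <- array(rnorm(H * W * Cin * N), c(H, W, Cin, N))
  w <- array(rnorm(9 * Cin * Cout), c(3, 3, Cin, Cout))
  b <- rnorm(Cout)
  y <- sctforge:::.conv2dFwd(x, w, b)
  ref <- array(0, c(H, W, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (r in 1:H) for (cl in 1:W) {
    s <- b[co]
    for (ci in 1:Cin) for (i in -1:1) for (j in -1:1) {
      rr <- r + i; cc <- cl + j
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W)
        s <- s + x[rr, cc, ci, n] * w[i + 2, j + 2, ci, co]
    }
    ref[r, cl, co, n] <- s
  }
  expect_equal(y, ref, tolerance = 1e-12)

  # transposed conv: adjoint relation <conv^T(x), y> == <x, convT_bwd... >
  xt <- array(rnorm(4 * 4 * 2 * 1), c(4, 4, 2, 1))
  wt <- array(rnorm(4 * 2 * 3), c(2, 2, 2, 3))
  yt <- sctforge:::.convT2Fwd(xt, wt, numeric(3))
  expect_equal(dim(yt), c(8L, 8L, 3L, 1L))
  ytRef <- array(0, c(8, 8, 3, 1))
  for (co in 1:3) for (ci in 1:2) for (i in 1:4) for (j in 1:4)
    for (di in 0:1) for (dj in 0:1)
      ytRef[2 * i - 1 + di, 2 * j - 1 + dj, co, 1] <-
        ytRef[2 * i - 1 + di, 2 * j - 1 + dj, co, 1] +
        xt[i, j, ci, 1] * wt[di + 1, dj + 1, ci, co]
  expect_equal(yt, ytRef, tolerance = 1e-12)

  # max-pool forward/backward round trip
  xp <- array(rnorm(4 * 4 * 1 * 1), c(4, 4, 1, 1))
  pl <- sctforge:::.maxpool2Fwd(xp)
  expect_equal(pl$y[1, 1, 1, 1], max(xp[1:2, 1:2, 1, 1]))
  dx <- sctforge:::.maxpool2Bwd(array(1, c(2, 2, 1, 1)), pl$idx, 4L, 4L)
  expect_equal(sum(dx), 4)
  expect_equal(sum(dx != 0), 4)
})

test_that("network preserves shape across side lengths and pads 270", {
  cfg <- tinyNetworkConfig()
  net <- buildNetwork(cfg, seed = 2)
  for (side in c(64, 128, 256)) {
    x <- array(rnorm(side * side) * 0.1, c(side, side, 1, 1))
    y <- netForward(net, x)
    expect_equal(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
  x270 <- array(rnorm(270 * 270) * 0.1, c(270, 270, 1, 1))
  y270 <- netForward(net, x270)
  expect_equal(dim(y270), c(270L, 270L, 1L, 1L))
})

test_that("inference is deterministic; dropout makes training stochastic", {
  cfg <- NetworkConfig(nPool = 2L, growthRate = 8L, layersPerBlock = 2L,
                       nFirst = 16L, residual = FALSE)
  net <- buildNetwork(cfg, seed = 3)
  set.seed(7)
  x <- array(rnorm(32 * 32, 0, 0.3), c(32, 32, 1, 1))
  expect_identical(netForward(net, x), netForward(net, x))
  set.seed(1); a <- netForward(net, x, train = TRUE)
  set.seed(2); b <- netForward(net, x, train = TRUE)
  expect_false(identical(a, b))
})

test_that("architecture introspection shows the transition compositions", {
  net <- buildNetwork(tinyNetworkConfig(), seed = 1)
  st <- networkStructure(net)
  expect_equal(st$transitionDown,
               c("batchnorm", "elu", "conv1x1", "dropout(p=0.2)",
                 "maxpool2x2"))
  expect_equal(st$denseLayer[1:3], c("batchnorm", "elu", "conv3x3"))
  expect_match(st$transitionUp, "transposedconv2x2")
  # every transition-down stage carries a 1x1 conv and a BN
  for (stage in net$params$down) {
    expect_equal(dim(stage$td$conv$w)[1:2], c(1L, 1L))
    expect_true(all(c("gamma", "beta") %in% names(stage$td$bn)))
  }
})

test_that("parameter count grows with the growth rate", {
  n8 <- buildNetwork(NetworkConfig(nPool = 2L, growthRate = 8L,
                                   layersPerBlock = 2L, nFirst = 16L),
                     seed = 1)
  n16 <- buildNetwork(NetworkConfig(nPool = 2L, growthRate = 16L,
                                    layersPerBlock = 2L, nFirst = 16L),
                      seed = 1)
  expect_gt(parameterCount(n16), parameterCount(n8))
})

test_that("combined-loss gradient through the network matches finite differences", {
  cfgN <- NetworkConfig(nPool = 2L, growthRate = 4L, layersPerBlock = 2L,
                        nFirst = 8L, dropoutP = 0, residual = FALSE)
  net <- buildNetwork(cfgN, seed = 5)
  set.seed(41)
  xb <- array(rnorm(16 * 16 * 2, 0, 0.4), c(16, 16, 1, 2))
  tb <- array(rnorm(16 * 16 * 2, 0, 0.4), c(16, 16, 1, 2))
  lcfg <- LossConfig("LPS")
  E <- defaultFeatureExtractor()
  lossAt <- function(nn) {
    fwd <- sctforge:::.netForwardFull(nn, xb, train = TRUE)
    sctforge:::.combinedLossGrad(tb, fwd$y, lcfg, E)$total
  }
  fwd <- sctforge:::.netForwardFull(net, xb, train = TRUE)
  lg <- sctforge:::.combinedLossGrad(tb, fwd$y, lcfg, E)
  expect_true(all(is.finite(lg$grad)))
  G <- sctforge:::.netBackward(net, fwd$caches, lg$grad)

  eps <- 1e-5
  # spot-check one weight in the first conv and one BN gain
  k <- 7
  np <- net; np$params$first$w[k] <- np$params$first$w[k] + eps
  nm <- net; nm$params$first$w[k] <- nm$params$first$w[k] - eps
  num <- (lossAt(np) - lossAt(nm)) / (2 * eps)
  expect_equal(G$first$w[k], num, tolerance = 1e-4)

  np <- net; np$params$down[[1]]$td$bn$gamma[2] <-
    np$params$down[[1]]$td$bn$gamma[2] + eps
  nm <- net; nm$params$down[[1]]$td$bn$gamma[2] <-
    nm$params$down[[1]]$td$bn$gamma[2] - eps
  num <- (lossAt(np) - lossAt(nm)) / (2 * eps)
  expect_equal(G$down[[1]]$td$bn$gamma[2], num, tolerance = 1e-4)
})
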