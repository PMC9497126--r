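# Loss functions for network training and evaluation: pixel-wise L1,
# structural similarity (global and gaussian-window forms), and a perceptual
# loss measuring squared Euclidean distance between deep feature maps.
# Analytic gradients with respect to the prediction are provided for the
# trainer; all gradients are finite-difference-checked in the test suite.

# coerce a matrix / 3D / 4D array into (H, W, C, N) batch form
.asBatch <- function(x) {
  if (is(x, "ImageSlice")) x <- x@values
  d <- dim(x)
  if (is.null(d) || length(d) == 2) x <- array(x, c(dim(as.matrix(x)), 1, 1))
  else if (length(d) == 3) x <- array(x, c(d, 1))
  else if (length(d) != 4) stop("expected a matrix or 3D/4D array")
  x
}

.checkSameShape <- function(x, gx) {
  if (!identical(dim(x), dim(gx)))
    stop("shape mismatch between the two image batches")
}

#' Pixel-wise mean absolute (L1) loss
#'
#' Mean over all pixels of `|x - G(x)|`; mean-reduced so the value is
#' resolution independent.
#'
#' @param x,gx matrices or `(H, W, C, N)` arrays of equal shape (ground
#'   truth and model output).
#' @return nonnegative scalar.
#' @export
l1Loss <- function(x, gx) {
  x <- .asBatch(x); gx <- .asBatch(gx)
  .checkSameShape(x, gx)
  mean(abs(x - gx))
}

# resolve SSIM stabilisation constants from fractions of the dynamic range
.ssimConstants <- function(params) {
  L <- params$dataRange
  c(c1 = (params$k1 * L)^2, c2 = (params$k2 * L)^2)
}

.ssimDefaults <- function(params = list()) {
  def <- list(window = "gaussian", windowSize = 11L, k1 = 0.01, k2 = 0.03,
              dataRange = 2, sigma = 1.5)
  def[names(params)] <- params
  if (def$k1 <= 0 || def$k2 <= 0 || def$dataRange <= 0)
    stop("SSIM stabilisation constants must be positive")
  def
}

# global-window SSIM for one pair of matrices (population moments)
.ssimGlobal1 <- function(x, p, c1, c2) {
  mx <- mean(x); mp <- mean(p)
  vx <- mean(x^2) - mx^2; vp <- mean(p^2) - mp^2
  cxp <- mean(x * p) - mx * mp
  ((2 * mx * mp + c1) * (2 * cxp + c2)) /
    ((mx^2 + mp^2 + c1) * (vx + vp + c2))
}

#' Structural similarity (SSIM)
#'
#' For `window = "global"` the similarity statistic is evaluated once from
#' image-wide means, variances and covariance. For `window = "gaussian"`
#' (mean-SSIM) it is evaluated per local gaussian window (size 11, sigma 1.5
#' by default) and averaged. Batches return the mean over samples.
#'
#' @param x,gx images of equal shape.
#' @param params list overriding any of `window` (`"global"`/`"gaussian"`),
#'   `windowSize`, `sigma`, `k1`, `k2`, `dataRange` (the dynamic range L;
#'   constants are `c1 = (k1 L)^2`, `c2 = (k2 L)^2`).
#' @return scalar in `(-1, 1]`; 1 iff the images are identical.
#' @export
ssimValue <- function(x, gx, params = list()) {
  p <- .ssimDefaults(params)
  x <- .asBatch(x); gx <- .asBatch(gx)
  .checkSameShape(x, gx)
  cc <- .ssimConstants(p)
  d <- dim(x)
  vals <- numeric(0)
  for (n in seq_len(d[4])) for (ch in seq_len(d[3])) {
    a <- x[, , ch, n]; b <- gx[, , ch, n]
    vals <- c(vals, if (p$window == "global") {
      .ssimGlobal1(a, b, cc["c1"], cc["c2"])
    } else {
      mean(.ssimMap(a, b, p, cc))
    })
  }
  mean(vals)
}

# local mean-SSIM map with gaussian weighting
.ssimMap <- function(a, b, p, cc) {
  f <- function(m) .gaussFilter(m, p$windowSize, p$sigma)
  mua <- f(a); mub <- f(b)
  va <- f(a * a) - mua^2; vb <- f(b * b) - mub^2
  cab <- f(a * b) - mua * mub
  ((2 * mua * mub + cc["c1"]) * (2 * cab + cc["c2"])) /
    ((mua^2 + mub^2 + cc["c1"]) * (va + vb + cc["c2"]))
}

#' SSIM training loss: `1 - ssimValue(x, gx)`
#'
#' The printed similarity is a quantity to maximise; the trainable loss is
#' its complement, zero iff the SSIM equals 1.
#'
#' @inheritParams ssimValue
#' @return nonnegative scalar.
#' @export
ssimLoss <- function(x, gx, params = list()) 1 - ssimValue(x, gx, params)

# ---- perceptual feature extractor ------------------------------------------

# Comparison features come from a fixed (non-trainable) convolutional stack.
# The default is seeded-random: stage s = 3x3 conv -> ELU -> 2x2 max-pool,
# He-initialised from a named seed, so no pretrained weights are required and
# the extractor is bit-reproducible. An adapter accepting externally supplied
# stage weights keeps the interface pluggable.

#' Build a fixed convolutional feature extractor
#'
#' @param seed integer seed for the (immutable) stage weights.
#' @param inChannels expected input channels; single-channel images are
#'   replicated on entry.
#' @param stageChannels output channels of each stage.
#' @param weights optional externally supplied list of `(w, b)` per stage
#'   (e.g. converted pretrained filters); overrides the seeded init.
#' @return an object of class `featureExtractor` with a `provenance` field
#'   (`"seeded-random"` or `"external"`).
#' @export
buildFeatureExtractor <- function(seed = 20831L, inChannels = 3L,
                                  stageChannels = c(8L, 16L, 16L, 16L),
                                  weights = NULL) {
  stages <- vector("list", length(stageChannels))
  if (is.null(weights)) {
    .withSeed(seed, function() {
      cin <- inChannels
      for (s in seq_along(stageChannels)) {
        cout <- stageChannels[s]
        fan <- 9 * cin
        w <- array(rnorm(9 * cin * cout, 0, sqrt(2 / fan)),
                   c(3, 3, cin, cout))
        stages[[s]] <<- list(w = w, b = numeric(cout))
        cin <- cout
      }
    })
    prov <- "seeded-random"
  } else {
    stages <- weights
    prov <- "external"
  }
  structure(list(stages = stages, inChannels = as.integer(inChannels),
                 seed = as.integer(seed), provenance = prov),
            class = "featureExtractor")
}

# package-level default extractor, built once per session
.pkgEnv <- new.env(parent = emptyenv())

#' @describeIn buildFeatureExtractor the package default (seeded-random)
#'   extractor, built once and cached.
#' @export
defaultFeatureExtractor <- function() {
  if (is.null(.pkgEnv$extractor))
    .pkgEnv$extractor <- buildFeatureExtractor()
  .pkgEnv$extractor
}

# replicate single-channel batches to the extractor's expected channels
.replicateChannels <- function(x, cin) {
  d <- dim(x)
  if (d[3] == cin) return(x)
  if (d[3] != 1) stop("cannot adapt ", d[3], " channels to ", cin)
  array(rep(x, each = 1), c(d[1], d[2], 1, d[4]))[, , rep(1, cin), ,
                                                  drop = FALSE]
}

# forward through all stages; returns list of stage outputs (+ caches)
.extractorForward <- function(E, x, cache = FALSE) {
  x <- .replicateChannels(.asBatch(x), E$inChannels)
  outs <- vector("list", length(E$stages))
  caches <- if (cache) vector("list", length(E$stages))
  for (s in seq_along(E$stages)) {
    st <- E$stages[[s]]
    z <- .conv2dFwd(x, st$w, st$b)
    a <- pmax(z, 0) + (exp(pmin(z, 0)) - 1)       # ELU, alpha = 1
    dim(a) <- dim(z)
    if (any(dim(a)[1:2] %% 2 != 0))
      stop("input side not divisible by 2^", length(E$stages),
           " as the extractor requires")
    pl <- .maxpool2Fwd(a)
    if (cache) caches[[s]] <- list(x = x, z = z, a = a, idx = pl$idx)
    x <- pl$y
    outs[[s]] <- x
  }
  list(outputs = outs, caches = caches)
}

# gradient of sum_l <douts[[l]], f_l(x)> with respect to x
.extractorBackward <- function(E, caches, douts) {
  ns <- length(E$stages)
  dy <- NULL
  for (s in rev(seq_len(ns))) {
    cc <- caches[[s]]
    da <- dim(cc$a)
    if (is.null(dy)) dy <- array(0, c(da[1] / 2, da[2] / 2, da[3], da[4]))
    if (!is.null(douts[[s]])) dy <- dy + douts[[s]]
    da <- .maxpool2Bwd(dy, cc$idx, dim(cc$a)[1], dim(cc$a)[2])
    dz <- da * ((cc$z > 0) + (cc$z <= 0) * exp(pmin(cc$z, 0)))
    dim(dz) <- dim(cc$z)
    dy <- .conv2dBwd(cc$x, E$stages[[s]]$w, dz)$dx
  }
  dy
}

#' Perceptual (feature-space) loss
#'
#' Mean over the selected extractor stages of the mean squared Euclidean
#' distance between the feature maps of the two images. Zero iff the feature
#' maps coincide; symmetric in its arguments.
#'
#' @param x,gx images of equal shape (single-channel inputs are replicated to
#'   the extractor's input channels).
#' @param extractor a [buildFeatureExtractor()] object.
#' @param layers stage indices to compare.
#' @return nonnegative scalar.
#' @export
perceptualLoss <- function(x, gx, extractor = defaultFeatureExtractor(),
                           layers = c(2L, 4L)) {
  if (any(layers < 1 | layers > length(extractor$stages)))
    stop("layer index out of range")
  fx <- .extractorForward(extractor, x)$outputs
  fg <- .extractorForward(extractor, gx)$outputs
  mean(vapply(layers, function(l) mean((fx[[l]] - fg[[l]])^2), numeric(1)))
}

#' Combined training loss
#'
#' Weighted sum of the enabled components:
#' `w_l1 * L1 + w_ssim * (1 - SSIM) + w_perc * perceptual`. Unit weights by
#' default. The four studied compositions are L1, LP (L1 + perceptual),
#' LS (L1 + SSIM) and LPS (all three).
#'
#' @param x,gx images of equal shape on the normalized `[-1, 1]` scale.
#' @param cfg a [LossConfig-class].
#' @param extractor feature extractor for the perceptual component.
#' @return list with `total` and a named `components` vector.
#' @export
combinedLoss <- function(x, gx, cfg = LossConfig("LPS"),
                         extractor = defaultFeatureExtractor()) {
  stopifnot(is(cfg, "LossConfig"))
  comps <- c(l1 = NA_real_, ssim = NA_real_, perceptual = NA_real_)
  total <- 0
  if (cfg@useL1) {
    comps["l1"] <- l1Loss(x, gx)
    total <- total + cfg@weights["l1"] * comps["l1"]
  }
  if (cfg@useSSIM) {
    comps["ssim"] <- ssimLoss(x, gx, cfg@ssimParams)
    total <- total + cfg@weights["ssim"] * comps["ssim"]
  }
  if (cfg@usePerceptual) {
    comps["perceptual"] <- perceptualLoss(x, gx, extractor,
                                          cfg@perceptualLayers)
    total <- total + cfg@weights["perceptual"] * comps["perceptual"]
  }
  list(total = unname(total), components = comps)
}

# ---- gradients (trainer internals) -----------------------------------------

# d(mean |p - x|)/dp
.l1Grad <- function(x, p) sign(p - x) / length(p)

# global-window SSIM loss (1 - S) and gradient w.r.t. the prediction,
# computed per sample then averaged over the batch
.ssimGlobalLossGrad <- function(x, p, params) {
  pp <- .ssimDefaults(params)
  cc <- .ssimConstants(pp)
  c1 <- cc["c1"]; c2 <- cc["c2"]
  d <- dim(x); N <- d[4]
  g <- array(0, d)
  sVals <- numeric(N)
  m <- prod(d[1:3])
  for (n in seq_len(N)) {
    a <- x[, , , n]; b <- p[, , , n]
    mx <- mean(a); mp <- mean(b)
    vx <- mean(a^2) - mx^2; vp <- mean(b^2) - mp^2
    cxp <- mean(a * b) - mx * mp
    A1 <- 2 * mx * mp + c1; A2 <- 2 * cxp + c2
    B1 <- mx^2 + mp^2 + c1; B2 <- vx + vp + c2
    S <- (A1 * A2) / (B1 * B2)
    sVals[n] <- S
    dS <- (2 / (m * B1 * B2)) *
      (mx * A2 + A1 * (a - mx) - S * (mp * B2 + B1 * (b - mp)))
    g[, , , n] <- -dS / N
  }
  list(loss = 1 - mean(sVals), grad = g)
}

# perceptual loss and gradient w.r.t. the prediction
.perceptualLossGrad <- function(x, p, extractor, layers) {
  fx <- .extractorForward(extractor, x)$outputs
  fp <- .extractorForward(extractor, p, cache = TRUE)
  K <- length(layers)
  douts <- vector("list", length(extractor$stages))
  loss <- 0
  for (l in layers) {
    diff <- fp$outputs[[l]] - fx[[l]]
    loss <- loss + mean(diff^2) / K
    g <- 2 * diff / (length(diff) * K)
    douts[[l]] <- if (is.null(douts[[l]])) g else douts[[l]] + g
  }
  dxRep <- .extractorBackward(extractor, fp$caches, douts)
  # fold the channel replication back to the single image channel
  d <- dim(p)
  if (d[3] == 1 && dim(dxRep)[3] > 1) {
    dx <- array(0, d)
    for (c in seq_len(dim(dxRep)[3])) dx <- dx + dxRep[, , c, , drop = FALSE]
  } else dx <- dxRep
  list(loss = loss, grad = dx)
}

# combined loss + gradient w.r.t. prediction. The SSIM component uses the
# global-window form during training (closed-form gradient); evaluation uses
# the windowed statistic.
.combinedLossGrad <- function(x, p, cfg, extractor) {
  comps <- c(l1 = NA_real_, ssim = NA_real_, perceptual = NA_real_)
  g <- array(0, dim(p))
  total <- 0
  if (cfg@useL1) {
    comps["l1"] <- mean(abs(p - x))
    total <- total + cfg@weights["l1"] * comps["l1"]
    g <- g + cfg@weights["l1"] * .l1Grad(x, p)
  }
  if (cfg@useSSIM) {
    sp <- cfg@ssimParams; sp$window <- "global"
    sg <- .ssimGlobalLossGrad(x, p, sp)
    comps["ssim"] <- sg$loss
    total <- total + cfg@weights["ssim"] * sg$loss
    g <- g + cfg@weights["ssim"] * sg$grad
  }
  if (cfg@usePerceptual) {
    pg <- .perceptualLossGrad(x, p, extractor, cfg@perceptualLayers)
    comps["perceptual"] <- pg$loss
    total <- total + cfg@weights["perceptual"] * pg$loss
    g <- g + cfg@weights["perceptual"] * pg$grad
  }
  list(total = unname(total), components = comps, grad = g)
}
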