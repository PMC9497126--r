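# Training loop: on-the-fly augmentation (horizontal flip, random rotation,
# random blur on the input only), Adam optimisation of the combined loss,
# per-epoch history and best-validation-MAE checkpointing.

# augmentation consuming the active RNG stream; geometric transforms are
# identical on input and target (pair integrity), blur degrades the input only
.augmentPairRNG <- function(sample, a) {
  if (runif(1) >= a$applyProb) return(sample)
  cb <- sample@cbct@values
  dc <- sample@dct@values
  if (runif(1) < a$hflipProb) {
    cb <- cb[, rev(seq_len(ncol(cb)))]
    dc <- dc[, rev(seq_len(ncol(dc)))]
  }
  if (a$rotationMaxDeg > 0) {
    th <- runif(1, -a$rotationMaxDeg, a$rotationMaxDeg)
    rot <- function(m)
      .clipHU(as.matrix(EBImage::rotate(m, th, filter = "bilinear",
                                        output.dim = dim(m),
                                        bg.col = -1000)))
    cb <- rot(cb); dc <- rot(dc)
  }
  if (runif(1) < 0.5) {
    sg <- runif(1, a$blurSigmaRange[1], a$blurSigmaRange[2])
    cb <- .gblur(cb, sg)
  }
  PairedSample(cbct = ImageSlice(.clipHU(cb), sample@cbct@spacing, "CBCT"),
               dct = ImageSlice(.clipHU(dc), sample@dct@spacing, "CT"),
               caseId = sample@caseId)
}

#' Augment a paired sample
#'
#' With probability `applyProb`: horizontal flip (probability `hflipProb`)
#' and a random rotation within `rotationMaxDeg` degrees are applied with
#' identical parameters to both members (bilinear resampling, -1000 HU
#' fill); a random gaussian blur is applied to the CBCT input only, since it
#' simulates imaging degradation and must not alter the learning target.
#' Deterministic given `seed`.
#'
#' @param sample a [PairedSample-class].
#' @param augmentCfg augment list as in [TrainConfig()].
#' @param seed integer seed.
#' @return a [PairedSample-class].
#' @export
augmentPair <- function(sample, augmentCfg = TrainConfig()@augment,
                        seed = 1L) {
  def <- TrainConfig()@augment
  def[names(augmentCfg)] <- augmentCfg
  .withSeed(seed, function() .augmentPairRNG(sample, def))
}

# ---- Adam over the parameter tree ------------------------------------------

.zerosLike <- function(p) {
  if (is.list(p)) lapply(p, .zerosLike)
  else if (is.numeric(p)) {
    z <- p * 0
    z
  } else p
}

.adamUpdate <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  if (is.list(p)) {
    nm <- names(p)
    for (k in seq_along(p)) {
      gk <- if (!is.null(nm) && !is.null(names(g))) g[[nm[k]]] else g[[k]]
      if (is.null(gk)) next          # non-trainable state (BN running stats)
      r <- .adamUpdate(p[[k]], gk, m[[k]], v[[k]], lr, t, b1, b2, eps)
      p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

# ---- training ----------------------------------------------------------------

# stack paired samples into normalized (H, W, 1, N) input/target arrays
.stackBatch <- function(samples) {
  d <- dim(samples[[1]]@cbct@values)
  N <- length(samples)
  x <- array(0, c(d[1], d[2], 1, N))
  y <- array(0, c(d[1], d[2], 1, N))
  for (i in seq_len(N)) {
    x[, , 1, i] <- normalizeHU(samples[[i]]@cbct@values)
    y[, , 1, i] <- normalizeHU(samples[[i]]@dct@values)
  }
  list(x = x, y = y)
}

#' Train the translation network
#'
#' Runs the full protocol: shuffled minibatches, on-the-fly augmentation,
#' Adam on the combined loss, per-epoch logging of every enabled loss
#' component and the validation MAE (HU), and retention of the
#' best-validation checkpoint. Fully reproducible given `cfg@seed`.
#'
#' @param trainSamples,validSamples lists of [PairedSample-class].
#' @param net a `sctNetwork`; built from scratch when `NULL` (tiny preset).
#' @param cfg a [TrainConfig-class].
#' @param extractor perceptual feature extractor.
#' @param verbose print per-epoch progress.
#' @return list with `net` (best-validation parameters, `trained = TRUE`)
#'   and `history` (data.frame: epoch, component losses, total, valMae).
#' @export
trainNetwork <- function(trainSamples, validSamples, net = NULL,
                         cfg = TrainConfig(),
                         extractor = defaultFeatureExtractor(),
                         verbose = FALSE) {
  stopifnot(is(cfg, "TrainConfig"))
  if (length(trainSamples) == 0) stop("empty training dataset")
  set.seed(cfg@seed)
  if (is.null(net)) net <- buildNetwork(tinyNetworkConfig())
  m <- .zerosLike(net$params)
  v <- .zerosLike(net$params)
  t <- 0
  nTr <- length(trainSamples)
  hist <- vector("list", cfg@epochs)
  bestMae <- Inf
  bestParams <- net$params

  for (epoch in seq_len(cfg@epochs)) {
    ord <- sample(nTr)
    starts <- seq(1, nTr, by = cfg@batchSize)
    comps <- c(l1 = 0, ssim = 0, perceptual = 0)
    totAcc <- 0; nb <- 0
    for (s in starts) {
      ids <- ord[s:min(s + cfg@batchSize - 1, nTr)]
      aug <- lapply(trainSamples[ids], .augmentPairRNG, a = cfg@augment)
      b <- .stackBatch(aug)
      fwd <- .netForwardFull(net, b$x, train = TRUE)
      net <- fwd$net
      lg <- .combinedLossGrad(b$y, fwd$y, cfg@loss, extractor)
      if (!is.finite(lg$total))
        stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, nb + 1))
      G <- .netBackward(net, fwd$caches, lg$grad)
      t <- t + 1
      upd <- .adamUpdate(net$params, G, m, v, cfg@learningRate, t)
      net$params <- upd$p; m <- upd$m; v <- upd$v
      ok <- is.finite(lg$components)
      comps[ok] <- comps[ok] + lg$components[ok]
      totAcc <- totAcc + lg$total
      nb <- nb + 1
    }
    valMae <- NA_real_
    if (length(validSamples) > 0) {
      valMae <- mean(vapply(validSamples, function(sm) {
        pred <- synthesizeCT(net, sm@cbct)
        mean(abs(pred@values - sm@dct@values))
      }, numeric(1)))
      if (valMae < bestMae) {
        bestMae <- valMae
        bestParams <- net$params
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, l1 = comps["l1"] / nb,
                                ssim = comps["ssim"] / nb,
                                perceptual = comps["perceptual"] / nb,
                                total = totAcc / nb, valMae = valMae,
                                row.names = NULL)
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  valMAE %.2f HU", epoch,
                      totAcc / nb, valMae))
  }
  if (is.finite(bestMae)) net$params <- bestParams
  net$trained <- TRUE
  list(net = net, history = do.call(rbind, hist))
}

#' Generate a synthetic CT from a CBCT slice
#'
#' Normalizes the input, runs the network in inference mode (dropout off,
#' running batch statistics) and maps the output back to HU.
#'
#' @param net a `sctNetwork`.
#' @param cbct an [ImageSlice-class].
#' @return an [ImageSlice-class] with modality `"SCT"`.
#' @export
synthesizeCT <- function(net, cbct) {
  stopifnot(is(cbct, "ImageSlice"))
  x <- array(normalizeHU(cbct@values), c(dim(cbct@values), 1, 1))
  y <- .netForwardFull(net, x, train = FALSE)$y
  ImageSlice(denormalizeHU(y[, , 1, 1]), spacing = cbct@spacing,
             modality = "SCT")
}
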