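# Fully convolutional DenseNet (down-sampling path, bottleneck, up-sampling
# path with skip concatenations) together with a hand-rolled reverse pass.
# Layer composition:
#   dense layer:      BN -> ELU -> 3x3 conv (growth maps) -> dropout
#   transition down:  BN -> ELU -> 1x1 conv -> dropout -> 2x2 max-pool
#   transition up:    2x2 stride-2 transposed convolution
# Only the new feature maps of the bottleneck / up-path blocks are upsampled
# (the classic FC-DenseNet economy); skip connections concatenate the full
# down-path block output at the matching resolution.

.concatC <- function(a, b) {
  d1 <- dim(a); d2 <- dim(b)
  out <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
  out[, , seq_len(d1[3]), ] <- a
  out[, , d1[3] + seq_len(d2[3]), ] <- b
  out
}

.sliceC <- function(x, from, len) x[, , from + seq_len(len) - 1, , drop = FALSE]

.elu <- function(z) {
  a <- pmax(z, 0) + (exp(pmin(z, 0)) - 1)
  dim(a) <- dim(z)
  a
}
.eluGrad <- function(z, da) {
  g <- da * ((z > 0) + (z <= 0) * exp(pmin(z, 0)))
  dim(g) <- dim(z)
  g
}

# ---- parameter initialisation ----------------------------------------------

.convInit <- function(k, cin, cout) {
  list(w = array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}
.convTInit <- function(cin, cout) {
  list(w = array(rnorm(4 * cin * cout, 0, sqrt(2 / (4 * cin))),
                 c(2, 2, cin, cout)),
       b = numeric(cout))
}
.bnInit <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c), rm = numeric(c), rv = rep(1, c))
}
.denseLayerInit <- function(cin, growth) {
  list(bn = .bnInit(cin), conv = .convInit(3, cin, growth))
}
.tdInit <- function(c) list(bn = .bnInit(c), conv = .convInit(1, c, c))

# ---- batch normalisation ----------------------------------------------------

.bnFwd <- function(P, x, train, momentum = 0.9, eps = 1e-5) {
  C <- dim(x)[3]
  y <- array(0, dim(x))
  xhat <- array(0, dim(x))
  invstd <- numeric(C)
  mu <- numeric(C); va <- numeric(C)
  for (c in seq_len(C)) {
    xc <- x[, , c, , drop = FALSE]
    if (train) {
      mu[c] <- mean(xc)
      va[c] <- mean((xc - mu[c])^2)
    } else {
      mu[c] <- P$rm[c]; va[c] <- P$rv[c]
    }
    invstd[c] <- 1 / sqrt(va[c] + eps)
    xh <- (xc - mu[c]) * invstd[c]
    xhat[, , c, ] <- xh
    y[, , c, ] <- P$gamma[c] * xh + P$beta[c]
  }
  newP <- P
  if (train) {
    newP$rm <- momentum * P$rm + (1 - momentum) * mu
    newP$rv <- momentum * P$rv + (1 - momentum) * va
  }
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = P$gamma),
       P = newP)
}

.bnBwd <- function(cache, dy) {
  C <- dim(dy)[3]
  dx <- array(0, dim(dy))
  dgamma <- numeric(C); dbeta <- numeric(C)
  m <- prod(dim(dy)[c(1, 2, 4)])
  for (c in seq_len(C)) {
    dyc <- dy[, , c, , drop = FALSE]
    xh <- cache$xhat[, , c, , drop = FALSE]
    dgamma[c] <- sum(dyc * xh)
    dbeta[c] <- sum(dyc)
    dxh <- dyc * cache$gamma[c]
    dx[, , c, ] <- (cache$invstd[c] / m) *
      (m * dxh - sum(dxh) - xh * sum(dxh * xh))
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

.dropoutFwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, mask = NULL))
  mask <- array((runif(length(x)) >= p) / (1 - p), dim(x))
  list(y = x * mask, mask = mask)
}

# ---- composite layers -------------------------------------------------------

.denseLayerFwd <- function(P, x, pDrop, train) {
  bn <- .bnFwd(P$bn, x, train)
  e <- .elu(bn$y)
  z <- .conv2dFwd(e, P$conv$w, P$conv$b)
  dr <- .dropoutFwd(z, pDrop, train)
  list(y = dr$y,
       cache = list(bn = bn$cache, bnY = bn$y, e = e, mask = dr$mask),
       P = list(bn = bn$P, conv = P$conv))
}

.denseLayerBwd <- function(P, cache, dy) {
  if (!is.null(cache$mask)) dy <- dy * cache$mask
  cb <- .conv2dBwd(cache$e, P$conv$w, dy)
  de <- .eluGrad(cache$bnY, cb$dx)
  bb <- .bnBwd(cache$bn, de)
  list(dx = bb$dx,
       grads = list(bn = bb$grads, conv = list(w = cb$dw, b = cb$db)))
}

.tdFwd <- function(P, x, pDrop, train) {
  bn <- .bnFwd(P$bn, x, train)
  e <- .elu(bn$y)
  z <- .conv2dFwd(e, P$conv$w, P$conv$b)
  dr <- .dropoutFwd(z, pDrop, train)
  pl <- .maxpool2Fwd(dr$y)
  list(y = pl$y,
       cache = list(bn = bn$cache, bnY = bn$y, e = e, mask = dr$mask,
                    idx = pl$idx, preH = dim(z)[1], preW = dim(z)[2]),
       P = list(bn = bn$P, conv = P$conv))
}

.tdBwd <- function(P, cache, dy) {
  dz <- .maxpool2Bwd(dy, cache$idx, cache$preH, cache$preW)
  if (!is.null(cache$mask)) dz <- dz * cache$mask
  cb <- .conv2dBwd(cache$e, P$conv$w, dz)
  de <- .eluGrad(cache$bnY, cb$dx)
  bb <- .bnBwd(cache$bn, de)
  list(dx = bb$dx,
       grads = list(bn = bb$grads, conv = list(w = cb$dw, b = cb$db)))
}

# dense block: returns the full concatenation [input, y1..yL] and the new
# maps [y1..yL]
.denseBlockFwd <- function(Ps, x, pDrop, train) {
  feats <- x
  caches <- vector("list", length(Ps))
  newPs <- vector("list", length(Ps))
  newMaps <- NULL
  for (l in seq_along(Ps)) {
    r <- .denseLayerFwd(Ps[[l]], feats, pDrop, train)
    caches[[l]] <- c(r$cache, list(cinBefore = dim(feats)[3]))
    newPs[[l]] <- r$P
    feats <- .concatC(feats, r$y)
    newMaps <- if (is.null(newMaps)) r$y else .concatC(newMaps, r$y)
  }
  list(full = feats, new = newMaps, caches = caches, Ps = newPs)
}

# backward through a dense block given gradients w.r.t. the full output
# and/or the new maps; returns gradient w.r.t. the block input
.denseBlockBwd <- function(Ps, caches, cin, growth, dFull = NULL,
                           dNew = NULL) {
  L <- length(Ps)
  cFinal <- cin + L * growth
  d <- dim(if (!is.null(dFull)) dFull else dNew)
  dfeats <- array(0, c(d[1], d[2], cFinal, d[4]))
  if (!is.null(dFull)) dfeats <- dfeats + dFull
  if (!is.null(dNew))
    dfeats[, , cin + seq_len(L * growth), ] <-
      dfeats[, , cin + seq_len(L * growth), , drop = FALSE] + dNew
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dy <- .sliceC(dfeats, cin + (l - 1) * growth + 1, growth)
    r <- .denseLayerBwd(Ps[[l]], caches[[l]], dy)
    grads[[l]] <- r$grads
    nIn <- caches[[l]]$cinBefore
    dfeats[, , seq_len(nIn), ] <-
      dfeats[, , seq_len(nIn), , drop = FALSE] + r$dx
  }
  list(dx = .sliceC(dfeats, 1, cin), grads = grads)
}

# ---- network construction ---------------------------------------------------

#' Build an FC-DenseNet translation network
#'
#' Constructs the parameter tree for the architecture: initial 3x3
#' convolution, `nPool` dense-block + transition-down stages, a bottleneck
#' dense block, `nPool` transition-up + dense-block stages with skip
#' concatenation from the matching down-path resolution, and a final 1x1
#' convolution. Weight initialisation is seeded by the caller
#' (`set.seed`) or via the `seed` argument.
#'
#' @param cfg a [NetworkConfig-class].
#' @param seed optional integer seed for weight initialisation.
#' @return a `sctNetwork` list: `config`, `params`, `arch` (channel
#'   bookkeeping), `trained` flag.
#' @export
buildNetwork <- function(cfg = tinyNetworkConfig(), seed = NULL) {
  stopifnot(is(cfg, "NetworkConfig"))
  build <- function() {
    g <- cfg@growthRate; L <- cfg@layersPerBlock; np <- cfg@nPool
    params <- list()
    params$first <- .convInit(3, cfg@inChannels, cfg@nFirst)
    chans <- cfg@nFirst
    skipCh <- integer(np)
    params$down <- vector("list", np)
    for (i in seq_len(np)) {
      block <- lapply(seq_len(L), function(l)
        .denseLayerInit(chans + (l - 1) * g, g))
      full <- chans + L * g
      skipCh[i] <- full
      params$down[[i]] <- list(block = block, td = .tdInit(full))
      chans <- full
    }
    params$bottleneck <- lapply(seq_len(L), function(l)
      .denseLayerInit(chans + (l - 1) * g, g))
    newCh <- L * g
    params$up <- vector("list", np)
    upIn <- integer(np)
    for (j in seq_len(np)) {
      sk <- skipCh[np + 1 - j]
      params$up[[j]] <- list(tu = .convTInit(newCh, newCh))
      upIn[j] <- sk + newCh
      params$up[[j]]$block <- lapply(seq_len(L), function(l)
        .denseLayerInit(upIn[j] + (l - 1) * g, g))
      newCh <- L * g
    }
    lastFull <- upIn[np] + L * g
    params$final <- .convInit(1, lastFull, cfg@outChannels)
    # identity initialisation for the residual form: the network starts as
    # the identity mapping and learns the artifact correction
    if (cfg@residual && cfg@inChannels == cfg@outChannels)
      params$final$w[] <- 0
    list(config = cfg, params = params,
         arch = list(skipCh = skipCh, upIn = upIn, lastFull = lastFull),
         trained = FALSE)
  }
  net <- if (is.null(seed)) build() else .withSeed(seed, build)
  class(net) <- "sctNetwork"
  net
}

#' Total number of trainable parameters
#' @param net a `sctNetwork`.
#' @export
parameterCount <- function(net) {
  n <- 0
  walk <- function(x, nm = "") {
    if (is.list(x)) {
      for (k in names(x)) walk(x[[k]], k)
      for (i in seq_along(x)) if (is.null(names(x))) walk(x[[i]], "")
    } else if (is.numeric(x) && !nm %in% c("rm", "rv")) {
      n <<- n + length(x)
    }
  }
  walk(net$params)
  n
}

#' Describe the layer composition of a built network
#'
#' Introspects the parameter tree: reports the operation sequence of the
#' dense layers, transition-down and transition-up stages with actual kernel
#' sizes and the dropout probability in use.
#'
#' @param net a `sctNetwork`.
#' @return list of character vectors, one per stage type.
#' @export
networkStructure <- function(net) {
  p <- net$config@dropoutP
  td <- net$params$down[[1]]$td
  kd <- dim(td$conv$w)
  dl <- net$params$down[[1]]$block[[1]]
  kl <- dim(dl$conv$w)
  tu <- net$params$up[[1]]$tu
  kt <- dim(tu$w)
  fin <- dim(net$params$final$w)
  list(
    denseLayer = c("batchnorm", "elu",
                   sprintf("conv%dx%d", kl[1], kl[2]),
                   sprintf("dropout(p=%.2g)", p)),
    transitionDown = c("batchnorm", "elu",
                       sprintf("conv%dx%d", kd[1], kd[2]),
                       sprintf("dropout(p=%.2g)", p), "maxpool2x2"),
    transitionUp = sprintf("transposedconv%dx%d_stride2", kt[1], kt[2]),
    finalConv = sprintf("conv%dx%d", fin[1], fin[2]))
}

# ---- forward / backward ------------------------------------------------------

# reflect-pad a batch on the bottom/right to reach target spatial dims
.padReflect <- function(x, Ht, Wt) {
  d <- dim(x)
  if (d[1] == Ht && d[2] == Wt) return(x)
  ri <- c(seq_len(d[1]), rev(seq_len(d[1]))[seq_len(Ht - d[1])])
  ci <- c(seq_len(d[2]), rev(seq_len(d[2]))[seq_len(Wt - d[2])])
  x[ri, ci, , , drop = FALSE]
}

# full forward pass; returns prediction, caches for backward and the network
# with updated BN running statistics
.netForwardFull <- function(net, x, train = FALSE) {
  cfg <- net$config
  div <- 2^cfg@nPool
  d <- dim(x)
  Ht <- ceiling(d[1] / div) * div
  Wt <- ceiling(d[2] / div) * div
  padded <- (Ht != d[1]) || (Wt != d[2])
  xp <- .padReflect(x, Ht, Wt)
  p <- net$params
  pd <- cfg@dropoutP
  C <- list(inDim = d, padded = padded)

  z <- .conv2dFwd(xp, p$first$w, p$first$b)
  C$firstX <- xp
  cur <- z
  skips <- vector("list", cfg@nPool)
  C$down <- vector("list", cfg@nPool)
  for (i in seq_len(cfg@nPool)) {
    blk <- .denseBlockFwd(p$down[[i]]$block, cur, pd, train)
    p$down[[i]]$block <- blk$Ps
    skips[[i]] <- blk$full
    td <- .tdFwd(p$down[[i]]$td, blk$full, pd, train)
    p$down[[i]]$td <- td$P
    C$down[[i]] <- list(block = blk$caches, td = td$cache,
                        cin = dim(cur)[3])
    cur <- td$y
  }
  bot <- .denseBlockFwd(p$bottleneck, cur, pd, train)
  p$bottleneck <- bot$Ps
  C$bottleneck <- list(caches = bot$caches, cin = dim(cur)[3])
  new <- bot$new
  C$up <- vector("list", cfg@nPool)
  for (j in seq_len(cfg@nPool)) {
    tuP <- p$up[[j]]$tu
    upx <- .convT2Fwd(new, tuP$w, tuP$b)
    sk <- skips[[cfg@nPool + 1 - j]]
    cat2 <- .concatC(sk, upx)
    blk <- .denseBlockFwd(p$up[[j]]$block, cat2, pd, train)
    p$up[[j]]$block <- blk$Ps
    C$up[[j]] <- list(tuX = new, block = blk$caches, cin = dim(cat2)[3],
                      skCh = dim(sk)[3], upCh = dim(upx)[3])
    new <- blk$new
    if (j == cfg@nPool) lastFull <- blk$full
  }
  y <- .conv2dFwd(lastFull, p$final$w, p$final$b)
  C$finalX <- lastFull
  if (padded) y <- y[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE]
  if (cfg@residual && cfg@inChannels == cfg@outChannels) y <- y + x
  net$params <- p
  list(y = y, caches = C, net = net)
}

#' Network forward pass
#'
#' @param net a `sctNetwork` from [buildNetwork()].
#' @param x matrix or `(H, W, C, N)` array on the normalized intensity
#'   scale. Sides not divisible by `2^nPool` are reflect-padded internally
#'   and the output cropped back.
#' @param train logical; enables dropout stochasticity and batch-statistic
#'   normalisation.
#' @return prediction array of the same spatial shape as the input.
#' @export
netForward <- function(net, x, train = FALSE) {
  x <- .asBatch(x)
  .netForwardFull(net, x, train = train)$y
}

# backward pass: dy w.r.t. network output -> gradient tree matching params
.netBackward <- function(net, C, dy) {
  cfg <- net$config
  p <- net$params
  g <- cfg@growthRate; L <- cfg@layersPerBlock; np <- cfg@nPool
  G <- list()
  if (C$padded) {
    dyFull <- array(0, c(dim(C$finalX)[1:2], dim(dy)[3], dim(dy)[4]))
    dyFull[seq_len(dim(dy)[1]), seq_len(dim(dy)[2]), , ] <- dy
    dy <- dyFull
  }
  fb <- .conv2dBwd(C$finalX, p$final$w, dy)
  G$final <- list(w = fb$dw, b = fb$db)
  dFull <- fb$dx
  G$up <- vector("list", np)
  dNew <- NULL
  for (j in rev(seq_len(np))) {
    cc <- C$up[[j]]
    r <- .denseBlockBwd(p$up[[j]]$block, cc$block, cc$cin, g,
                        dFull = if (j == np) dFull else NULL,
                        dNew = dNew)
    dcat <- r$dx
    dsk <- .sliceC(dcat, 1, cc$skCh)
    dup <- .sliceC(dcat, cc$skCh + 1, cc$upCh)
    tb <- .convT2Bwd(cc$tuX, p$up[[j]]$tu$w, dup)
    G$up[[j]] <- list(tu = list(w = tb$dw, b = tb$db), block = r$grads)
    # gradient into the skip connection accumulates at the down stage
    C$down[[np + 1 - j]]$dSkip <- dsk
    dNew <- tb$dx
  }
  r <- .denseBlockBwd(p$bottleneck, C$bottleneck$caches, C$bottleneck$cin, g,
                      dNew = dNew)
  G$bottleneck <- r$grads
  dcur <- r$dx
  G$down <- vector("list", np)
  for (i in rev(seq_len(np))) {
    cc <- C$down[[i]]
    tdb <- .tdBwd(p$down[[i]]$td, cc$td, dcur)
    dFullBlk <- tdb$dx + cc$dSkip
    rb <- .denseBlockBwd(p$down[[i]]$block, cc$block, cc$cin, g,
                         dFull = dFullBlk)
    G$down[[i]] <- list(block = rb$grads, td = tdb$grads)
    dcur <- rb$dx
  }
  fb1 <- .conv2dBwd(C$firstX, p$first$w, dcur)
  G$first <- list(w = fb1$dw, b = fb1$db)
  G
}
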