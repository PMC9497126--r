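# Shared fixtures and independent oracles, all generated in code.

tinyPhantomCfg <- function(seed = 7L, n = 64L, nCases = 5L, ...) {
  PhantomConfig(imageSize = as.integer(n), seed = as.integer(seed),
                nCases = as.integer(nCases), ...)
}

# a feature-rich head slice for keypoint work
featureRichSlice <- function(seed = 7L, n = 128L) {
  generateAnatomy(tinyPhantomCfg(seed = seed, n = n), 0)
}

# exhaustive O(n^2) Hamming matcher with the same acceptance rule as the
# fast path (mutual minima with ties, greedy one-to-one by distance/index),
# written with naive loops
oracleMatch <- function(A, B, threshold = 0.8) {
  nA <- nrow(A); nB <- nrow(B); bits <- ncol(A)
  D <- matrix(0, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB))
    D[i, j] <- sum(A[i, ] != B[j, ]) / bits
  cand <- list()
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    if (D[i, j] >= threshold) next
    if (D[i, j] > min(D[i, ]) || D[i, j] > min(D[, j])) next
    cand[[length(cand) + 1]] <- c(i, j, D[i, j])
  }
  if (length(cand) == 0)
    return(data.frame(indexA = integer(0), indexB = integer(0),
                      distance = numeric(0)))
  M <- do.call(rbind, cand)
  M <- M[order(M[, 3], M[, 1], M[, 2]), , drop = FALSE]
  usedA <- logical(nA); usedB <- logical(nB)
  keep <- logical(nrow(M))
  for (k in seq_len(nrow(M))) {
    i <- M[k, 1]; j <- M[k, 2]
    if (usedA[i] || usedB[j]) next
    usedA[i] <- TRUE; usedB[j] <- TRUE
    keep[k] <- TRUE
  }
  M <- M[keep, , drop = FALSE]
  data.frame(indexA = as.integer(M[, 1]), indexB = as.integer(M[, 2]),
             distance = M[, 3])
}

# exhaustive gamma search oracle: loops over every fine-grid offset within
# the search radius, bilinear interpolation, vectorised over points
oracleGammaMap <- function(ref, ev, spacing, ddPct, dtaMm, cutoffPct,
                           radiusFactor = 3, interpFraction = 10) {
  mx <- max(ref)
  ddAbs <- ddPct / 100 * mx
  cut <- cutoffPct / 100 * mx
  radius <- radiusFactor * dtaMm
  step <- dtaMm / interpFraction
  H <- nrow(ref); W <- ncol(ref)
  best <- matrix(Inf, H, W)
  offs <- seq(-radius, radius, by = step)
  bilin <- function(drPx, dcPx) {
    # value of ev at (r + drPx, c + dcPx) for all (r, c); NA outside
    r <- seq_len(H) + drPx; c <- seq_len(W) + dcPx
    r0 <- floor(r); c0 <- floor(c)
    fr <- r - r0; fc <- c - c0
    val <- matrix(NA_real_, H, W)
    okr <- r >= 1 & r <= H; okc <- c >= 1 & c <= W
    if (!any(okr) || !any(okc)) return(val)
    g <- function(ri, ci) {
      ri <- pmin(pmax(ri, 1), H); ci <- pmin(pmax(ci, 1), W)
      ev[ri, ci, drop = FALSE]
    }
    sub <- g(r0[okr], c0[okc]) * outer(1 - fr[okr], 1 - fc[okc]) +
      g(r0[okr] + 1, c0[okc]) * outer(fr[okr], 1 - fc[okc]) +
      g(r0[okr], c0[okc] + 1) * outer(1 - fr[okr], fc[okc]) +
      g(r0[okr] + 1, c0[okc] + 1) * outer(fr[okr], fc[okc])
    val[okr, okc] <- sub
    val
  }
  for (dr in offs) for (dc in offs) {
    if (dr^2 + dc^2 > radius^2 + 1e-9) next
    v <- bilin(dr / spacing[1], dc / spacing[2])
    g2 <- (v - ref)^2 / ddAbs^2 + (dr^2 + dc^2) / dtaMm^2
    best <- pmin(best, g2, na.rm = TRUE)
  }
  g <- sqrt(best)
  g[ref < cut] <- NA_real_
  g
}
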