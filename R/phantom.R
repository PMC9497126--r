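# Seeded digital head phantom: paired CT/CBCT slices and dose grids with the
# statistical structure the translation method assumes. Anatomy is built from
# randomized nested ellipses (air background, skull ring, brain soft tissue,
# low-contrast lesions, air cavities); the CBCT copy adds cupping/shading,
# scatter haze, noise and a global HU shift on identical anatomy.

# ellipse membership on a coordinate grid; a, b are semi-axes in the same
# normalized units as xg/yg
.inEllipse <- function(xg, yg, cx, cy, a, b) {
  ((xg - cx) / a)^2 + ((yg - cy) / b)^2
}

#' Generate one head-like CT slice
#'
#' Deterministic given `(cfg@seed, caseIndex)`: air background (-1000 HU),
#' an elliptical skull ring (700-1200 HU), brain soft tissue (20-50 HU) with
#' a smooth low-amplitude texture, 2-5 low-contrast lesions (about +/-30 HU)
#' and 1-2 air cavities.
#'
#' @param cfg a [PhantomConfig-class].
#' @param caseIndex 0-based case index, `< cfg@nCases`.
#' @return an [ImageSlice-class] with modality `"CT"`.
#' @export
generateAnatomy <- function(cfg, caseIndex) {
  stopifnot(is(cfg, "PhantomConfig"))
  if (caseIndex < 0 || caseIndex >= cfg@nCases)
    stop("caseIndex must be in [0, nCases)")
  n <- cfg@imageSize
  .withSeed(.subSeed(cfg@seed, caseIndex, 1L), function() {
    ax <- seq(-1, 1, length.out = n)
    xg <- matrix(ax, n, n, byrow = TRUE)   # column coordinate
    yg <- matrix(ax, n, n)                 # row coordinate
    a <- runif(1, 0.58, 0.70)              # head semi-axes (fits in frame)
    b <- runif(1, 0.66, 0.78)
    cx <- runif(1, -0.03, 0.03)
    cy <- runif(1, -0.03, 0.03)
    thick <- runif(1, 0.05, 0.08)
    boneHU <- runif(1, 700, 1200)

    r2 <- .inEllipse(xg, yg, cx, cy, a, b)
    img <- matrix(-1000, n, n)
    skull <- r2 <= 1 & r2 > (1 - thick)^2
    brain <- r2 <= (1 - thick)^2
    img[skull] <- boneHU
    base <- runif(1, 25, 45)
    texture <- .gblur(matrix(rnorm(n * n), n, n), sigma = n / 16)
    texture <- texture / max(abs(texture)) * 8
    img[brain] <- base + texture[brain]

    nles <- sample(2:5, 1)
    for (k in seq_len(nles)) {
      lc <- runif(2, -0.35, 0.35) * c(a, b) + c(cx, cy)
      la <- runif(2, 0.05, 0.14) * c(a, b)
      dhu <- sample(c(-1, 1), 1) * runif(1, 15, 30)
      les <- .inEllipse(xg, yg, lc[1], lc[2], la[1], la[2]) <= 1 & brain
      img[les] <- img[les] + dhu
    }

    ncav <- sample(1:2, 1)
    for (k in seq_len(ncav)) {
      cc <- c(runif(1, -0.2, 0.2) * a + cx, runif(1, 0.25, 0.45) * b + cy)
      ca <- runif(2, 0.04, 0.09) * c(a, b)
      cav <- .inEllipse(xg, yg, cc[1], cc[2], ca[1], ca[2]) <= 1 & brain
      img[cav] <- -1000
    }
    ImageSlice(.clipHU(img), spacing = rep(cfg@pixelSpacing, 2),
               modality = "CT")
  })
}

#' Degrade a CT slice into a CBCT-like slice
#'
#' Applies, on identical anatomy (no geometric deformation): a multiplicative
#' low-frequency bias field on the attenuation-offset image `HU + 1000`
#' (radial cupping plus a seeded smooth random component), an additive
#' scatter-haze term proportional to a wide-kernel blur of the attenuation,
#' additive Gaussian noise, and a constant HU shift. Output is clipped to the
#' CT range. With all artifact amplitudes zero the input is returned
#' unchanged.
#'
#' @param ct an [ImageSlice-class].
#' @param cfg a [PhantomConfig-class] carrying `artifact` amplitudes.
#' @param seed integer seed for the stochastic components.
#' @return an [ImageSlice-class] with modality `"CBCT"`.
#' @export
corruptToCBCT <- function(ct, cfg, seed = cfg@seed) {
  stopifnot(is(ct, "ImageSlice"), is(cfg, "PhantomConfig"))
  a <- cfg@artifact
  n <- nrow(ct@values)
  .withSeed(seed, function() {
    att <- ct@values + 1000
    out <- att
    if (a$biasAmplitude > 0) {
      ax <- seq(-1, 1, length.out = n)
      rho2 <- outer(ax, seq(-1, 1, length.out = ncol(ct@values)),
                    function(y, x) x^2 + y^2) / 2
      radial <- 2 * rho2 - 1                       # darker centre: cupping
      noise <- .gblur(matrix(rnorm(length(att)), nrow(att)),
                      sigma = a$biasScale)
      noise <- noise / max(abs(noise))
      bias <- 0.7 * radial + 0.3 * noise
      out <- out * (1 + (a$biasAmplitude / 1000) * bias)
    }
    if (a$scatterFraction > 0)
      out <- out + a$scatterFraction * .gblur(att, sigma = n / 8)
    out <- out - 1000
    if (a$noiseSigma > 0)
      out <- out + matrix(rnorm(length(out), 0, a$noiseSigma), nrow(out))
    out <- out + a$huShift
    ImageSlice(.clipHU(out), spacing = ct@spacing, modality = "CBCT")
  })
}

#' Generate a paired (reference, evaluated) dose surrogate
#'
#' The reference dose is a superposition of 2-5 anisotropic Gaussian "beam"
#' lobes inside the anatomy, normalized to maximum 1. The evaluated dose is
#' the reference shifted by `shiftMm`, scaled by `scale`, plus proportional
#' noise — a controllable surrogate for synthetic-CT-induced dose error.
#'
#' @param ct anatomy [ImageSlice-class] (lobes are placed inside the body).
#' @param perturbation list with `shiftMm` (length 1 or 2, mm), `scale`,
#'   `noiseFrac`.
#' @param seed integer seed.
#' @return list with elements `reference` and `evaluated`
#'   ([DoseGrid-class]).
#' @export
generateDosePair <- function(ct,
                             perturbation = list(shiftMm = 0, scale = 1,
                                                 noiseFrac = 0),
                             seed = 1L) {
  stopifnot(is(ct, "ImageSlice"))
  p <- list(shiftMm = 0, scale = 1, noiseFrac = 0)
  p[names(perturbation)] <- perturbation
  if (!all(is.finite(unlist(p)))) stop("perturbation fields must be finite")
  shift <- rep(as.numeric(p$shiftMm), length.out = 2)
  sp <- ct@spacing
  ext <- dim(ct@values) * sp
  if (any(abs(shift) >= ext))
    stop("shift exceeds the grid extent")
  .withSeed(seed, function() {
    H <- nrow(ct@values); W <- ncol(ct@values)
    lob <- .sampleLobes(ct@values, H, W)
    ref <- .evalLobes(lob, H, W, 0, 0)
    mx <- max(ref)
    ref <- ref / mx
    # evaluated dose: the continuous lobe model sampled at shifted
    # positions (an exact spatial translation), then scaled, plus
    # proportional noise
    ev <- .evalLobes(lob, H, W, shift[1] / sp[1], shift[2] / sp[2]) / mx *
      p$scale
    if (p$noiseFrac > 0)
      ev <- ev + p$noiseFrac * ref * matrix(rnorm(length(ref)), nrow(ref))
    ev <- pmax(ev, 0)
    list(reference = DoseGrid(ref, spacing = sp, role = "reference"),
         evaluated = DoseGrid(ev, spacing = sp, role = "evaluated"))
  })
}

# sample 2-5 anisotropic Gaussian lobes centred inside the body (HU > -400
# mask when present, central box otherwise); consumes the active RNG stream
.sampleLobes <- function(values, H, W) {
  body <- which(values > -400, arr.ind = TRUE)
  if (nrow(body) < 10)
    body <- as.matrix(expand.grid(round(H * 0.3):round(H * 0.7),
                                  round(W * 0.3):round(W * 0.7)))
  nl <- sample(2:5, 1)
  lob <- vector("list", nl)
  for (k in seq_len(nl)) {
    ctr <- body[sample(nrow(body), 1), ]
    # lobes no narrower than 5 px: the dose grid must resolve the beam,
    # as clinical dose grids do
    lob[[k]] <- list(r0 = ctr[1], c0 = ctr[2],
                     sr = runif(1, max(5, 0.06 * H), max(8, 0.15 * H)),
                     sc = runif(1, max(5, 0.06 * W), max(8, 0.15 * W)),
                     w = runif(1, 0.5, 1))
  }
  lob
}

# evaluate the lobe superposition on the pixel grid displaced by
# (drPx, dcPx): the value at pixel (r, c) is the continuous dose at
# (r - drPx, c - dcPx). A smooth cosine taper to zero at the grid edges is
# part of the continuous model (beams are collimated; the grid boundary
# carries no dose), so shifted fields stay self-consistent.
.evalLobes <- function(lob, H, W, drPx = 0, dcPx = 0) {
  taper1 <- function(u, n) {
    m <- max(4, 0.12 * n)
    x <- pmin(pmin(u - 1, n - u) / m, 1)
    sin(pi / 2 * pmax(x, 0))^2
  }
  rows <- matrix(seq_len(H) - drPx, H, W)
  cols <- matrix(seq_len(W) - dcPx, H, W, byrow = TRUE)
  d <- matrix(0, H, W)
  for (lb in lob)
    d <- d + lb$w * exp(-((rows - lb$r0)^2 / (2 * lb$sr^2) +
                            (cols - lb$c0)^2 / (2 * lb$sc^2)))
  d * taper1(rows, H) * taper1(cols, W)
}

#' Deterministic pseudo-dose from anatomy
#'
#' A fixed surrogate dose engine used by the ablation harness: a seeded lobe
#' fluence (geometry drawn from `seed` only, so paired images share it)
#' attenuated by the cumulative attenuation of the anatomy along the beam
#' (row) direction. HU errors in a synthetic CT therefore propagate to dose
#' errors, mimicking — not reproducing — Monte-Carlo recomputation.
#'
#' @param img anatomy [ImageSlice-class].
#' @param seed integer seed shared between the images being compared.
#' @param role passed to [DoseGrid()].
#' @return a [DoseGrid-class]; the fluence component has maximum 1.
#' @export
doseFromAnatomy <- function(img, seed = 1L, role = "reference") {
  stopifnot(is(img, "ImageSlice"))
  H <- nrow(img@values); W <- ncol(img@values)
  phi <- .withSeed(seed, function() {
    # geometry independent of image content: lobes in the central box
    nl <- sample(2:5, 1)
    d <- matrix(0, H, W)
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (k in seq_len(nl)) {
      ctr <- c(runif(1, 0.35, 0.65) * H, runif(1, 0.35, 0.65) * W)
      sr <- runif(1, 0.06, 0.15) * H
      sc <- runif(1, 0.06, 0.15) * W
      w <- runif(1, 0.5, 1)
      d <- d + w * exp(-((rows - ctr[1])^2 / (2 * sr^2) +
                           (cols - ctr[2])^2 / (2 * sc^2)))
    }
    d / max(d)
  })
  att <- .gblur(.clipHU(img@values) + 1000, sigma = 2)
  depth <- apply(att, 2, cumsum) / (1000 * H)
  DoseGrid(phi * exp(-2.5 * depth), spacing = img@spacing, role = role)
}

#' Generate a full paired phantom dataset with a split manifest
#'
#' Produces `cfg@nCases` paired samples and a train/validation/test split in
#' the 50/5/10 proportions of the full-scale protocol (scaled and rounded for
#' other dataset sizes). Deterministic given `cfg@seed`; generating twice
#' yields bit-identical data.
#'
#' @param cfg a [PhantomConfig-class].
#' @return list with `samples` (list of [PairedSample-class]) and `manifest`
#'   (data.frame: `caseId`, `split`, `caseIndex`, `seed`).
#' @export
generatePhantomDataset <- function(cfg) {
  stopifnot(is(cfg, "PhantomConfig"))
  n <- cfg@nCases
  nTest <- max(1L, as.integer(round(n * 10 / 65)))
  nValid <- max(1L, as.integer(round(n * 5 / 65)))
  nTrain <- n - nValid - nTest
  if (nTrain < 1) stop("nCases too small to split")
  split <- c(rep("train", nTrain), rep("valid", nValid), rep("test", nTest))
  samples <- vector("list", n)
  ids <- sprintf("case%03d", seq_len(n) - 1)
  for (i in seq_len(n)) {
    ct <- generateAnatomy(cfg, i - 1)
    cbct <- corruptToCBCT(ct, cfg, seed = .subSeed(cfg@seed, i - 1, 2L))
    samples[[i]] <- PairedSample(cbct = cbct, dct = ct, caseId = ids[i])
  }
  list(samples = samples,
       manifest = data.frame(caseId = ids, split = split,
                             caseIndex = seq_len(n) - 1L, seed = cfg@seed,
                             stringsAsFactors = FALSE))
}
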