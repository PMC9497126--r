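#' @import methods
#' @importFrom stats rnorm runif sd quantile
#' @useDynLib sctforge, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# CT number conventions used across the package (12-bit CT range; the
# normalisation window feeds the network and the SSIM constants).
.HU_MIN <- -1024
.HU_MAX <- 3071
.HU_WINDOW <- c(-1000, 2000)

#' ImageSlice: a single 2D axial image in Hounsfield units
#'
#' The basic image container: a numeric matrix of CT numbers with a pixel
#' spacing in millimetres and a modality tag identifying whether the slice is
#' a planning CT (`"CT"`), a cone-beam CT (`"CBCT"`) or a network-generated
#' synthetic CT (`"SCT"`).
#'
#' @slot values numeric matrix of HU values, finite, within `[-1024, 3071]`.
#' @slot spacing numeric length-2, (row, col) pixel spacing in mm, positive.
#' @slot modality one of `"CT"`, `"CBCT"`, `"SCT"`.
#' @export
setClass("ImageSlice",
  representation(values = "matrix", spacing = "numeric",
                 modality = "character"),
  prototype(spacing = c(1, 1), modality = "CT"))

setValidity("ImageSlice", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (any(!is.finite(v))) return("values must be finite")
  if (min(v) < .HU_MIN - 1e-6 || max(v) > .HU_MAX + 1e-6)
    return(sprintf("HU values outside [%d, %d]", .HU_MIN, .HU_MAX))
  if (length(object@spacing) != 2 || any(object@spacing <= 0))
    return("spacing must be two positive numbers (mm)")
  if (!object@modality %in% c("CT", "CBCT", "SCT"))
    return("modality must be CT, CBCT or SCT")
  TRUE
})

#' Construct an ImageSlice
#'
#' @param values numeric matrix of HU values.
#' @param spacing pixel spacing in mm, recycled to length 2.
#' @param modality `"CT"`, `"CBCT"` or `"SCT"`.
#' @return An [ImageSlice-class] object.
#' @export
ImageSlice <- function(values, spacing = c(1, 1), modality = "CT") {
  new("ImageSlice", values = as.matrix(values),
      spacing = rep(as.numeric(spacing), length.out = 2),
      modality = modality)
}

#' @describeIn ImageSlice-class pixel values (HU matrix)
#' @param x an `ImageSlice`.
#' @export
sliceValues <- function(x) x@values

#' @describeIn ImageSlice-class pixel spacing in mm
#' @export
sliceSpacing <- function(x) x@spacing

#' @describeIn ImageSlice-class modality tag
#' @export
modality <- function(x) x@modality

setMethod("show", "ImageSlice", function(object) {
  v <- object@values
  cat(sprintf("ImageSlice [%s] %d x %d, %.3g x %.3g mm, HU range [%.0f, %.0f]\n",
              object@modality, nrow(v), ncol(v), object@spacing[1],
              object@spacing[2], min(v), max(v)))
})

#' PairedSample: an aligned (CBCT, dCT) slice pair
#'
#' Holds one training/evaluation pair: the CBCT-like input and the deformed
#' planning CT (dCT) ground truth. Members share shape and spacing; pairs are
#' born aligned (registration is upstream and out of scope).
#'
#' @slot cbct,dct [ImageSlice-class] members.
#' @slot caseId character case identifier.
#' @export
setClass("PairedSample",
  representation(cbct = "ImageSlice", dct = "ImageSlice",
                 caseId = "character"))

setValidity("PairedSample", function(object) {
  if (!identical(dim(object@cbct@values), dim(object@dct@values)))
    return("cbct and dct must have identical shapes")
  if (any(abs(object@cbct@spacing - object@dct@spacing) > 1e-9))
    return("cbct and dct must have identical spacing")
  TRUE
})

#' @param cbct,dct ImageSlice members.
#' @param caseId case identifier string.
#' @rdname PairedSample-class
#' @export
PairedSample <- function(cbct, dct, caseId = "case") {
  new("PairedSample", cbct = cbct, dct = dct, caseId = caseId)
}

setMethod("show", "PairedSample", function(object) {
  cat(sprintf("PairedSample '%s': %d x %d (CBCT + dCT)\n", object@caseId,
              nrow(object@cbct@values), ncol(object@cbct@values)))
})

#' DoseGrid: a 2D absorbed-dose distribution
#'
#' @slot values nonnegative finite numeric matrix (arbitrary dose units/Gy).
#' @slot spacing numeric length-2, mm.
#' @slot role `"reference"` or `"evaluated"`.
#' @export
setClass("DoseGrid",
  representation(values = "matrix", spacing = "numeric", role = "character"),
  prototype(spacing = c(1, 1), role = "reference"))

setValidity("DoseGrid", function(object) {
  v <- object@values
  if (any(!is.finite(v)) || any(v < 0)) return("dose must be finite and >= 0")
  if (length(object@spacing) != 2 || any(object@spacing <= 0))
    return("spacing must be two positive numbers (mm)")
  if (!object@role %in% c("reference", "evaluated"))
    return("role must be 'reference' or 'evaluated'")
  TRUE
})

#' @param values dose matrix.
#' @param spacing spacing in mm.
#' @param role `"reference"` or `"evaluated"`.
#' @rdname DoseGrid-class
#' @export
DoseGrid <- function(values, spacing = c(1, 1), role = "reference") {
  new("DoseGrid", values = as.matrix(values),
      spacing = rep(as.numeric(spacing), length.out = 2), role = role)
}

#' @describeIn DoseGrid-class dose values
#' @param x a `DoseGrid`.
#' @export
doseValues <- function(x) x@values

setMethod("show", "DoseGrid", function(object) {
  cat(sprintf("DoseGrid [%s] %d x %d, max %.4g\n", object@role,
              nrow(object@values), ncol(object@values), max(object@values)))
})

#' FeatureSet: keypoints plus binary descriptors for one image
#'
#' @slot keypoints data.frame with columns `row`, `col`, `scale`, `response`,
#'   `level` (1-based pixel coordinates; scale in pixels).
#' @slot descriptors 0/1 integer matrix, one row per keypoint.
#' @export
setClass("FeatureSet",
  representation(keypoints = "data.frame", descriptors = "matrix"))

setValidity("FeatureSet", function(object) {
  if (nrow(object@keypoints) != nrow(object@descriptors))
    return("one descriptor row per keypoint required")
  if (nrow(object@descriptors) > 0 &&
      !all(object@descriptors %in% c(0L, 1L)))
    return("descriptors must be 0/1")
  TRUE
})

#' @describeIn FeatureSet-class keypoint table
#' @param x a `FeatureSet`.
#' @export
keypoints <- function(x) x@keypoints

#' @describeIn FeatureSet-class descriptor bit matrix
#' @export
descriptors <- function(x) x@descriptors

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet: %d keypoints, %d-bit descriptors\n",
              nrow(object@keypoints), ncol(object@descriptors)))
})

#' MatchResult: one-to-one descriptor matches between two feature sets
#'
#' @slot pairs data.frame with columns `indexA`, `indexB`, `distance`
#'   (normalized Hamming distance in `[0, 1]`).
#' @slot nDetectedA,nDetectedB keypoint counts on each side.
#' @export
setClass("MatchResult",
  representation(pairs = "data.frame", nDetectedA = "integer",
                 nDetectedB = "integer"))

setValidity("MatchResult", function(object) {
  p <- object@pairs
  if (nrow(p) > 0) {
    if (anyDuplicated(p$indexA) || anyDuplicated(p$indexB))
      return("matches must be one-to-one")
    if (any(p$distance < 0 | p$distance > 1))
      return("normalized distances must lie in [0, 1]")
  }
  TRUE
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: %d matches (of %d vs %d detected)\n",
              nrow(object@pairs), object@nDetectedA, object@nDetectedB))
})

#' MetricReport: per-case and aggregate evaluation metrics
#'
#' The row shape of the evaluation tables: one row per test case with image
#' similarity (MAE in HU, SSIM, PSNR in dB, FMR) and dosimetric columns
#' (gamma passing rates, mean absolute dose difference), plus a mean +/- sd
#' aggregate per metric.
#'
#' @slot perCase data.frame, one row per case.
#' @slot aggregate data.frame with columns `metric`, `mean`, `sd`.
#' @slot configTag loss configuration label (`"L1"`, `"LP"`, `"LS"`, `"LPS"`).
#' @export
setClass("MetricReport",
  representation(perCase = "data.frame", aggregate = "data.frame",
                 configTag = "character"))

setValidity("MetricReport", function(object) {
  agg <- object@aggregate
  pc <- object@perCase
  for (m in agg$metric) {
    if (!m %in% names(pc)) next
    mu <- mean(pc[[m]])
    if (is.finite(mu) && abs(mu - agg$mean[agg$metric == m]) > 1e-9)
      return(sprintf("aggregate mean for '%s' disagrees with per-case mean", m))
  }
  TRUE
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport [%s]: %d cases\n", object@configTag,
              nrow(object@perCase)))
  print(object@aggregate, row.names = FALSE)
})

# ---- configuration objects --------------------------------------------------

#' PhantomConfig: head-phantom simulator settings
#'
#' @slot imageSize pixels per side (even, >= 32); 270 matches the clinical
#'   acquisition geometry the simulator emulates.
#' @slot pixelSpacing mm per pixel.
#' @slot seed integer root seed; the same seed reproduces the dataset
#'   bit-for-bit.
#' @slot nCases number of cases available from this configuration.
#' @slot artifact list of CBCT degradation amplitudes: `biasAmplitude` (HU at
#'   water for the low-frequency cupping/shading field), `biasScale`
#'   (correlation length of the random bias component, pixels),
#'   `scatterFraction` (scatter haze as a fraction of blurred attenuation),
#'   `noiseSigma` (additive Gaussian noise, HU), `huShift` (global HU offset).
#' @export
setClass("PhantomConfig",
  representation(imageSize = "integer", pixelSpacing = "numeric",
                 seed = "integer", nCases = "integer", artifact = "list"))

setValidity("PhantomConfig", function(object) {
  if (object@imageSize < 32 || object@imageSize %% 2 != 0)
    return("imageSize must be even and >= 32")
  a <- object@artifact
  need <- c("biasAmplitude", "biasScale", "scatterFraction", "noiseSigma",
            "huShift")
  if (!all(need %in% names(a))) return("artifact list incomplete")
  if (any(unlist(a[c("biasAmplitude", "biasScale", "scatterFraction",
                     "noiseSigma")]) < 0))
    return("artifact amplitudes must be >= 0")
  if (object@pixelSpacing <= 0) return("pixelSpacing must be > 0")
  if (object@nCases < 1) return("nCases must be >= 1")
  TRUE
})

#' @param imageSize,pixelSpacing,seed,nCases,artifact see slot documentation.
#' @rdname PhantomConfig-class
#' @export
PhantomConfig <- function(imageSize = 270L, pixelSpacing = 1.0, seed = 1L,
                          nCases = 65L,
                          artifact = list(biasAmplitude = 70, biasScale = 48,
                                          scatterFraction = 0.06,
                                          noiseSigma = 10, huShift = 15)) {
  def <- list(biasAmplitude = 70, biasScale = 48, scatterFraction = 0.06,
              noiseSigma = 10, huShift = 15)
  def[names(artifact)] <- artifact
  new("PhantomConfig", imageSize = as.integer(imageSize),
      pixelSpacing = as.numeric(pixelSpacing), seed = as.integer(seed),
      nCases = as.integer(nCases), artifact = def)
}

#' LossConfig: composition of the training loss
#'
#' The four studied compositions are L1 only (`"L1"`), L1 + perceptual
#' (`"LP"`), L1 + SSIM (`"LS"`) and all three (`"LPS"`); weights default to
#' 1 for every enabled component.
#'
#' @slot useL1,useSSIM,usePerceptual component switches.
#' @slot weights named numeric `(l1, ssim, perceptual)`, nonnegative.
#' @slot ssimParams list: `window` (`"global"` or `"gaussian"`),
#'   `windowSize` (odd), `k1`, `k2` (stabilisation fractions of the dynamic
#'   range; constants are `c1 = (k1 L)^2`, `c2 = (k2 L)^2`).
#' @slot perceptualLayers integer stages of the feature extractor to compare.
#' @export
setClass("LossConfig",
  representation(useL1 = "logical", useSSIM = "logical",
                 usePerceptual = "logical", weights = "numeric",
                 ssimParams = "list", perceptualLayers = "integer"))

setValidity("LossConfig", function(object) {
  if (!any(object@useL1, object@useSSIM, object@usePerceptual))
    return("at least one loss component must be enabled")
  w <- object@weights
  if (length(w) != 3 || any(w < 0)) return("need 3 nonnegative weights")
  en <- c(object@useL1, object@useSSIM, object@usePerceptual)
  if (any(w[en] <= 0)) return("enabled components need positive weights")
  sp <- object@ssimParams
  if (sp$windowSize %% 2 != 1) return("ssim windowSize must be odd")
  if (sp$k1 <= 0 || sp$k2 <= 0) return("ssim constants must be positive")
  if (!sp$window %in% c("global", "gaussian"))
    return("ssim window must be 'global' or 'gaussian'")
  TRUE
})

#' @param tag shorthand composition: `"L1"`, `"LP"`, `"LS"` or `"LPS"`;
#'   ignored when the `use*` switches are given explicitly.
#' @param useL1,useSSIM,usePerceptual,weights,ssimParams,perceptualLayers
#'   see slot documentation.
#' @rdname LossConfig-class
#' @export
LossConfig <- function(tag = c("LPS", "L1", "LP", "LS"),
                       useL1 = NULL, useSSIM = NULL, usePerceptual = NULL,
                       weights = c(l1 = 1, ssim = 1, perceptual = 1),
                       ssimParams = list(window = "gaussian", windowSize = 11L,
                                         k1 = 0.01, k2 = 0.03),
                       perceptualLayers = c(2L, 4L)) {
  tag <- match.arg(tag)
  if (is.null(useL1)) {
    useL1 <- TRUE
    useSSIM <- tag %in% c("LS", "LPS")
    usePerceptual <- tag %in% c("LP", "LPS")
  }
  def <- list(window = "gaussian", windowSize = 11L, k1 = 0.01, k2 = 0.03)
  def[names(ssimParams)] <- ssimParams
  def$windowSize <- as.integer(def$windowSize)
  w <- rep(as.numeric(weights), length.out = 3)
  names(w) <- c("l1", "ssim", "perceptual")
  new("LossConfig", useL1 = useL1, useSSIM = useSSIM,
      usePerceptual = usePerceptual, weights = w, ssimParams = def,
      perceptualLayers = as.integer(perceptualLayers))
}

#' @describeIn LossConfig-class short label of the composition
#' @param x a `LossConfig`.
#' @export
lossTag <- function(x) {
  if (x@usePerceptual && x@useSSIM) "LPS"
  else if (x@useSSIM) "LS"
  else if (x@usePerceptual) "LP"
  else "L1"
}

#' NetworkConfig: FC-DenseNet hyper-parameters
#'
#' @slot nPool number of transition-down/up stages; input sides must be
#'   divisible by `2^nPool` (non-divisible sizes are reflect-padded by the
#'   forward pass).
#' @slot growthRate feature maps added by each dense layer.
#' @slot layersPerBlock dense layers per block (scalar, used for all blocks).
#' @slot nFirst channels of the initial 3x3 convolution.
#' @slot dropoutP dropout probability in dense layers and transition-downs.
#' @slot inChannels,outChannels image channels (1 for HU slices).
#' @slot residual when TRUE (default) the network output is added to its
#'   input, so the model learns the artifact correction rather than the full
#'   image reconstruction; essential for convergence at desk-scale training
#'   budgets.
#' @export
setClass("NetworkConfig",
  representation(nPool = "integer", growthRate = "integer",
                 layersPerBlock = "integer", nFirst = "integer",
                 dropoutP = "numeric", inChannels = "integer",
                 outChannels = "integer", residual = "logical"))

setValidity("NetworkConfig", function(object) {
  if (object@nPool < 1) return("nPool must be >= 1")
  if (object@growthRate < 1 || object@layersPerBlock < 1 ||
      object@nFirst < 1)
    return("growthRate, layersPerBlock, nFirst must be >= 1")
  if (object@dropoutP < 0 || object@dropoutP >= 1)
    return("dropoutP must be in [0, 1)")
  TRUE
})

#' @param nPool,growthRate,layersPerBlock,nFirst,dropoutP,inChannels,outChannels,residual
#'   see slot documentation.
#' @rdname NetworkConfig-class
#' @export
NetworkConfig <- function(nPool = 5L, growthRate = 12L, layersPerBlock = 4L,
                          nFirst = 48L, dropoutP = 0.2, inChannels = 1L,
                          outChannels = 1L, residual = TRUE) {
  new("NetworkConfig", nPool = as.integer(nPool),
      growthRate = as.integer(growthRate),
      layersPerBlock = as.integer(layersPerBlock), nFirst = as.integer(nFirst),
      dropoutP = dropoutP, inChannels = as.integer(inChannels),
      outChannels = as.integer(outChannels), residual = residual)
}

#' @describeIn NetworkConfig-class small CPU-friendly preset (nPool 2,
#'   growth 8, 2 layers/block) used for desk-scale experiments and tests.
#' @export
tinyNetworkConfig <- function() {
  NetworkConfig(nPool = 2L, growthRate = 8L, layersPerBlock = 2L,
                nFirst = 16L)
}

#' TrainConfig: optimisation protocol
#'
#' Defaults reproduce the full-scale protocol (150 epochs, Adam, initial
#' learning rate 2e-5); desk-scale experiments override epochs/learning rate.
#'
#' @slot epochs number of epochs (>= 1).
#' @slot learningRate Adam step size.
#' @slot batchSize minibatch size.
#' @slot seed integer seed controlling init, shuffling, dropout, augmentation.
#' @slot loss a [LossConfig-class].
#' @slot augment list: `hflipProb`, `rotationMaxDeg`, `blurSigmaRange`
#'   (length 2), `applyProb` (chance a sample is augmented at all).
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", learningRate = "numeric",
                 batchSize = "integer", seed = "integer", loss = "LossConfig",
                 augment = "list"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1) return("epochs must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@batchSize < 1) return("batchSize must be >= 1")
  a <- object@augment
  need <- c("hflipProb", "rotationMaxDeg", "blurSigmaRange", "applyProb")
  if (!all(need %in% names(a))) return("augment list incomplete")
  TRUE
})

#' @param epochs,learningRate,batchSize,seed,loss,augment see slots.
#' @rdname TrainConfig-class
#' @export
TrainConfig <- function(epochs = 150L, learningRate = 2e-5, batchSize = 8L,
                        seed = 1L, loss = LossConfig("LPS"),
                        augment = list(hflipProb = 0.5, rotationMaxDeg = 10,
                                       blurSigmaRange = c(0.5, 1.5),
                                       applyProb = 0.5)) {
  def <- list(hflipProb = 0.5, rotationMaxDeg = 10,
              blurSigmaRange = c(0.5, 1.5), applyProb = 0.5)
  def[names(augment)] <- augment
  new("TrainConfig", epochs = as.integer(epochs), learningRate = learningRate,
      batchSize = as.integer(batchSize), seed = as.integer(seed), loss = loss,
      augment = def)
}

#' ScaleSpaceConfig: nonlinear scale space / detector settings
#'
#' @slot nOctaves,nSublevels pyramid extent; evolution has
#'   `nOctaves * nSublevels` levels at scales `sigma0 * 2^(i/nSublevels)`.
#' @slot sigma0 base smoothing scale in pixels.
#' @slot contrastPercentile percentile of the gradient magnitude used for the
#'   Perona-Malik contrast parameter k.
#' @slot detectionThreshold minimum |response| on the 8-bit intensity scale.
#' @slot descriptorBits descriptor length (pairwise comparisons).
#' @export
setClass("ScaleSpaceConfig",
  representation(nOctaves = "integer", nSublevels = "integer",
                 sigma0 = "numeric", contrastPercentile = "numeric",
                 detectionThreshold = "numeric", descriptorBits = "integer"))

setValidity("ScaleSpaceConfig", function(object) {
  if (object@nOctaves < 1 || object@nSublevels < 1)
    return("nOctaves and nSublevels must be >= 1")
  if (object@detectionThreshold < 0)
    return("detectionThreshold must be >= 0")
  TRUE
})

#' @param nOctaves,nSublevels,sigma0,contrastPercentile,detectionThreshold,descriptorBits
#'   see slot documentation.
#' @rdname ScaleSpaceConfig-class
#' @export
ScaleSpaceConfig <- function(nOctaves = 2L, nSublevels = 3L, sigma0 = 1.6,
                             contrastPercentile = 0.7,
                             detectionThreshold = 1.0,
                             descriptorBits = 256L) {
  new("ScaleSpaceConfig", nOctaves = as.integer(nOctaves),
      nSublevels = as.integer(nSublevels), sigma0 = sigma0,
      contrastPercentile = contrastPercentile,
      detectionThreshold = detectionThreshold,
      descriptorBits = as.integer(descriptorBits))
}

#' GammaCriteria: gamma-index acceptance criteria
#'
#' @slot doseDiffPct dose-difference criterion, percent of the reference
#'   maximum (global normalisation).
#' @slot dtaMm distance-to-agreement criterion in mm.
#' @slot doseCutoffPct points with reference dose below this percent of the
#'   maximum are excluded (NaN in the gamma map).
#' @slot searchRadiusFactor search radius as a multiple of the DTA.
#' @slot interpFraction evaluated dose interpolated at `dta/interpFraction`
#'   steps.
#' @export
setClass("GammaCriteria",
  representation(doseDiffPct = "numeric", dtaMm = "numeric",
                 doseCutoffPct = "numeric", searchRadiusFactor = "numeric",
                 interpFraction = "integer"))

setValidity("GammaCriteria", function(object) {
  if (object@doseDiffPct <= 0 || object@dtaMm <= 0)
    return("doseDiffPct and dtaMm must be > 0")
  if (object@doseCutoffPct < 0) return("doseCutoffPct must be >= 0")
  if (object@searchRadiusFactor <= 0 || object@interpFraction < 1)
    return("invalid search settings")
  TRUE
})

#' @param doseDiffPct,dtaMm,doseCutoffPct,searchRadiusFactor,interpFraction
#'   see slot documentation.
#' @rdname GammaCriteria-class
#' @export
GammaCriteria <- function(doseDiffPct = 1, dtaMm = 1, doseCutoffPct = 10,
                          searchRadiusFactor = 3, interpFraction = 10L) {
  new("GammaCriteria", doseDiffPct = doseDiffPct, dtaMm = dtaMm,
      doseCutoffPct = doseCutoffPct, searchRadiusFactor = searchRadiusFactor,
      interpFraction = as.integer(interpFraction))
}
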