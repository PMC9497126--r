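# Conventional image-similarity metrics, computed in HU.

#' Mean absolute error in HU
#'
#' @param sct,dct [ImageSlice-class] or matrices of equal shape (HU).
#' @param mask optional logical matrix; defaults to the whole slice.
#' @return nonnegative scalar, HU.
#' @export
maeHU <- function(sct, dct, mask = NULL) {
  a <- if (is(sct, "ImageSlice")) sct@values else as.matrix(sct)
  b <- if (is(dct, "ImageSlice")) dct@values else as.matrix(dct)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (is.null(mask)) return(mean(abs(a - b)))
  if (!any(mask)) stop("empty evaluation mask")
  mean(abs(a[mask] - b[mask]))
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(dataRange^2 / MSE)`. The data range defaults to a fixed 3000 HU
#' (the clip-window width) so values are comparable across cases; identical
#' images return `Inf`.
#'
#' @inheritParams maeHU
#' @param dataRange positive dynamic range.
#' @return dB value (possibly `Inf`).
#' @export
psnrDB <- function(sct, dct, dataRange = 3000, mask = NULL) {
  if (dataRange <= 0) stop("dataRange must be > 0")
  a <- if (is(sct, "ImageSlice")) sct@values else as.matrix(sct)
  b <- if (is(dct, "ImageSlice")) dct@values else as.matrix(dct)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(dataRange^2 / mse)
}

#' SSIM evaluation metric
#'
#' Delegates to [ssimValue()] with evaluation defaults: gaussian window of
#' size 11 and the HU data range (3000).
#'
#' @inheritParams maeHU
#' @param params overrides merged into the evaluation defaults.
#' @return scalar in `(-1, 1]`.
#' @export
ssimMetric <- function(sct, dct, params = list()) {
  a <- if (is(sct, "ImageSlice")) sct@values else as.matrix(sct)
  b <- if (is(dct, "ImageSlice")) dct@values else as.matrix(dct)
  def <- list(window = "gaussian", windowSize = 11L, dataRange = 3000)
  def[names(params)] <- params
  ssimValue(a, b, def)
}

#' Body mask: thresholded largest connected component
#'
#' Air background can dominate whole-slice similarity; this mask keeps the
#' largest connected component of `HU > threshold` for masked evaluation.
#'
#' @param img [ImageSlice-class] or matrix.
#' @param threshold HU threshold.
#' @return logical matrix.
#' @export
bodyMask <- function(img, threshold = -400) {
  v <- if (is(img, "ImageSlice")) img@values else as.matrix(img)
  lab <- EBImage::bwlabel(v > threshold)
  tab <- tabulate(as.integer(lab))
  if (length(tab) == 0 || all(tab == 0)) return(v > threshold)
  as.matrix(lab) == which.max(tab)
}
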