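# Shared numeric helpers: HU normalisation, seeded-RNG scoping, small
# image utilities.

.clipHU <- function(x) pmin(pmax(x, .HU_MIN), .HU_MAX)

#' Normalize HU values for the network
#'
#' Clips to the `[-1000, 2000]` HU window and maps it affinely to `[-1, 1]`
#' (dynamic range L = 2), the intensity scale on which losses and the network
#' operate.
#'
#' @param x numeric matrix/array of HU values.
#' @return values in `[-1, 1]`.
#' @export
normalizeHU <- function(x) {
  x <- pmin(pmax(x, .HU_WINDOW[1]), .HU_WINDOW[2])
  2 * (x - .HU_WINDOW[1]) / diff(.HU_WINDOW) - 1
}

#' Invert [normalizeHU()]
#' @param x values in `[-1, 1]`.
#' @return HU values (clipped to the CT range).
#' @export
denormalizeHU <- function(x) {
  .clipHU((x + 1) / 2 * diff(.HU_WINDOW) + .HU_WINDOW[1])
}

# Evaluate f() under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Keeps every seeded operation independent of
# call order.
.withSeed <- function(seed, f) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  f()
}

# Derive a per-case sub-seed from a root seed, staying within 32-bit range.
.subSeed <- function(seed, index, salt = 0L) {
  (as.double(seed) * 48271 + as.double(index) * 16807 + salt * 69621) %%
    2147483629
}

# Gaussian blur that keeps matrix orientation; thin wrapper over EBImage.
# The kernel radius is clamped to the image size so wide blurs remain valid
# on small test images.
.gblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- 2 * ceiling(3 * sigma) + 1
  rmax <- min(dim(m))
  if (rmax %% 2 == 0) rmax <- rmax - 1
  as.matrix(EBImage::gblur(m, sigma = sigma, radius = min(r, rmax)))
}

# 2D separable Gaussian filtering with replicated borders (for windowed
# SSIM). The window shrinks on images smaller than the requested size.
.gaussFilter <- function(m, size, sigma) {
  lim <- min(dim(m))
  if (size > lim) size <- lim - (1 - lim %% 2)
  half <- (size - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k <- k / sum(k)
  as.matrix(EBImage::filter2(m, k, boundary = "replicate"))
}

# Location (lag) of the cross-correlation peak between two matrices, via FFT.
# Returns c(dr, dc) with 0,0 meaning best alignment at zero lag.
.ccfPeak <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  fa <- stats::fft(a); fb <- stats::fft(b)
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  w <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  lag <- as.integer(w) - 1L
  d <- dim(a)
  ifelse(lag > d / 2, lag - d, lag)
}
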