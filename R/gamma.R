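# Gamma-index dose comparison: per-point minimum of the combined
# dose-difference / distance-to-agreement metric, global normalisation to the
# reference maximum, configurable low-dose cutoff.

#' Compute a gamma-index map
#'
#' For every reference point at or above the dose cutoff,
#' `gamma = min over evaluated positions within the search radius of
#' sqrt((Ddiff/dd)^2 + (r/dta)^2)`, with `dd = doseDiffPct * max(ref) / 100`
#' (global normalisation) and `dta = dtaMm`. The evaluated dose is
#' bilinearly interpolated at `dta / interpFraction` steps; the search
#' radius is `searchRadiusFactor * dta`. Points below the cutoff are `NaN`.
#'
#' @param ref,eval [DoseGrid-class] objects with equal shape and spacing.
#' @param crit a [GammaCriteria-class].
#' @return numeric matrix of gamma values (`NaN` below cutoff).
#' @export
gammaMap <- function(ref, eval, crit = GammaCriteria()) {
  stopifnot(is(ref, "DoseGrid"), is(eval, "DoseGrid"),
            is(crit, "GammaCriteria"))
  if (!identical(dim(ref@values), dim(eval@values)))
    stop("dose grids must have identical shapes")
  if (any(abs(ref@spacing - eval@spacing) > 1e-9))
    stop("dose grids must have identical spacings")
  mx <- max(ref@values)
  if (mx <= 0) stop("reference dose is empty")
  g <- .gammaMapC(ref@values, eval@values, ref@spacing[1], ref@spacing[2],
                  crit@doseDiffPct / 100 * mx, crit@dtaMm,
                  crit@doseCutoffPct / 100 * mx,
                  crit@searchRadiusFactor * crit@dtaMm,
                  crit@dtaMm / crit@interpFraction)
  g
}

#' Gamma passing rate
#'
#' Fraction of evaluable (non-NaN) points with `gamma <= 1`.
#'
#' @param gamma matrix from [gammaMap()].
#' @return fraction in `[0, 1]`.
#' @export
gammaPassRate <- function(gamma) {
  ok <- !is.na(gamma)
  if (!any(ok)) stop("no points above the dose cutoff")
  mean(gamma[ok] <= 1)
}

#' Mean absolute dose difference
#'
#' Mean over reference points at or above the cutoff of
#' `|eval - ref| / max(ref)` — dimensionless, matching the convention of
#' dose-difference tables with ~0.01 magnitudes.
#'
#' @param ref,eval [DoseGrid-class] objects of equal shape.
#' @param cutoffPct exclude points below this percent of the reference
#'   maximum.
#' @return nonnegative scalar.
#' @export
doseDifference <- function(ref, eval, cutoffPct = 10) {
  stopifnot(is(ref, "DoseGrid"), is(eval, "DoseGrid"))
  if (!identical(dim(ref@values), dim(eval@values)))
    stop("dose grids must have identical shapes")
  mx <- max(ref@values)
  if (mx <= 0) stop("reference maximum is zero")
  sel <- ref@values >= cutoffPct / 100 * mx
  if (!any(sel)) stop("no points above the dose cutoff")
  mean(abs(eval@values[sel] - ref@values[sel])) / mx
}
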