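#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a wavelength grid
#'
#' @param start_nm first wavelength (nm)
#' @param step_nm band spacing (nm)
#' @param n_bands number of bands
#' @return a \linkS4class{WavelengthGrid}
#' @examples
#' g <- WavelengthGrid()          # 421-730 nm in 3 nm steps
#' head(wavelengths(g))
#' @export
WavelengthGrid <- function(start_nm = 421, step_nm = 3, n_bands = 104L) {
  new("WavelengthGrid", start_nm = as.numeric(start_nm),
      step_nm = as.numeric(step_nm), n_bands = as.integer(n_bands))
}

#' @describeIn WavelengthGrid the sampled wavelengths in nm
#' @param x a WavelengthGrid
#' @export
setMethod("wavelengths", "WavelengthGrid", function(x) {
  x@start_nm + (seq_len(x@n_bands) - 1L) * x@step_nm
})

#' Recover a grid from a vector of wavelengths
#'
#' The wavelengths must be strictly increasing and uniformly spaced
#' (to 1e-6 nm), as produced by a tunable-filter sweep.
#'
#' @param wl numeric vector of wavelengths in nm
#' @return a \linkS4class{WavelengthGrid}
#' @export
gridFromWavelengths <- function(wl) {
  wl <- as.numeric(wl)
  if (length(wl) < 2L) stop("need at least 2 wavelengths")
  d <- diff(wl)
  if (any(d <= 0)) stop("wavelengths must be strictly increasing")
  if (max(d) - min(d) > 1e-6) stop("wavelengths must be uniformly spaced")
  WavelengthGrid(wl[1], mean(d), length(wl))
}

sameGrid <- function(a, b, tol = 1e-9) {
  a@n_bands == b@n_bands &&
    abs(a@start_nm - b@start_nm) <= tol &&
    abs(a@step_nm - b@step_nm) <= tol
}

#' Linearly resample a spectrum onto another grid
#'
#' Used to reconcile endmember libraries measured on a different spectral
#' sampling with the acquisition grid. Plain linear interpolation; the
#' target range must lie inside the source range (no extrapolation).
#'
#' @param values spectrum sampled on \code{source}
#' @param source the grid \code{values} live on
#' @param target the grid to resample onto
#' @return numeric vector of length \code{target@n_bands}
#' @export
resampleToGrid <- function(values, source, target) {
  stopifnot(is(source, "WavelengthGrid"), is(target, "WavelengthGrid"))
  if (length(values) != source@n_bands)
    stop("length(values) must equal source n_bands")
  src <- wavelengths(source)
  tgt <- wavelengths(target)
  if (min(tgt) < min(src) - 1e-9 || max(tgt) > max(src) + 1e-9)
    stop("target grid extends beyond the source range; refusing to extrapolate")
  stats::approx(src, values, xout = tgt, method = "linear", rule = 1)$y
}
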