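#' @include AllClasses.R AllGenerics.R EndmemberLibrary.R SpectraSet.R
NULL

#' Dual-band correction configuration
#'
#' The classical attenuation correction integrates the white-light
#' reflectance over two wavelength bands, raises the excitation-side
#' integral to an empirical exponent, and multiplies the two to obtain a
#' per-pixel scaling factor. The exact bands and exponent vary between
#' instruments; defaults here are 450-480 nm (excitation side), 620-640 nm
#' (emission side), exponent 0.7.
#'
#' @param band_a numeric length-2 interval in nm, raised to \code{exponent}
#' @param band_b numeric length-2 interval in nm
#' @param exponent empirical exponent applied to the band-a integral
#' @return a list of class \code{DualBandConfig}
#' @export
dualBandConfig <- function(band_a = c(450, 480), band_b = c(620, 640),
                           exponent = 0.7) {
  stopifnot(length(band_a) == 2L, length(band_b) == 2L,
            band_a[1] < band_a[2], band_b[1] < band_b[2],
            is.finite(exponent))
  structure(list(band_a = as.numeric(band_a), band_b = as.numeric(band_b),
                 exponent = as.numeric(exponent)),
            class = "DualBandConfig")
}

#' Linear mixture of endmember spectra
#'
#' The forward model: a measured emission spectrum is a non-negative
#' linear combination of the K endmember spectra, \code{B \%*\% z}.
#'
#' @param B an \linkS4class{EndmemberLibrary}
#' @param z abundance vector of length K (or K x n matrix)
#' @return spectrum vector of length m (or m x n matrix)
#' @export
mixSpectra <- function(B, z) {
  Bm <- endmemberMatrix(B)
  z <- if (is.matrix(z)) z else matrix(z, ncol = 1)
  if (nrow(z) != ncol(Bm))
    stop(sprintf("abundance length %d does not match K = %d", nrow(z), ncol(Bm)))
  out <- Bm %*% z
  if (ncol(out) == 1L) drop(out) else out
}

#' Unit-l2 relative abundances
#'
#' \code{z / ||z||2}, or the all-zero vector when \code{||z|| = 0}.
#'
#' @param z abundance vector or K x n matrix (columns normalized)
#' @export
relativeAbundance <- function(z) {
  if (is.matrix(z)) {
    nrm <- sqrt(colSums(z^2))
    sc <- ifelse(nrm > 0, 1 / nrm, 0)
    sweep(z, 2, sc, "*")
  } else {
    nrm <- sqrt(sum(z^2))
    if (nrm > 0) z / nrm else z * 0
  }
}

#' Non-negative least squares unmixing
#'
#' Solves \code{argmin_{z >= 0} ||B z - phi||^2} per spectrum with the
#' Lawson-Hanson active-set algorithm.
#'
#' @param phi spectrum of length m, or an m x n matrix of spectra
#' @param B an \linkS4class{EndmemberLibrary}
#' @return abundance vector of length K, or a K x n matrix
#' @export
nnlsUnmix <- function(phi, B) {
  Bm <- endmemberMatrix(B)
  one <- function(v) {
    if (any(!is.finite(v))) stop("non-finite spectrum passed to nnlsUnmix")
    pracma::lsqnonneg(Bm, v)$x
  }
  if (is.matrix(phi)) {
    if (nrow(phi) != nrow(Bm)) stop("spectrum length does not match grid")
    z <- apply(phi, 2, one)
    rownames(z) <- endmemberNames(B)
    z
  } else {
    if (length(phi) != nrow(Bm)) stop("spectrum length does not match grid")
    stats::setNames(one(phi), endmemberNames(B))
  }
}

.band_integral <- function(values, wl, band) {
  sel <- which(wl >= band[1] - 1e-9 & wl <= band[2] + 1e-9)
  if (length(sel) < 2L)
    stop(sprintf("band [%g, %g] nm covers fewer than 2 grid points", band[1], band[2]))
  pracma::trapz(wl[sel], values[sel])
}

#' Dual-band scaling factor
#'
#' \code{s = (integral over band_a of phi_ref)^x * (integral over band_b)},
#' with trapezoidal integration on the native grid.
#'
#' @param phi_ref white-light reflectance spectrum (length m)
#' @param grid the \linkS4class{WavelengthGrid}
#' @param cfg a \code{\link{dualBandConfig}}
#' @return positive scalar s
#' @export
dualBandFactor <- function(phi_ref, grid, cfg = dualBandConfig()) {
  wl <- wavelengths(grid)
  ia <- .band_integral(phi_ref, wl, cfg$band_a)
  ib <- .band_integral(phi_ref, wl, cfg$band_b)
  if (!is.finite(ia) || !is.finite(ib) || ia <= 0 || ib <= 0)
    stop("non-positive band integral: saturated or empty reflectance spectrum")
  ia^cfg$exponent * ib
}

#' Dual-band attenuation correction
#'
#' Divides each fluorescence spectrum by the scaling factor computed from
#' its paired reflectance spectrum, collapsing the intensity variation
#' induced by heterogeneous absorption, scattering and geometry.
#'
#' @param x a \linkS4class{SpectraSet}
#' @param cfg a \code{\link{dualBandConfig}}
#' @return m x n matrix of corrected fluorescence spectra
#' @export
correctDualBand <- function(x, cfg = dualBandConfig()) {
  f <- fluoSpectra(x); r <- refSpectra(x)
  g <- spectraGrid(x)
  s <- apply(r, 2, dualBandFactor, grid = g, cfg = cfg)
  sweep(f, 2, s, "/")
}

#' Classical unmixing pipeline: dual-band correction then NNLS
#'
#' The field-standard benchmark. Estimated PpIX abundance is the
#' \code{ppix634} row of the result (up to a calibration factor).
#'
#' @param x a \linkS4class{SpectraSet}
#' @param B an \linkS4class{EndmemberLibrary}
#' @param cfg a \code{\link{dualBandConfig}}
#' @return list with \code{z} (K x n abundances), \code{z_hat} (unit-l2
#'   columns), \code{corrected} (m x n corrected spectra) and
#'   \code{recon} (m x n reconstructions B z_hat)
#' @export
classicalPipeline <- function(x, B, cfg = dualBandConfig()) {
  corrected <- correctDualBand(x, cfg)
  z <- nnlsUnmix(corrected, B)
  if (!is.matrix(z)) z <- matrix(z, ncol = 1, dimnames = list(names(z), NULL))
  zh <- relativeAbundance(z)
  list(z = z, z_hat = zh, corrected = corrected,
       recon = endmemberMatrix(B) %*% zh)
}
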