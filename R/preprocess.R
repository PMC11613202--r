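#' @include AllClasses.R AllGenerics.R HyperCube.R SpectraSet.R
NULL

#' Construct sensitivity curves
#'
#' @param filter_transmission per-band filter transmission (> 0)
#' @param camera_sensitivity per-band camera sensitivity (> 0)
#' @return a \linkS4class{SensitivityCurves}
#' @export
SensitivityCurves <- function(filter_transmission, camera_sensitivity) {
  new("SensitivityCurves",
      filter_transmission = as.numeric(filter_transmission),
      camera_sensitivity = as.numeric(camera_sensitivity))
}

#' Read sensitivity curves from CSV
#'
#' Expects columns \code{wavelength_nm}, \code{filter_transmission},
#' \code{camera_sensitivity}; resampled onto \code{grid} if needed.
#'
#' @param path CSV path
#' @param grid target \linkS4class{WavelengthGrid} (optional)
#' @export
readSensitivityCurves <- function(path, grid = NULL) {
  dt <- data.table::fread(path)
  need <- c("wavelength_nm", "filter_transmission", "camera_sensitivity")
  if (!all(need %in% colnames(dt)))
    stop("sensitivity CSV must have wavelength_nm, filter_transmission, camera_sensitivity")
  ft <- dt$filter_transmission; cs <- dt$camera_sensitivity
  if (!is.null(grid)) {
    src <- gridFromWavelengths(dt$wavelength_nm)
    if (!sameGrid(src, grid)) {
      ft <- resampleToGrid(ft, src, grid)
      cs <- resampleToGrid(cs, src, grid)
    }
  }
  SensitivityCurves(ft, cs)
}

#' Subtract the dark cube from a measurement cube
#'
#' Removes sensor dark noise; negative differences are clamped to zero so
#' every downstream stage sees non-negative counts.
#'
#' @param cube fluorescence or white-light \linkS4class{HyperCube}
#' @param dark dark \linkS4class{HyperCube} of identical shape and grid
#' @return the dark-subtracted cube (role preserved)
#' @export
subtractDark <- function(cube, dark) {
  if (!identical(dim(cube@data), dim(dark@data)))
    stop("cube and dark must have identical dimensions")
  if (!sameGrid(cube@grid, dark@grid))
    stop("cube and dark must share one wavelength grid")
  HyperCube(pmax(cube@data - dark@data, 0), cube@grid, cube@role,
            cube@exposure_ms)
}

#' Correct a cube for filter and camera sensitivity
#'
#' Band i is divided by \code{filter_transmission[i] * camera_sensitivity[i]}.
#'
#' @param cube dark-subtracted \linkS4class{HyperCube}
#' @param curves a \linkS4class{SensitivityCurves} on the cube's grid
#' @return corrected cube
#' @export
correctSensitivity <- function(cube, curves) {
  denom <- curves@filter_transmission * curves@camera_sensitivity
  if (length(denom) != dim(cube@data)[1])
    stop("sensitivity curves must have one entry per band")
  if (any(denom <= 0)) stop("sensitivity curve entries must be > 0")
  HyperCube(cube@data / denom, cube@grid, cube@role, cube@exposure_ms)
}

#' Average non-overlapping b x b pixel blocks
#'
#' Spatial binning to raise SNR: each output pixel is the mean of a
#' b x b block; remainder rows/columns beyond the last full block are
#' dropped.
#'
#' @param cube a \linkS4class{HyperCube}
#' @param b block edge in pixels (default 10)
#' @return binned cube with floor(H/b) x floor(W/b) pixels
#' @export
binPixels <- function(cube, b = 10L) {
  b <- as.integer(b)
  if (is.na(b) || b <= 0L) stop("b must be a positive integer")
  d <- dim(cube@data)
  if (b == 1L) return(cube)
  Ho <- d[2] %/% b; Wo <- d[3] %/% b
  if (Ho < 1L || Wo < 1L) stop("cube smaller than one block")
  x <- cube@data[, seq_len(Ho * b), seq_len(Wo * b), drop = FALSE]
  # fold each spatial axis into (b, out) and average the b-axes
  dim(x) <- c(d[1], b, Ho, b, Wo)
  out <- apply(x, c(1, 3, 5), mean)
  HyperCube(out, cube@grid, cube@role, cube@exposure_ms)
}

#' Foreground mask from a binned white-light cube
#'
#' Classical sample detection: Otsu threshold on the band-integrated
#' intensity, morphological opening with a disk of radius 1 binned pixel
#' (removes speckle), then the largest connected component.
#'
#' @param white_cube binned white-light \linkS4class{HyperCube}
#' @return logical H' x W' matrix, TRUE on the sample
#' @export
maskForeground <- function(white_cube) {
  intensity <- apply(white_cube@data, c(2, 3), sum)
  rng <- range(intensity)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, rng[2]))
    stop("uniform white-light image: no foreground detectable")
  norm <- (intensity - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  kern <- EBImage::makeBrush(3, shape = "disc")
  opened <- EBImage::opening(EBImage::Image(mask * 1), kern) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(opened * 1))
  lab <- EBImage::imageData(lab)
  if (max(lab) < 1) stop("empty foreground after opening: sample not found")
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  m <- matrix(lab == keep, nrow(intensity), ncol(intensity))
  if (!any(m)) stop("empty foreground mask")
  m
}

#' Raw cube triplet to binned, corrected spectrum pairs
#'
#' The full preprocessing pipeline: dark-subtract the fluorescence and
#' white cubes, correct both for filter/camera sensitivity, bin b x b,
#' mask the sample, and emit one unlabeled pixel per retained binned
#' position. Pixel coordinates are kept in \code{colData} (\code{px_row},
#' \code{px_col}) for abundance-map rendering.
#'
#' @param fluo_cube,white_cube,dark_cube aligned \linkS4class{HyperCube}s
#' @param curves a \linkS4class{SensitivityCurves}; \code{NULL} for unit
#' @param b binning factor (default 10)
#' @param mask optional logical H' x W' matrix; default
#'   \code{maskForeground} of the binned white cube
#' @param group_id sample identifier stamped on every pixel
#' @return a \linkS4class{SpectraSet} (unlabeled)
#' @export
extractPairs <- function(fluo_cube, white_cube, dark_cube, curves = NULL,
                         b = 10L, mask = NULL, group_id = "sample") {
  f <- subtractDark(fluo_cube, dark_cube)
  w <- subtractDark(white_cube, dark_cube)
  if (!is.null(curves)) {
    f <- correctSensitivity(f, curves)
    w <- correctSensitivity(w, curves)
  }
  f <- binPixels(f, b)
  w <- binPixels(w, b)
  if (is.null(mask)) mask <- maskForeground(w)
  d <- dim(f@data)
  if (!identical(dim(mask), d[2:3]))
    stop("mask dimensions must match the binned cube")
  keep <- which(mask)
  if (length(keep) == 0L) stop("mask retains no pixels")
  fm <- matrix(f@data, d[1])[, keep, drop = FALSE]
  wm <- matrix(w@data, d[1])[, keep, drop = FALSE]
  out <- SpectraSet(fm, wm, f@grid, group_id = group_id)
  rc <- arrayInd(keep, d[2:3])
  SummarizedExperiment::colData(out)$px_row <- rc[, 1]
  SummarizedExperiment::colData(out)$px_col <- rc[, 2]
  out
}
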