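#' @include AllClasses.R AllGenerics.R WavelengthGrid.R
NULL

#' Construct an endmember library
#'
#' Columns are divided by their maxima so every endmember has unit peak;
#' abundances then carry all magnitude information. The applied scale
#' factors are kept in the object.
#'
#' @param B m x K non-negative matrix, one column per fluorophore emission
#'   spectrum
#' @param grid the \linkS4class{WavelengthGrid} the rows live on
#' @param names endmember names (defaults to colnames of B)
#' @return an \linkS4class{EndmemberLibrary}
#' @export
EndmemberLibrary <- function(B, grid, names = colnames(B)) {
  B <- as.matrix(B)
  if (is.null(names)) names <- paste0("endmember", seq_len(ncol(B)))
  peaks <- apply(B, 2, max)
  if (any(!is.finite(peaks)) || any(peaks <= 0))
    stop("every endmember must have a positive finite peak")
  B <- sweep(B, 2, peaks, "/")
  colnames(B) <- names
  new("EndmemberLibrary", B = B, grid = grid, scale_factors = peaks)
}

#' @describeIn EndmemberLibrary the peak-normalized m x K matrix B
#' @param x an EndmemberLibrary
#' @export
setMethod("endmemberMatrix", "EndmemberLibrary", function(x) x@B)

#' @describeIn EndmemberLibrary endmember names
#' @export
setMethod("endmemberNames", "EndmemberLibrary", function(x) colnames(x@B))

#' @describeIn EndmemberLibrary the wavelength grid
#' @export
setMethod("spectraGrid", "EndmemberLibrary", function(x) x@grid)

#' @describeIn EndmemberLibrary sampled wavelengths in nm
#' @export
setMethod("wavelengths", "EndmemberLibrary", function(x) wavelengths(x@grid))

#' Write an endmember library to CSV
#'
#' First column \code{wavelength_nm}, then one column per endmember.
#'
#' @param x an \linkS4class{EndmemberLibrary}
#' @param path output path
#' @export
writeEndmemberLibrary <- function(x, path) {
  dt <- data.table::data.table(wavelength_nm = wavelengths(x))
  dt <- cbind(dt, data.table::as.data.table(endmemberMatrix(x)))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Read an endmember library from CSV
#'
#' Columns are re-normalized to unit peak on load (scale factors recorded
#' in the returned object). If \code{grid} is supplied and differs from the
#' file's wavelengths, spectra are linearly resampled onto it.
#'
#' @param path CSV with a \code{wavelength_nm} column plus one column per
#'   endmember
#' @param grid optional target \linkS4class{WavelengthGrid}
#' @return an \linkS4class{EndmemberLibrary}
#' @export
readEndmemberLibrary <- function(path, grid = NULL) {
  dt <- data.table::fread(path)
  if (!("wavelength_nm" %in% colnames(dt)))
    stop("endmember CSV must have a wavelength_nm column")
  src <- gridFromWavelengths(dt$wavelength_nm)
  B <- as.matrix(dt[, setdiff(colnames(dt), "wavelength_nm"), with = FALSE])
  if (!is.null(grid) && !sameGrid(src, grid)) {
    B <- apply(B, 2, resampleToGrid, source = src, target = grid)
  } else grid <- src
  EndmemberLibrary(B, grid)
}
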