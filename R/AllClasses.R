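#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib fluorounmix, .registration = TRUE
NULL

#' Uniform wavelength grid
#'
#' Describes the spectral sampling of an acquisition: \code{n_bands}
#' wavelengths starting at \code{start_nm} with constant spacing
#' \code{step_nm}. The default (421 nm start, 3 nm step, 104 bands) matches
#' a liquid-crystal tunable filter sweep from 421 to 730 nm.
#'
#' @slot start_nm first sampled wavelength in nm
#' @slot step_nm band spacing in nm (strictly positive)
#' @slot n_bands number of bands (at least 2)
#' @export
setClass("WavelengthGrid",
  representation(start_nm = "numeric", step_nm = "numeric", n_bands = "integer"),
  prototype(start_nm = 421, step_nm = 3, n_bands = 104L)
)

setValidity("WavelengthGrid", function(object) {
  if (length(object@start_nm) != 1L || !is.finite(object@start_nm))
    return("start_nm must be a single finite number")
  if (length(object@step_nm) != 1L || !is.finite(object@step_nm) || object@step_nm <= 0)
    return("step_nm must be a single positive number")
  if (length(object@n_bands) != 1L || is.na(object@n_bands) || object@n_bands < 2L)
    return("n_bands must be an integer >= 2")
  TRUE
})

#' Paired fluorescence / white-light spectra
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one column per
#' binned pixel with two assays: \code{fluo} (405 nm-excited fluorescence
#' emission, camera counts) and \code{ref} (white-light reflectance, camera
#' counts). Rows are wavelength bands. \code{colData} carries the sample /
#' vial identifier (\code{group_id}), the known PpIX concentration
#' (\code{c_ppix}, \code{NA} when unlabeled) and its unit
#' (\code{unit_tag}: \code{"ug_per_ml"}, \code{"pmol_per_mg"} or
#' \code{"unlabeled"}). The \linkS4class{WavelengthGrid} lives in
#' \code{metadata(x)$grid}.
#'
#' @export
#' @import SummarizedExperiment
setClass("SpectraSet", contains = "SummarizedExperiment")

.unit_tags <- c("ug_per_ml", "pmol_per_mg", "unlabeled")

setValidity("SpectraSet", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("fluo", "ref") %in% an))
    return("assays must include 'fluo' and 'ref'")
  grid <- S4Vectors::metadata(object)$grid
  if (!is(grid, "WavelengthGrid"))
    return("metadata(x)$grid must be a WavelengthGrid")
  if (nrow(object) != grid@n_bands)
    return("row count must equal grid n_bands")
  cd <- SummarizedExperiment::colData(object)
  need <- c("group_id", "c_ppix", "unit_tag")
  if (!all(need %in% colnames(cd)))
    return("colData must contain group_id, c_ppix, unit_tag")
  if (!all(cd$unit_tag %in% .unit_tags))
    return(sprintf("unit_tag must be one of %s", paste(.unit_tags, collapse = ", ")))
  lab <- cd$unit_tag != "unlabeled"
  if (any(lab & is.na(cd$c_ppix)))
    return("labeled pairs (unit_tag != 'unlabeled') must have c_ppix")
  if (any(!lab & !is.na(cd$c_ppix)))
    return("unlabeled pairs must have c_ppix = NA")
  if (ncol(object) > 0) {
    for (a in c("fluo", "ref")) {
      v <- SummarizedExperiment::assay(object, a)
      if (any(!is.finite(v)) || any(v < 0))
        return(sprintf("assay '%s' must be finite and non-negative", a))
    }
    if (any(!is.na(cd$c_ppix) & cd$c_ppix < 0))
      return("c_ppix must be non-negative")
  }
  TRUE
})

#' Endmember library
#'
#' The m x K matrix B whose columns are pure fluorophore emission spectra
#' on a common \linkS4class{WavelengthGrid}. Columns are peak-normalized
#' (maximum 1) at construction; the scale factors applied are retained in
#' \code{scale_factors} so absolute abundances can be mapped back if the
#' source library carried physical units.
#'
#' @slot B peak-normalized m x K spectral matrix, full column rank
#' @slot grid the shared wavelength grid
#' @slot scale_factors the per-column maxima divided out at construction
#' @export
setClass("EndmemberLibrary",
  representation(B = "matrix", grid = "WavelengthGrid", scale_factors = "numeric")
)

setValidity("EndmemberLibrary", function(object) {
  B <- object@B
  if (ncol(B) < 1L) return("need at least one endmember")
  if (nrow(B) != object@grid@n_bands) return("row count must equal grid n_bands")
  if (any(!is.finite(B)) || any(B < 0)) return("B must be finite and non-negative")
  if (is.null(colnames(B))) return("endmember columns must be named")
  if (max(abs(apply(B, 2, max) - 1)) > 1e-9) return("columns must be peak-normalized to 1")
  if (qr(B)$rank < ncol(B)) return("endmember columns must be linearly independent")
  TRUE
})

#' Hyperspectral data cube
#'
#' A bands x rows x cols image stack with its wavelength grid and a role
#' tag: \code{"fluorescence"} (405 nm-excited emission), \code{"white"}
#' (broadband reflectance) or \code{"dark"} (shutter-closed sensor noise).
#'
#' @slot data numeric array, dim = c(n_bands, H, W)
#' @slot grid the wavelength grid
#' @slot role one of "fluorescence", "white", "dark"
#' @slot exposure_ms exposure time per band in milliseconds
#' @export
setClass("HyperCube",
  representation(data = "array", grid = "WavelengthGrid",
                 role = "character", exposure_ms = "numeric")
)

.cube_roles <- c("fluorescence", "white", "dark")

setValidity("HyperCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-d array (bands x H x W)")
  if (d[1] != object@grid@n_bands) return("band count must equal grid n_bands")
  if (d[2] < 1L || d[3] < 1L) return("H and W must be >= 1")
  if (!(object@role %in% .cube_roles))
    return(sprintf("role must be one of %s", paste(.cube_roles, collapse = ", ")))
  if (any(!is.finite(object@data))) return("cube data must be finite")
  TRUE
})

#' Per-band instrument sensitivity curves
#'
#' Filter transmission and camera quantum sensitivity sampled on the
#' acquisition grid; both must be strictly positive so division is safe.
#'
#' @export
setClass("SensitivityCurves",
  representation(filter_transmission = "numeric", camera_sensitivity = "numeric")
)

setValidity("SensitivityCurves", function(object) {
  ft <- object@filter_transmission; cs <- object@camera_sensitivity
  if (length(ft) != length(cs)) return("curves must have equal length")
  if (any(!is.finite(ft)) || any(ft <= 0)) return("filter_transmission must be > 0")
  if (any(!is.finite(cs)) || any(cs <= 0)) return("camera_sensitivity must be > 0")
  TRUE
})

#' Trained model container
#'
#' Architecture configuration, learned parameters, learned homoscedastic
#' loss weights (log sigma), and per-epoch training history for any of the
#' package's learned predictors ("acunet", "acusa", "mlp", "pls").
#'
#' @slot kind model family identifier
#' @slot config architecture / optimizer configuration used to build it
#' @slot params named list of parameter arrays (or the fitted object for PLS)
#' @slot state learned non-architecture state, e.g. log-sigma loss weights
#' @slot history data.frame of per-epoch training diagnostics
#' @export
setClass("FluoroModel",
  representation(kind = "character", config = "list", params = "list",
                 state = "list", history = "data.frame")
)

setValidity("FluoroModel", function(object) {
  if (!(object@kind %in% c("acunet", "acusa", "mlp", "pls")))
    return("kind must be one of acunet, acusa, mlp, pls")
  TRUE
})

setMethod("show", "WavelengthGrid", function(object) {
  cat(sprintf("WavelengthGrid: %d bands, %.4g-%.4g nm, step %.4g nm\n",
              object@n_bands, object@start_nm,
              object@start_nm + (object@n_bands - 1L) * object@step_nm,
              object@step_nm))
})

setMethod("show", "SpectraSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("SpectraSet: %d bands x %d pixels, %d groups, units: %s\n",
              nrow(object), ncol(object),
              length(unique(cd$group_id)),
              paste(unique(cd$unit_tag), collapse = "/")))
})

setMethod("show", "EndmemberLibrary", function(object) {
  cat(sprintf("EndmemberLibrary: %d bands x %d endmembers (%s)\n",
              nrow(object@B), ncol(object@B),
              paste(colnames(object@B), collapse = ", ")))
})

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperCube[%s]: %d bands x %d x %d, exposure %g ms\n",
              object@role, d[1], d[2], d[3], object@exposure_ms))
})

setMethod("show", "FluoroModel", function(object) {
  cat(sprintf("FluoroModel<%s>: %d parameter arrays, %d training epochs\n",
              object@kind, length(object@params), nrow(object@history)))
})
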