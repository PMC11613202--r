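#' @include AllClasses.R AllGenerics.R WavelengthGrid.R
NULL

#' Construct a SpectraSet
#'
#' @param fluo m x n matrix of fluorescence emission spectra (counts)
#' @param ref m x n matrix of white-light reflectance spectra (counts)
#' @param grid the shared \linkS4class{WavelengthGrid}
#' @param group_id character vector (length n or 1): vial / homogenate
#'   sample / biopsy identifier, used for split-by-sample evaluation
#' @param c_ppix known PpIX concentration per pixel, or \code{NULL} for
#'   unlabeled data
#' @param unit_tag "ug_per_ml", "pmol_per_mg" or "unlabeled"
#' @return a \linkS4class{SpectraSet}
#' @export
SpectraSet <- function(fluo, ref, grid, group_id = "sample",
                       c_ppix = NULL, unit_tag = NULL) {
  fluo <- as.matrix(fluo); ref <- as.matrix(ref)
  if (!identical(dim(fluo), dim(ref)))
    stop("fluo and ref must have identical dimensions")
  n <- ncol(fluo)
  if (is.null(unit_tag)) unit_tag <- if (is.null(c_ppix)) "unlabeled" else "ug_per_ml"
  if (is.null(c_ppix)) c_ppix <- rep(NA_real_, n)
  cd <- S4Vectors::DataFrame(
    group_id = rep_len(as.character(group_id), n),
    c_ppix = rep_len(as.numeric(c_ppix), n),
    unit_tag = rep_len(as.character(unit_tag), n)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fluo = unname(fluo), ref = unname(ref)),
    rowData = S4Vectors::DataFrame(wavelength_nm = wavelengths(grid)),
    colData = cd,
    metadata = list(grid = grid)
  )
  new("SpectraSet", se)
}

#' @describeIn SpectraSet fluorescence assay matrix (bands x pixels)
#' @param x a SpectraSet
#' @export
setMethod("fluoSpectra", "SpectraSet", function(x)
  SummarizedExperiment::assay(x, "fluo"))

#' @describeIn SpectraSet white-light reflectance assay matrix
#' @export
setMethod("refSpectra", "SpectraSet", function(x)
  SummarizedExperiment::assay(x, "ref"))

#' @describeIn SpectraSet PpIX concentration labels (NA when unlabeled)
#' @export
setMethod("ppixConc", "SpectraSet", function(x)
  SummarizedExperiment::colData(x)$c_ppix)

#' @describeIn SpectraSet group identifiers (vial / sample / biopsy)
#' @export
setMethod("groupIds", "SpectraSet", function(x)
  SummarizedExperiment::colData(x)$group_id)

#' @describeIn SpectraSet concentration unit tags
#' @export
setMethod("unitTags", "SpectraSet", function(x)
  SummarizedExperiment::colData(x)$unit_tag)

#' @describeIn SpectraSet the wavelength grid
#' @export
setMethod("spectraGrid", "SpectraSet", function(x)
  S4Vectors::metadata(x)$grid)

#' @describeIn SpectraSet sampled wavelengths in nm
#' @export
setMethod("wavelengths", "SpectraSet", function(x)
  wavelengths(spectraGrid(x)))

.fmt_wl <- function(wl) sub("\\.?0+$", "", sprintf("%.4f", wl))

#' Write spectra to a delimited text table
#'
#' One row per binned pixel with columns \code{group_id}, \code{unit_tag},
#' \code{c_ppix} (empty when unlabeled), then \code{f_<wavelength>} and
#' \code{w_<wavelength>} columns. Wavelengths are embedded in the header so
#' the file is self-describing; values are written with 15 significant
#' digits, making the round trip lossless to ~1e-15 relative.
#'
#' @param x a \linkS4class{SpectraSet}
#' @param path output file path (CSV, UTF-8, '.' decimal)
#' @return \code{path}, invisibly
#' @export
writeSpectraTable <- function(x, path) {
  stopifnot(is(x, "SpectraSet"))
  wl <- .fmt_wl(wavelengths(x))
  f <- t(fluoSpectra(x)); w <- t(refSpectra(x))
  colnames(f) <- paste0("f_", wl); colnames(w) <- paste0("w_", wl)
  dt <- data.table::data.table(
    group_id = groupIds(x), unit_tag = unitTags(x), c_ppix = ppixConc(x))
  dt <- cbind(dt, data.table::as.data.table(f), data.table::as.data.table(w))
  data.table::fwrite(dt, path, na = "", quote = FALSE)
  invisible(path)
}

#' Read spectra from a delimited text table
#'
#' Inverse of \code{\link{writeSpectraTable}}. The wavelength grid is
#' inferred from the \code{f_}/\code{w_} column names; an empty
#' \code{c_ppix} entry makes the pixel unlabeled.
#'
#' @param path CSV file as written by \code{writeSpectraTable}
#' @return a \linkS4class{SpectraSet}
#' @export
readSpectraTable <- function(path) {
  dt <- data.table::fread(path, na.strings = "")
  cn <- colnames(dt)
  fcols <- grep("^f_", cn, value = TRUE)
  wcols <- grep("^w_", cn, value = TRUE)
  if (length(fcols) == 0L) stop("no f_<wavelength> columns found")
  if (length(fcols) != length(wcols))
    stop(sprintf("format error: %d fluorescence but %d white-light columns",
                 length(fcols), length(wcols)))
  fwl <- as.numeric(sub("^f_", "", fcols))
  wwl <- as.numeric(sub("^w_", "", wcols))
  if (any(abs(fwl - wwl) > 1e-6))
    stop("format error: f_ and w_ wavelength grids differ")
  grid <- gridFromWavelengths(fwl)
  f <- t(as.matrix(dt[, fcols, with = FALSE]))
  w <- t(as.matrix(dt[, wcols, with = FALSE]))
  bad <- which(apply(f < 0, 2, any) | apply(w < 0, 2, any))
  if (length(bad))
    stop(sprintf("validation error: negative spectral values in row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  cp <- if ("c_ppix" %in% cn) as.numeric(dt$c_ppix) else rep(NA_real_, ncol(f))
  ut <- if ("unit_tag" %in% cn) as.character(dt$unit_tag) else
    rep("unlabeled", ncol(f))
  ut[is.na(cp)] <- "unlabeled"
  gid <- if ("group_id" %in% cn) as.character(dt$group_id) else "sample"
  SpectraSet(f, w, grid, group_id = gid, c_ppix = cp, unit_tag = ut)
}

#' Combine SpectraSets column-wise
#'
#' @param ... SpectraSets on one grid
#' @return the concatenated \linkS4class{SpectraSet}
#' @export
bindSpectra <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is(xs[[1]], "SpectraSet"))
    xs <- xs[[1]]
  g <- spectraGrid(xs[[1]])
  for (x in xs[-1]) if (!sameGrid(g, spectraGrid(x)))
    stop("cannot combine SpectraSets on different grids")
  SpectraSet(
    do.call(cbind, lapply(xs, fluoSpectra)),
    do.call(cbind, lapply(xs, refSpectra)),
    g,
    group_id = unlist(lapply(xs, groupIds)),
    c_ppix = unlist(lapply(xs, ppixConc)),
    unit_tag = unlist(lapply(xs, unitTags))
  )
}
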