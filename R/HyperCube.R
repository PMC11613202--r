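#' @include AllClasses.R AllGenerics.R WavelengthGrid.R
NULL

#' Construct a hyperspectral cube
#'
#' @param data numeric array, dim = c(n_bands, H, W)
#' @param grid the \linkS4class{WavelengthGrid}
#' @param role "fluorescence", "white" or "dark"
#' @param exposure_ms per-band exposure in ms (default 500)
#' @return a \linkS4class{HyperCube}
#' @export
HyperCube <- function(data, grid, role = "fluorescence", exposure_ms = 500) {
  new("HyperCube", data = data, grid = grid, role = role,
      exposure_ms = as.numeric(exposure_ms))
}

#' @describeIn HyperCube the bands x H x W data array
#' @param x a HyperCube
#' @export
setMethod("cubeData", "HyperCube", function(x) x@data)

#' @describeIn HyperCube the role tag
#' @export
setMethod("cubeRole", "HyperCube", function(x) x@role)

#' @describeIn HyperCube the wavelength grid
#' @export
setMethod("spectraGrid", "HyperCube", function(x) x@grid)

#' @describeIn HyperCube sampled wavelengths in nm
#' @export
setMethod("wavelengths", "HyperCube", function(x) wavelengths(x@grid))

.envi_role <- function(role) switch(role,
  fluorescence = "fluorescence", white = "white", dark = "dark", role)

#' Write a cube as an ENVI header + band-sequential binary
#'
#' Writes \code{<base>.hdr} (text) and \code{<base>.raw} (64-bit IEEE
#' little-endian, BSQ interleave). Wavelengths are listed in the header so
#' the file round-trips through \code{\link{readEnviCube}} exactly.
#'
#' @param x a \linkS4class{HyperCube}
#' @param base path without extension
#' @return the header path, invisibly
#' @export
writeEnviCube <- function(x, base) {
  d <- dim(x@data)
  hdr <- paste0(base, ".hdr"); raw <- paste0(base, ".raw")
  wl <- paste(.fmt_wl(wavelengths(x)), collapse = ", ")
  lines <- c(
    "ENVI",
    sprintf("description = {fluorounmix %s cube}", x@role),
    sprintf("samples = %d", d[3]),
    sprintf("lines = %d", d[2]),
    sprintf("bands = %d", d[1]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("exposure ms = %g", x@exposure_ms),
    sprintf("wavelength units = nm"),
    sprintf("wavelength = {%s}", wl)
  )
  writeLines(lines, hdr)
  # BSQ: band-major, rows (lines) next, samples fastest
  con <- file(raw, "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(x@data, c(3, 2, 1))), con, size = 8, endian = "little")
  invisible(hdr)
}

.parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get1 <- function(key) {
    m <- regmatches(txt, regexec(sprintf("(?mi)^%s\\s*=\\s*([^\\{\\n]+)$", key),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) NA_character_ else trimws(m[2])
  }
  getblock <- function(key) {
    m <- regmatches(txt, regexec(sprintf("(?si)%s\\s*=\\s*\\{([^}]*)\\}", key),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  list(samples = as.integer(get1("samples")),
       lines = as.integer(get1("lines")),
       bands = as.integer(get1("bands")),
       dtype = as.integer(get1("data type")),
       interleave = tolower(get1("interleave")),
       byte_order = as.integer(get1("byte order")),
       exposure = suppressWarnings(as.numeric(get1("exposure ms"))),
       wavelength = getblock("wavelength"))
}

#' Read an ENVI band-sequential cube
#'
#' Supports BSQ interleave with IEEE float (data type 4) or double (5)
#' pixels. The header must list the band wavelengths.
#'
#' @param hdr_path path to the \code{.hdr} header; the binary is looked up
#'   next to it (\code{.raw}, \code{.img}, \code{.dat} or extensionless)
#' @param role role tag for the returned cube (default "fluorescence")
#' @return a \linkS4class{HyperCube}
#' @export
readEnviCube <- function(hdr_path, role = "fluorescence") {
  h <- .parse_envi_header(hdr_path)
  if (is.na(h$wavelength)) stop("ENVI header has no wavelength field")
  wl <- as.numeric(strsplit(h$wavelength, ",")[[1]])
  if (anyNA(wl)) stop("unparseable wavelength list in ENVI header")
  if (length(wl) != h$bands)
    stop(sprintf("header lists %d wavelengths but %d bands", length(wl), h$bands))
  if (!identical(h$interleave, "bsq"))
    stop("only BSQ interleave is supported")
  if (!(h$dtype %in% c(4L, 5L)))
    stop("only ENVI data types 4 (float) and 5 (double) are supported")
  base <- sub("\\.hdr$", "", hdr_path)
  raw <- NULL
  for (ext in c(".raw", ".img", ".dat", "")) {
    if (file.exists(paste0(base, ext))) { raw <- paste0(base, ext); break }
  }
  if (is.null(raw)) stop("no binary file found next to header")
  n <- h$samples * h$lines * h$bands
  endian <- if (identical(h$byte_order, 1L)) "big" else "little"
  con <- file(raw, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = if (h$dtype == 4L) 4 else 8,
               endian = endian)
  if (length(v) != n) stop("binary file shorter than header promises")
  data <- aperm(array(v, c(h$samples, h$lines, h$bands)), c(3, 2, 1))
  HyperCube(data, gridFromWavelengths(wl), role = role,
            exposure_ms = if (is.na(h$exposure)) 500 else h$exposure)
}
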