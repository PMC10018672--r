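#' Hounsfield-unit / relative-electron-density calibration curve
#'
#' A monotone piecewise-linear mapping between CT numbers (HU) and relative
#' electron density (RED, water = 1). Treatment planning systems ship such a
#' curve to convert CT numbers to electron density for dose calculation; the
#' same curve links the ICRU-46 electron densities of bone, fat and lung to
#' the HU thresholds used for tissue masks.
#'
#' The default curve is pinned so that the tissue electron densities used in
#' this package map exactly onto the corresponding HU mask thresholds:
#' air (RED 0) at -1000 HU, lung (0.26) at -740 HU, fat (0.93-0.98) at
#' -100..-20 HU, water (1.0) at 0 HU and bone (1.2) at 150 HU, extended to
#' 1500 HU. Vendor curves are not published; internal consistency between
#' thresholds and their electron-density provenance is preferred over
#' guessing one, and the curve is user-replaceable (see
#' [read_calibration_curve()]). Tissue-mask thresholds themselves are stored
#' in HU (see [tissue_thresholds()]), so replacing the curve never silently
#' moves a mask threshold.
#'
#' @param hu numeric vector of node HU values, strictly increasing; must
#'   cover at least \[-1000, 1500\].
#' @param red numeric vector of node RED values, non-decreasing, same length.
#' @return A `calibration_curve` object.
#' @export
calibration_curve <- function(hu, red) {
  hu <- as.numeric(hu); red <- as.numeric(red)
  if (length(hu) < 2L || length(hu) != length(red))
    stop("need at least 2 (HU, RED) node pairs of equal length", call. = FALSE)
  if (any(!is.finite(hu)) || any(!is.finite(red)))
    stop("curve nodes must be finite", call. = FALSE)
  if (any(diff(hu) <= 0))
    stop("HU nodes must be strictly increasing", call. = FALSE)
  if (any(diff(red) < 0))
    stop("RED nodes must be non-decreasing", call. = FALSE)
  if (hu[1] > -1000 || hu[length(hu)] < 1500)
    stop("curve must cover at least HU in [-1000, 1500]", call. = FALSE)
  structure(list(hu = hu, red = red), class = "calibration_curve")
}

#' @rdname calibration_curve
#' @export
default_calibration_curve <- function() {
  calibration_curve(
    hu  = c(-1000, -740, -100, -20, 0, 150, 1500),
    red = c(0.0, 0.26, 0.93, 0.98, 1.0, 1.2, 2.0)
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve>\n")
  print(data.frame(HU = x$hu, RED = x$red), row.names = FALSE)
  invisible(x)
}

#' Convert between relative electron density and Hounsfield units
#'
#' Piecewise-linear interpolation on the calibration curve nodes. The two
#' directions are exact inverses on segments where RED is strictly
#' increasing. Values outside the curve's range are an error naming the
#' admissible interval, never extrapolated.
#'
#' @param curve a [calibration_curve()].
#' @param red,hu numeric vector of values to convert.
#' @return numeric vector of HU (for `red_to_hu`) or RED (for `hu_to_red`).
#' @examples
#' crv <- default_calibration_curve()
#' red_to_hu(crv, c(0, 1, 1.2))   # -1000, 0, 150
#' hu_to_red(crv, c(-1000, 0, 150))
#' @export
red_to_hu <- function(curve, red) {
  stopifnot(inherits(curve, "calibration_curve"))
  rng <- range(curve$red)
  if (any(red < rng[1] | red > rng[2], na.rm = TRUE))
    stop(sprintf("RED out of range: admissible interval is [%g, %g]",
                 rng[1], rng[2]), call. = FALSE)
  # on a flat (non-increasing RED) segment approx() with ties = min picks the
  # segment's lower HU end deterministically
  stats::approx(curve$red, curve$hu, xout = red, method = "linear",
                ties = min)$y
}

#' @rdname red_to_hu
#' @export
hu_to_red <- function(curve, hu) {
  stopifnot(inherits(curve, "calibration_curve"))
  rng <- range(curve$hu)
  if (any(hu < rng[1] | hu > rng[2], na.rm = TRUE))
    stop(sprintf("HU out of range: admissible interval is [%g, %g]",
                 rng[1], rng[2]), call. = FALSE)
  stats::approx(curve$hu, curve$red, xout = hu, method = "linear")$y
}

#' Load a calibration curve from a config file
#'
#' Accepts either a JSON file with fields `hu` and `red` (equal-length
#' arrays) or a plain-text two-column table (HU, RED per row; `#` comments
#' and a header line are tolerated).
#'
#' @param path file path.
#' @return A `calibration_curve`.
#' @export
read_calibration_curve <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(j$hu) || is.null(j$red))
      stop("JSON calibration curve needs 'hu' and 'red' arrays", call. = FALSE)
    return(calibration_curve(j$hu, j$red))
  }
  tab <- utils::read.table(path, comment.char = "#", header = FALSE,
                           col.names = c("hu", "red"),
                           colClasses = c("character", "character"))
  suppressWarnings({
    hu <- as.numeric(tab$hu); red <- as.numeric(tab$red)
  })
  keep <- !is.na(hu) & !is.na(red)   # drops a header line if present
  calibration_curve(hu[keep], red[keep])
}
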