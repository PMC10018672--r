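#' 3D scalar volume on a regular grid
#'
#' The basic carrier for images (HU) and dose grids (Gy): a 3D numeric array
#' with voxel spacing and origin in millimetres. The first array axis is the
#' slice (cranial-caudal) axis; axes two and three are in-plane row and
#' column. All pairwise comparisons in this package require both volumes to
#' live on the identical grid; geometry mismatch is always a hard error,
#' never silent resampling.
#'
#' @param values 3D numeric array.
#' @param spacing voxel spacing in mm, length-3 positive numeric
#'   (slice, row, column).
#' @param origin position of the first voxel centre in mm, length 3.
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' Binary mask on a volume grid geometry
#'
#' @param values 3D logical (or 0/1 numeric) array.
#' @param spacing,origin grid geometry, as in [volume_grid()].
#' @param label name of the mask (structure name, tissue class, ...).
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        label = "mask") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  v <- array(as.logical(values), dim = dim(values))
  if (anyNA(v)) stop("mask values must be TRUE/FALSE without NA", call. = FALSE)
  g <- volume_grid(array(0, dim = dim(values)), spacing, origin)
  structure(list(values = v, spacing = g$spacing, origin = g$origin,
                 label = as.character(label)[1]),
            class = "binary_mask")
}

#' Build a mask sharing the geometry of an existing grid object
#'
#' @param values logical array with the template's dimensions.
#' @param template a `volume_grid` or `binary_mask` supplying the geometry.
#' @param label mask name.
#' @export
mask_like <- function(values, template, label = "mask") {
  stopifnot(identical(dim(values), dim(template$values)))
  binary_mask(values, template$spacing, template$origin, label)
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %s mm, range [%.6g, %.6g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> '%s' %d x %d x %d voxels, %d set\n",
              x$label, d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

#' Do two grid objects share shape, spacing and origin?
#'
#' @param a,b `volume_grid`, `binary_mask` or `displacement_field` objects.
#' @param tol tolerance on spacing/origin in mm.
#' @return logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values)[1:3], dim(b$values)[1:3]) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

assert_same_geometry <- function(..., what = "volumes") {
  objs <- list(...)
  ref <- objs[[1]]
  for (o in objs[-1]) {
    if (!same_geometry(ref, o))
      stop(sprintf("geometry mismatch between %s: shapes/spacings/origins must be identical (no silent resampling)",
                   what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Voxel volume in cubic centimetres
#'
#' @param x an object with a `spacing` field (mm).
#' @return scalar, cm^3 per voxel.
#' @export
voxel_volume_cc <- function(x) prod(x$spacing) / 1000

# -- NIfTI IO -----------------------------------------------------------------

#' Read / write volumes and masks as NIfTI
#'
#' Volumes are stored as floating point, masks as unsigned 8-bit labels.
#' Spacing is carried in the NIfTI pixdim; the origin is carried in this
#' package's own JSON sidecars when cases are written with [write_case()]
#' (NIfTI sform conventions differ in axis handedness across toolkits and
#' are deliberately not interpreted here).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param origin origin in mm to attach on read (default 0).
#' @return [read_volume()] a `volume_grid`; [read_mask()] a `binary_mask`.
#' @export
read_volume <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  a <- array(as.numeric(a), dim = dim(a)[1:3])  # drop NIfTI header attributes
  volume_grid(a, spacing = RNifti::pixdim(img)[1:3], origin = origin)
}

#' @rdname read_volume
#' @param vol a `volume_grid` to write.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param label mask name to attach on read.
#' @export
read_mask <- function(path, origin = c(0, 0, 0), label = "mask") {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- array(a, dim = dim(a)[1:3])
  if (!all(a %in% c(0, 1)))
    stop(sprintf("'%s' is not a binary label volume", path), call. = FALSE)
  binary_mask(a != 0, spacing = RNifti::pixdim(img)[1:3], origin = origin,
              label = label)
}

#' @rdname read_volume
#' @param mask a `binary_mask` to write (stored as uint8 0/1).
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$values), dim = dim(mask$values)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
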