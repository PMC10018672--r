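#' Displacement field on the common frame
#'
#' A per-voxel 3-vector field in mm mapping common-frame voxel positions to
#' the positions at which the daily-frame volume is sampled (pull-back
#' convention: `output(x) = input(x + u(x))`, the form in which resamplers
#' consume deformable-registration outputs). Estimating the registration is
#' out of scope; fields are consumed as data.
#'
#' @param vectors 4D numeric array `(slice, row, column, 3)`, mm, finite.
#' @param spacing,origin common-frame geometry as in [volume_grid()].
#' @return A `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  if (!is.array(vectors) || length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("`vectors` must be a 4D array with last dimension 3", call. = FALSE)
  if (any(!is.finite(vectors)))
    stop("displacement field components must be finite", call. = FALSE)
  g <- volume_grid(array(0, dim = dim(vectors)[1:3]), spacing, origin)
  structure(list(values = array(as.numeric(vectors), dim = dim(vectors)),
                 spacing = g$spacing, origin = g$origin),
            class = "displacement_field")
}

#' @rdname displacement_field
#' @param path NIfTI path; fields are stored as 4D volumes (three vector
#'   components, mm).
#' @export
read_displacement_field <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 5L) a <- array(a, dim = dim(a)[c(1:3, 5)]) # NIfTI t-dim
  displacement_field(a, spacing = RNifti::pixdim(img)[1:3], origin = origin)
}

#' @rdname displacement_field
#' @param field a `displacement_field` to write.
#' @export
write_displacement_field <- function(field, path) {
  img <- RNifti::asNifti(field$values)
  RNifti::pixdim(img) <- c(field$spacing, 1)  # 4th dim: vector component axis
  RNifti::writeNifti(img, path)
  invisible(path)
}

# fractional voxel sample coordinates (1-based) for every common-frame voxel
.warp_coords <- function(vol, field) {
  assert_same_geometry(vol, field, what = "volume and displacement field")
  dm <- dim(vol$values)
  ii <- array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dim = dm)
  jj <- array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dim = dm)
  kk <- array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dim = dm)
  list(
    i = ii + field$values[, , , 1] / vol$spacing[1],
    j = jj + field$values[, , , 2] / vol$spacing[2],
    k = kk + field$values[, , , 3] / vol$spacing[3],
    dm = dm
  )
}

.sample_nearest <- function(values, co, fill) {
  i <- round(co$i); j <- round(co$j); k <- round(co$k)
  dm <- co$dm
  inside <- i >= 1 & i <= dm[1] & j >= 1 & j <= dm[2] & k >= 1 & k <= dm[3]
  out <- array(fill, dim = dm)
  idx <- (i[inside] - 1) + dm[1] * ((j[inside] - 1) + dm[2] * (k[inside] - 1)) + 1
  out[inside] <- values[idx]
  attr(out, "n_out_of_field") <- sum(!inside)
  out
}

.sample_trilinear <- function(values, co, fill) {
  dm <- co$dm
  i0 <- floor(co$i); j0 <- floor(co$j); k0 <- floor(co$k)
  fi <- co$i - i0; fj <- co$j - j0; fk <- co$k - k0
  # clamp the upper corner back when the sample sits exactly on a node
  i1 <- ifelse(fi == 0, i0, i0 + 1)
  j1 <- ifelse(fj == 0, j0, j0 + 1)
  k1 <- ifelse(fk == 0, k0, k0 + 1)
  inside <- i0 >= 1 & i1 <= dm[1] & j0 >= 1 & j1 <= dm[2] & k0 >= 1 & k1 <= dm[3]
  out <- array(fill, dim = dm)
  lin <- function(a, b, c) (a[inside] - 1) + dm[1] * ((b[inside] - 1) + dm[2] * (c[inside] - 1)) + 1
  wi <- fi[inside]; wj <- fj[inside]; wk <- fk[inside]
  out[inside] <-
    (1 - wi) * (1 - wj) * (1 - wk) * values[lin(i0, j0, k0)] +
    wi * (1 - wj) * (1 - wk) * values[lin(i1, j0, k0)] +
    (1 - wi) * wj * (1 - wk) * values[lin(i0, j1, k0)] +
    wi * wj * (1 - wk) * values[lin(i1, j1, k0)] +
    (1 - wi) * (1 - wj) * wk * values[lin(i0, j0, k1)] +
    wi * (1 - wj) * wk * values[lin(i1, j0, k1)] +
    (1 - wi) * wj * wk * values[lin(i0, j1, k1)] +
    wi * wj * wk * values[lin(i1, j1, k1)]
  attr(out, "n_out_of_field") <- sum(!inside)
  out
}

#' Warp a scalar volume through a displacement field
#'
#' Resamples the volume onto the common frame: each output voxel takes the
#' input value at its own position plus the field vector. Samples falling
#' outside the input grid are filled with `fill` (0 Gy for dose) and their
#' count is flagged in the `"n_out_of_field"` attribute. Plain resampling,
#' no Jacobian energy correction.
#'
#' @param vol `volume_grid` to warp.
#' @param field `displacement_field` on the same geometry.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill value for out-of-field samples.
#' @return warped `volume_grid` with attribute `"n_out_of_field"`.
#' @export
warp_scalar <- function(vol, field, interpolation = c("trilinear", "nearest"),
                        fill = 0) {
  stopifnot(inherits(vol, "volume_grid"), inherits(field, "displacement_field"))
  interpolation <- match.arg(interpolation)
  co <- .warp_coords(vol, field)
  out <- if (interpolation == "nearest") .sample_nearest(vol$values, co, fill)
         else .sample_trilinear(vol$values, co, fill)
  res <- volume_grid(array(out, dim = co$dm), vol$spacing, vol$origin)
  attr(res, "n_out_of_field") <- attr(out, "n_out_of_field")
  res
}

#' @rdname warp_scalar
#' @param mask `binary_mask` to warp (nearest-neighbour; stays binary,
#'   out-of-field samples become `FALSE`).
#' @export
warp_mask <- function(mask, field) {
  stopifnot(inherits(mask, "binary_mask"), inherits(field, "displacement_field"))
  co <- .warp_coords(mask, field)
  out <- .sample_nearest(mask$values, co, fill = FALSE)
  res <- mask_like(array(as.logical(out), dim = co$dm), mask, label = mask$label)
  attr(res, "n_out_of_field") <- attr(out, "n_out_of_field")
  res
}

#' Registration quality as planned-vs-warped structure overlap
#'
#' Dice score of the planned structure against the warped daily structure
#' (gross or clinical target volume), the standard sanity check on a
#' deformable registration before accumulating doses through it.
#'
#' @param planned,warped_daily `binary_mask`s on the common frame.
#' @return Dice in percent (see [dice()]).
#' @export
registration_quality <- function(planned, warped_daily)
  dice(planned, warped_daily)
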