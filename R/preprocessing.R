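#' Threshold body mask
#'
#' Voxels strictly above `threshold` HU. Thresholding both the reference and
#' the evaluated CT at -950 HU separates patient from background air and
#' from field-of-view edge effects, independently of the (sometimes
#' imprecise) delineated body structure.
#'
#' @param vol a `volume_grid` in HU.
#' @param threshold HU; the mask is `vol > threshold` (strict).
#' @return A `binary_mask`.
#' @export
threshold_body_mask <- function(vol, threshold = -950) {
  stopifnot(inherits(vol, "volume_grid"))
  mask_like(vol$values > threshold, vol,
            label = sprintf("body>%g", threshold))
}

#' Build the evaluation volume of interest
#'
#' The VOI is the intersection of the delineated body structure with the
#' two threshold body masks (reference and evaluated CT each > `threshold`
#' HU), with the `trim_slices` outermost slices at both the cranial and the
#' caudal end removed. Trimming discards whole axial slices regardless of
#' content, because synthetic CTs blur at the outermost slices (limited MRI
#' field of view, network padding).
#'
#' @param body_structure `binary_mask`, the delineated body outline.
#' @param dct,sct `volume_grid`s in HU on the same geometry.
#' @param threshold HU threshold applied to both volumes (strict `>`).
#' @param trim_slices number of slices removed at each cranial/caudal end.
#' @return A `binary_mask` labelled "voi".
#' @export
build_voi <- function(body_structure, dct, sct, threshold = -950,
                      trim_slices = 3) {
  stopifnot(inherits(body_structure, "binary_mask"),
            inherits(dct, "volume_grid"), inherits(sct, "volume_grid"))
  assert_same_geometry(body_structure, dct, sct, what = "body structure, dCT and sCT")
  n_slices <- dim(dct$values)[1]
  trim_slices <- as.integer(trim_slices)
  if (n_slices <= 2L * trim_slices)
    stop(sprintf("volume has %d slices; need more than 2 x trim_slices = %d",
                 n_slices, 2L * trim_slices), call. = FALSE)
  voi <- body_structure$values &
    (dct$values > threshold) &
    (sct$values > threshold)
  if (trim_slices > 0L) {
    voi[seq_len(trim_slices), , ] <- FALSE
    voi[seq(n_slices - trim_slices + 1L, n_slices), , ] <- FALSE
  }
  mask_like(voi, dct, label = "voi")
}

#' Overwrite mismatched air pockets in the reference CT
#'
#' Air pockets (bowel gas) move between the daily MRI, from which the
#' synthetic CT derives, and the deformed planning CT; that mismatch is not
#' the synthetic-CT algorithm's error. Within the VOI, voxels that look like
#' air in the reference CT (`dct < air_cut`) but like tissue in the
#' synthetic CT (`sct > tissue_cut`) are set to water (`fill` HU) in a copy
#' of the reference CT. The synthetic CT is never edited, only the
#' reference; the overwrite is restricted to the VOI so that background air
#' is never flooded with water. All inequalities are strict; boundary
#' values are untouched.
#'
#' @param dct reference CT `volume_grid` (HU); returned modified as a copy.
#' @param sct evaluated (synthetic) CT `volume_grid` (HU); never modified.
#' @param voi `binary_mask` restricting the overwrite.
#' @param air_cut HU; trigger requires `dct < air_cut`.
#' @param tissue_cut HU; trigger requires `sct > tissue_cut`.
#' @param fill HU value written (water = 0).
#' @return A `volume_grid` copy of `dct`; attribute `"changed"` holds the
#'   linear indices of overwritten voxels.
#' @export
overwrite_air_pockets <- function(dct, sct, voi, air_cut = -500,
                                  tissue_cut = -200, fill = 0) {
  stopifnot(inherits(dct, "volume_grid"), inherits(sct, "volume_grid"),
            inherits(voi, "binary_mask"))
  assert_same_geometry(dct, sct, voi, what = "dCT, sCT and VOI")
  hit <- voi$values & (dct$values < air_cut) & (sct$values > tissue_cut)
  out <- dct
  out$values[hit] <- fill
  attr(out, "changed") <- which(hit)
  out
}
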