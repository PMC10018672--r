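#' HU-agreement statistics between a reference and an evaluated CT
#'
#' Mean error (signed, reference minus evaluated) and mean absolute error
#' over the voxels of a volume of interest:
#' \deqn{ME = \frac{1}{N}\sum_i (dCT_i - sCT_i), \qquad
#'       MAE = \frac{1}{N}\sum_i |dCT_i - sCT_i|}
#' where N is the number of VOI voxels. The sign convention is reference
#' minus evaluated throughout the package.
#'
#' @param dct,sct `volume_grid`s in HU on identical geometry.
#' @param voi non-empty `binary_mask`.
#' @return scalar HU.
#' @export
mean_error <- function(dct, sct, voi) {
  d <- .voi_diff(dct, sct, voi)
  mean(d)
}

#' @rdname mean_error
#' @export
mean_absolute_error <- function(dct, sct, voi) {
  d <- .voi_diff(dct, sct, voi)
  mean(abs(d))
}

.voi_diff <- function(dct, sct, voi) {
  stopifnot(inherits(dct, "volume_grid"), inherits(sct, "volume_grid"),
            inherits(voi, "binary_mask"))
  assert_same_geometry(dct, sct, voi, what = "dCT, sCT and VOI")
  sel <- voi$values
  if (!any(sel)) stop("VOI is empty", call. = FALSE)
  dct$values[sel] - sct$values[sel]
}

#' MAE in 20-HU intervals
#'
#' Mean absolute error computed separately in uniform HU bins (default
#' width 20 HU from -1000 to 1500 HU). VOI voxels are assigned to bins by
#' the reference (dCT) HU value, with half-open bins \[lower, upper) so
#' every in-range value lands in exactly one bin; 1500 HU itself is out of
#' range. Voxels outside \[-1000, 1500) are excluded from the bins and
#' counted in the `n_out_of_range` attribute. Bins indexed by the reference
#' image make the air-pocket overwrite visible as an occupancy drop below
#' the -500 HU trigger.
#'
#' @inheritParams mean_error
#' @param lower,upper,width bin range and width in HU.
#' @return data.frame with columns `lower`, `upper`, `mid`, `n`, `mae`
#'   (`mae` is `NA` for empty bins, flagged not erroneous); attribute
#'   `n_out_of_range` counts VOI voxels outside the bin range.
#' @export
binned_mae <- function(dct, sct, voi, lower = -1000, upper = 1500, width = 20) {
  d <- .voi_diff(dct, sct, voi)
  ref <- dct$values[voi$values]
  edges <- seq(lower, upper, by = width)
  in_range <- ref >= lower & ref < upper
  idx <- findInterval(ref[in_range], edges, rightmost.closed = FALSE)
  nbin <- length(edges) - 1L
  n <- tabulate(idx, nbins = nbin)
  abs_sum <- as.numeric(tapply(abs(d[in_range]),
                               factor(idx, levels = seq_len(nbin)), sum))
  abs_sum[is.na(abs_sum)] <- 0
  mae <- ifelse(n > 0, abs_sum / n, NA_real_)
  out <- data.frame(
    lower = edges[-length(edges)],
    upper = edges[-1],
    mid = (edges[-length(edges)] + edges[-1]) / 2,
    n = n,
    mae = mae
  )
  attr(out, "n_out_of_range") <- sum(!in_range)
  out
}

#' Tissue mask specifications from HU thresholds
#'
#' Threshold tissue classes used for Dice scoring: bone (> 150 HU), fat
#' (> -100 and < -20 HU) and lung (< -700 HU), all strict inequalities,
#' applied within the body outline. The thresholds correspond to ICRU-46
#' relative electron densities (bone 1.2, fat 0.93-0.98, lung 0.26) through
#' the default calibration curve, but are stored operationally in HU so a
#' replaced curve cannot silently move them.
#'
#' @param name tissue class name.
#' @param lower,upper HU bounds (`-Inf` / `Inf` for one-sided); the mask is
#'   `lower < value < upper` (strict).
#' @return `tissue_mask_spec` object; `tissue_thresholds()` returns the
#'   default named list of the three specs.
#' @export
tissue_mask_spec <- function(name, lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (!(lower < upper)) stop("need lower < upper", call. = FALSE)
  structure(list(name = as.character(name)[1], lower = lower, upper = upper),
            class = "tissue_mask_spec")
}

#' @rdname tissue_mask_spec
#' @export
tissue_thresholds <- function() {
  list(
    bone = tissue_mask_spec("bone", 150, Inf),
    fat  = tissue_mask_spec("fat", -100, -20),
    lung = tissue_mask_spec("lung", -Inf, -700)
  )
}

#' Threshold tissue mask within the body outline
#'
#' @param vol `volume_grid` in HU.
#' @param spec a [tissue_mask_spec()].
#' @param body `binary_mask` body outline restricting the mask.
#' @return A `binary_mask` named after the tissue class.
#' @export
tissue_mask <- function(vol, spec, body) {
  stopifnot(inherits(vol, "volume_grid"), inherits(spec, "tissue_mask_spec"),
            inherits(body, "binary_mask"))
  assert_same_geometry(vol, body, what = "volume and body mask")
  m <- body$values & (vol$values > spec$lower) & (vol$values < spec$upper)
  mask_like(m, vol, label = spec$name)
}

#' Dice similarity coefficient of two binary masks, in percent
#'
#' \deqn{DSC = 100\% \times \frac{2|A \cap B|}{|A| + |B|}}
#' 100 is complete overlap, 0 no overlap. Two empty masks have no defined
#' overlap: `NA` is returned (not-applicable, mirroring tissue classes
#' absent from an anatomy, e.g. lung in pelvic image volumes) rather than
#' 0 or 100. Empty versus non-empty is 0.
#'
#' @param a,b `binary_mask`s on identical geometry.
#' @return percent in \[0, 100\], or `NA` if both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  assert_same_geometry(a, b, what = "masks")
  na <- sum(a$values); nb <- sum(b$values)
  if (na == 0 && nb == 0) return(NA_real_)
  100 * 2 * sum(a$values & b$values) / (na + nb)
}

#' Tissue Dice scores for a dCT/sCT pair
#'
#' Convenience wrapper: builds the three threshold tissue masks on both
#' volumes within the body outline and returns their Dice scores. The lung
#' score is reported only when both lung masks exceed `min_lung_voxels`
#' (pelvic anatomies carry little to no lung tissue; a Dice on a handful of
#' noise voxels is not meaningful), otherwise `NA`.
#'
#' @inheritParams mean_error
#' @param body `binary_mask` body outline.
#' @param specs named list of [tissue_mask_spec()]s.
#' @param min_lung_voxels minimum voxel count in both lung masks for the
#'   lung score to be reported.
#' @return named numeric vector of Dice percentages.
#' @export
tissue_dice <- function(dct, sct, body, specs = tissue_thresholds(),
                        min_lung_voxels = 100) {
  out <- vapply(specs, function(sp) {
    ma <- tissue_mask(dct, sp, body)
    mb <- tissue_mask(sct, sp, body)
    if (identical(sp$name, "lung") &&
        (sum(ma$values) < min_lung_voxels || sum(mb$values) < min_lung_voxels))
      return(NA_real_)
    dice(ma, mb)
  }, numeric(1))
  names(out) <- vapply(specs, `[[`, character(1), "name")
  out
}
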