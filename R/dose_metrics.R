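#' One fraction's physical dose grid
#'
#' @param dose `volume_grid` in Gy, non-negative everywhere.
#' @param fraction integer fraction index (1-based).
#' @param basis which electron-density map the dose was calculated on:
#'   `"dCT"` (reference) or `"sCT"` (evaluated).
#' @return A `fraction_dose` object.
#' @export
fraction_dose <- function(dose, fraction = 1L, basis = c("dCT", "sCT")) {
  stopifnot(inherits(dose, "volume_grid"))
  if (any(dose$values < 0))
    stop("fraction dose must be non-negative everywhere", call. = FALSE)
  basis <- match.arg(basis)
  structure(list(dose = dose, fraction = as.integer(fraction), basis = basis),
            class = "fraction_dose")
}

#' DVH-point specification
#'
#' `Dv%` (dose to the hottest v percent of the structure volume), `Dxcc`
#' (dose to the hottest x cm^3) or `Dmean` (volume-weighted mean dose).
#'
#' @param kind `"percent"`, `"cc"` or `"mean"`.
#' @param value percent of structure volume in (0, 100\] for `"percent"`,
#'   cm^3 > 0 for `"cc"`, ignored for `"mean"`.
#' @return A `dvh_point_spec`; `format()` gives the conventional label
#'   (`D2%`, `D0.1cc`, `Dmean`).
#' @export
dvh_point_spec <- function(kind = c("percent", "cc", "mean"), value = NULL) {
  kind <- match.arg(kind)
  if (kind == "percent") {
    value <- as.numeric(value)
    if (!is.finite(value) || value <= 0 || value > 100)
      stop("percent-volume DVH point needs value in (0, 100]", call. = FALSE)
  } else if (kind == "cc") {
    value <- as.numeric(value)
    if (!is.finite(value) || value <= 0)
      stop("absolute-volume DVH point needs cm^3 > 0", call. = FALSE)
  } else value <- NA_real_
  structure(list(kind = kind, value = value), class = "dvh_point_spec")
}

#' @export
format.dvh_point_spec <- function(x, ...) {
  switch(x$kind,
         percent = sprintf("D%g%%", x$value),
         cc = sprintf("D%gcc", x$value),
         mean = "Dmean")
}

#' @export
print.dvh_point_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Named structure set for dosimetric evaluation
#'
#' A list of delineated structures, each with a binary mask, a role and a
#' fractionation-sensitivity parameter. The alpha/beta ratio defaults to
#' 10 Gy for target volumes and 3 Gy for organs at risk when not given.
#'
#' @param ... `rt_structure` objects.
#' @return A `structure_set` (list with class attribute).
#' @export
structure_set <- function(...) {
  structures <- list(...)
  if (length(structures) == 1L && is.list(structures[[1]]) &&
      !inherits(structures[[1]], "rt_structure"))
    structures <- structures[[1]]
  stopifnot(all(vapply(structures, inherits, logical(1), "rt_structure")))
  names(structures) <- vapply(structures, `[[`, character(1), "name")
  if (anyDuplicated(names(structures)))
    stop("structure names must be unique", call. = FALSE)
  structure(structures, class = "structure_set")
}

#' @rdname structure_set
#' @param name structure name.
#' @param mask `binary_mask` on the case's common frame.
#' @param role `"body"`, `"target"` or `"OAR"`.
#' @param alpha_beta alpha/beta in Gy (> 0); default 10 for targets, 3
#'   otherwise.
#' @param dvh_points list of [dvh_point_spec()]s evaluated for this
#'   structure.
#' @export
rt_structure <- function(name, mask, role = c("target", "OAR", "body"),
                         alpha_beta = NULL, dvh_points = list()) {
  role <- match.arg(role)
  stopifnot(inherits(mask, "binary_mask"))
  if (is.null(alpha_beta)) alpha_beta <- if (role == "target") 10 else 3
  if (!is.finite(alpha_beta) || alpha_beta <= 0)
    stop("alpha/beta must be a positive number of Gy", call. = FALSE)
  stopifnot(all(vapply(dvh_points, inherits, logical(1), "dvh_point_spec")))
  structure(list(name = as.character(name)[1], mask = mask, role = role,
                 alpha_beta = as.numeric(alpha_beta), dvh_points = dvh_points),
            class = "rt_structure")
}

#' Extract a structure's dose-volume histogram from a dose grid
#'
#' Takes the doses of exactly the masked voxels, each carrying the voxel
#' volume implied by the grid spacing, sorted in descending dose order.
#'
#' @param dose a `fraction_dose` or a dose `volume_grid` in Gy.
#' @param mask non-empty `binary_mask` of the structure.
#' @return A `dvh` object: descending voxel doses (Gy), per-voxel volume
#'   and total volume (cm^3).
#' @export
extract_structure_dose <- function(dose, mask) {
  if (inherits(dose, "fraction_dose")) dose <- dose$dose
  stopifnot(inherits(dose, "volume_grid"), inherits(mask, "binary_mask"))
  assert_same_geometry(dose, mask, what = "dose grid and structure mask")
  if (!any(mask$values))
    stop(sprintf("structure '%s' has an empty mask", mask$label), call. = FALSE)
  d <- sort(dose$values[mask$values], decreasing = TRUE)
  vv <- voxel_volume_cc(dose)
  structure(list(dose = d, voxel_cc = vv, total_cc = vv * length(d)),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %d voxels, %.3f cm^3, dose [%.4g, %.4g] Gy\n",
              length(x$dose), x$total_cc, min(x$dose), max(x$dose)))
  invisible(x)
}

#' Voxel-wise accumulation of fractional doses
#'
#' Element-wise sum over fractions; linear and order-independent.
#'
#' @param fractions non-empty list of `fraction_dose` objects on a shared
#'   geometry.
#' @return `volume_grid` of accumulated dose in Gy.
#' @export
accumulate_dose <- function(fractions) {
  if (inherits(fractions, "fraction_dose")) fractions <- list(fractions)
  stopifnot(length(fractions) >= 1L,
            all(vapply(fractions, inherits, logical(1), "fraction_dose")))
  ref <- fractions[[1]]$dose
  acc <- array(0, dim = dim(ref$values))
  for (f in fractions) {
    assert_same_geometry(ref, f$dose, what = "fraction dose grids")
    acc <- acc + f$dose$values
  }
  volume_grid(acc, ref$spacing, ref$origin)
}

#' Biologically effective dose of one fraction
#'
#' Linear-quadratic biologically effective dose,
#' \deqn{BED = D\,(1 + d / (\alpha/\beta))}
#' with D the total dose and d the dose per fraction received by a voxel.
#' For a single fraction D = d, so per voxel BED = d (1 + d/ab). BED is
#' computed per fraction and then accumulated by summation
#' ([accumulate_bed()]); for varying fractional doses this differs from
#' applying the formula to the accumulated physical dose, and the per-
#' fraction order is the one used throughout.
#'
#' @param fdose a `fraction_dose`.
#' @param alpha_beta tissue alpha/beta ratio in Gy (> 0).
#' @return `volume_grid` of the fraction's BED in Gy.
#' @export
bed_fraction <- function(fdose, alpha_beta) {
  stopifnot(inherits(fdose, "fraction_dose"))
  if (!is.finite(alpha_beta) || alpha_beta <= 0)
    stop("alpha/beta must be a positive number of Gy", call. = FALSE)
  d <- fdose$dose$values
  volume_grid(d * (1 + d / alpha_beta), fdose$dose$spacing, fdose$dose$origin)
}

#' @rdname bed_fraction
#' @param fractions list of `fraction_dose` objects.
#' @export
accumulate_bed <- function(fractions, alpha_beta) {
  if (inherits(fractions, "fraction_dose")) fractions <- list(fractions)
  stopifnot(length(fractions) >= 1L)
  beds <- lapply(fractions, function(f)
    fraction_dose(bed_fraction(f, alpha_beta), f$fraction, f$basis))
  accumulate_dose(beds)
}

#' Read a DVH point off the cumulative dose-volume curve
#'
#' `Dv%` is the minimum dose received by the hottest v percent of the
#' structure volume; `Dxcc` the same on an absolute-volume axis; `Dmean`
#' the volume-weighted mean. With `method = "interpolate"` (default) the
#' dose is interpolated linearly between the step points of the descending
#' cumulative curve, each sorted voxel sitting at its cumulative-volume
#' midpoint; `method = "step"` reads the plain step function (the dose of
#' the voxel whose volume interval contains the requested volume). The two
#' agree to within one voxel's dose increment.
#'
#' An absolute-volume request larger than the structure is clamped to the
#' whole structure with a warning.
#'
#' @param dvh a `dvh` from [extract_structure_dose()].
#' @param spec a [dvh_point_spec()].
#' @param method `"interpolate"` or `"step"`.
#' @return dose in Gy.
#' @export
dvh_point <- function(dvh, spec, method = c("interpolate", "step")) {
  stopifnot(inherits(dvh, "dvh"), inherits(spec, "dvh_point_spec"))
  method <- match.arg(method)
  n <- length(dvh$dose)
  if (n == 0L) stop("empty DVH", call. = FALSE)
  if (spec$kind == "mean") return(mean(dvh$dose))
  # target cumulative volume in cm^3 from the hot end
  v_cc <- if (spec$kind == "percent") spec$value / 100 * dvh$total_cc
          else spec$value
  if (v_cc > dvh$total_cc) {
    warning(sprintf("requested volume %.3g cm^3 exceeds structure volume %.3g cm^3; clamped",
                    v_cc, dvh$total_cc), call. = FALSE)
    v_cc <- dvh$total_cc
  }
  if (method == "step") {
    k <- min(n, max(1L, ceiling(v_cc / dvh$voxel_cc - 1e-12)))
    return(dvh$dose[k])
  }
  # each sorted voxel k occupies cumulative volume ((k-1)*vv, k*vv]; its
  # dose is anchored at the interval midpoint (k - 0.5)*vv and doses are
  # interpolated linearly between midpoints, clamped to min/max beyond them
  mids <- (seq_len(n) - 0.5) * dvh$voxel_cc
  if (v_cc <= mids[1]) return(dvh$dose[1])
  if (v_cc >= mids[n]) return(dvh$dose[n])
  stats::approx(mids, dvh$dose, xout = v_cc, method = "linear", ties = "ordered")$y
}

#' Relative dose difference to the reference-based dose, in percent
#'
#' \code{100 (d_ref - d_eval) / d_ref}: positive when the reference (dCT)
#' based dose is higher than the evaluated (sCT) based dose.
#'
#' @param d_ref reference dose in Gy (> 0 for a defined result).
#' @param d_eval evaluated dose in Gy.
#' @return percent; `NA` where `d_ref` is 0 (not-applicable).
#' @export
relative_difference <- function(d_ref, d_eval) {
  out <- 100 * (d_ref - d_eval) / d_ref
  out[d_ref == 0] <- NA_real_
  out
}
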