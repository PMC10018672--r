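#' Specification of a synthetic evaluation case
#'
#' Defines a fully self-contained digital phantom: paired reference (dCT)
#' and evaluated (sCT) HU volumes with a body outline inside a larger
#' field of view, threshold-consistent tissue regions, mismatched air
#' pockets, a smooth synthetic-CT error field, named target/OAR structures
#' and multi-fraction Gaussian-beam dose grids. Every statistical knob is
#' recoverable downstream from the generated case and is recorded in the
#' ground-truth record.
#'
#' Defaults emulate an abdominal stereotactic case: 5 fractions of 10 Gy
#' (the modal prescription pattern of the emulated cohort), HU noise with
#' 60 HU standard deviation and a 20 HU smooth bias (global MAE near 50 HU,
#' mean error within roughly +/-15 HU), 30% bone dropout (small bony
#' structures missing from the synthetic CT), and an evaluated-basis dose
#' scale of 0.99 (about 1% dose differences). Internal air pockets carry
#' partial-volume intensities (-600 +/- 30 HU) so they stay inside the
#' -950 HU body masks while still triggering the -500 HU air-pocket rule.
#'
#' @param shape grid dimensions (slices, rows, columns).
#' @param spacing voxel spacing in mm.
#' @param anatomy `"abdominal"` (with lung regions at the cranial end) or
#'   `"pelvic"` (no lung).
#' @param tissue_hu named list of `c(mean, sd)` HU per tissue class
#'   (`soft`, `fat`, `bone`, `lung`, `pocket`) plus scalars `air` and
#'   `pocket_sd`.
#' @param bias_amplitude_hu amplitude of the smooth sCT error field (HU).
#' @param bias_type `"smooth"` (low-frequency sinusoidal field) or
#'   `"constant"` (uniform offset of `bias_amplitude_hu`).
#' @param noise_sd_hu white-noise SD added to the sCT inside the body (HU).
#' @param bone_dropout_prob probability that a small bone element (rib) is
#'   missing from the sCT.
#' @param edge_blur logical; blur the outermost slices of the sCT.
#' @param n_air_dct_only,n_air_sct_only,n_air_shared air-pocket counts.
#' @param air_radius_mm range of air-pocket radii in mm.
#' @param n_fractions number of treatment fractions (>= 1).
#' @param fraction_dose_gy prescribed dose per fraction (Gy), realized as
#'   the target median dose (D50%).
#' @param sct_dose_scale multiplicative scale between the sCT-basis and
#'   dCT-basis fraction doses (true dosimetric error).
#' @param dose_perturb_frac amplitude of a localized Gaussian perturbation
#'   added to the sCT-basis dose, as a fraction of the maximum dose (0
#'   disables it).
#' @param seed integer seed; identical specs and seeds give bit-identical
#'   cases.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(20, 48, 48),
                         spacing = c(3, 1.5, 1.5),
                         anatomy = c("abdominal", "pelvic"),
                         tissue_hu = list(soft = c(40, 20), fat = c(-60, 15),
                                          bone = c(400, 150), lung = c(-750, 50),
                                          pocket = c(-600, 30), air = -1000),
                         bias_amplitude_hu = 20,
                         bias_type = c("smooth", "constant"),
                         noise_sd_hu = 60,
                         bone_dropout_prob = 0.3,
                         edge_blur = TRUE,
                         n_air_dct_only = 2,
                         n_air_sct_only = 1,
                         n_air_shared = 1,
                         air_radius_mm = c(4, 8),
                         n_fractions = 5,
                         fraction_dose_gy = 10,
                         sct_dose_scale = 0.99,
                         dose_perturb_frac = 0.02,
                         seed = 1L) {
  anatomy <- match.arg(anatomy)
  bias_type <- match.arg(bias_type)
  shape <- as.integer(shape)
  if (length(shape) == 3L && shape[1] < 2L * 3L + 1L)
    stop("degenerate geometry: need more than 2 x trim + 1 slices", call. = FALSE)
  stopifnot(length(shape) == 3L, all(shape >= 4L),
            length(spacing) == 3L, all(spacing > 0),
            noise_sd_hu >= 0, bias_amplitude_hu >= 0,
            bone_dropout_prob >= 0, bone_dropout_prob <= 1,
            n_fractions >= 1, fraction_dose_gy > 0, sct_dose_scale > 0,
            dose_perturb_frac >= 0)
  structure(list(shape = shape, spacing = as.numeric(spacing), anatomy = anatomy,
                 tissue_hu = tissue_hu, bias_amplitude_hu = bias_amplitude_hu,
                 bias_type = bias_type, noise_sd_hu = noise_sd_hu,
                 bone_dropout_prob = bone_dropout_prob, edge_blur = edge_blur,
                 n_air_dct_only = as.integer(n_air_dct_only),
                 n_air_sct_only = as.integer(n_air_sct_only),
                 n_air_shared = as.integer(n_air_shared),
                 air_radius_mm = as.numeric(air_radius_mm),
                 n_fractions = as.integer(n_fractions),
                 fraction_dose_gy = as.numeric(fraction_dose_gy),
                 sct_dose_scale = as.numeric(sct_dose_scale),
                 dose_perturb_frac = as.numeric(dose_perturb_frac),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}


# voxel-centre coordinate arrays in mm
.coord_mm <- function(shape, spacing) {
  list(
    x = array(rep((seq_len(shape[1]) - 1) * spacing[1], times = shape[2] * shape[3]),
              dim = shape),
    y = array(rep(rep((seq_len(shape[2]) - 1) * spacing[2], each = shape[1]),
                  times = shape[3]), dim = shape),
    z = array(rep((seq_len(shape[3]) - 1) * spacing[3], each = shape[1] * shape[2]),
              dim = shape)
  )
}

.ellipsoid <- function(co, centre, radii) {
  ((co$x - centre[1]) / radii[1])^2 + ((co$y - centre[2]) / radii[2])^2 +
    ((co$z - centre[3]) / radii[3])^2 <= 1
}

#' Generate a synthetic evaluation case
#'
#' Builds the paired dCT/sCT volumes, structure set and per-fraction dose
#' grids described by a [phantom_spec()], together with a ground-truth
#' record holding the injected error parameters (bias field and its VOI
#' mean, noise SD, air-pocket voxel index sets, true tissue masks, dose
#' scale) against which every downstream metric can be checked.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_case` list: `dct`, `sct` (`volume_grid`s),
#'   `structures` (`structure_set` with body, PTV/GTV targets and OARs),
#'   `fractions_dct`, `fractions_sct` (lists of `fraction_dose`), `truth`
#'   (ground-truth record), and the `spec`.
#' @export
generate_case <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  sh <- spec$shape; sp <- spec$spacing
  co <- .coord_mm(sh, sp)
  ext <- (sh - 1) * sp               # physical extent, mm
  ctr <- ext / 2
  th <- spec$tissue_hu

  # body: ellipsoid filling ~80% of the in-plane FOV and ~95% cranio-caudally
  body <- .ellipsoid(co, ctr, c(0.50 * ext[1], 0.42 * ext[2], 0.42 * ext[3]))

  # tissue label map inside the body (priority: bone > lung > fat > soft)
  label <- array("soft", dim = sh)
  fat_ring <- body & !.ellipsoid(co, ctr, c(0.50 * ext[1], 0.34 * ext[2], 0.34 * ext[3]))
  label[fat_ring] <- "fat"
  # vertebral column: posterior cylinder along the slice axis
  vert <- ((co$y - 0.70 * ext[2])^2 + (co$z - ctr[3])^2) <= (0.07 * min(ext[2:3]))^2
  label[body & vert] <- "bone"
  # ribs: small lateral bone blobs, each individually droppable in the sCT
  n_ribs <- 6L
  rib_masks <- vector("list", n_ribs)
  for (r in seq_len(n_ribs)) {
    ang <- 2 * pi * (r - 0.5) / n_ribs
    cy <- ctr[2] + 0.38 * ext[2] * sin(ang) * 0.9
    cz <- ctr[3] + 0.38 * ext[3] * cos(ang) * 0.9
    cx <- ctr[1] + (r %% 3 - 1) * 0.2 * ext[1]
    rib <- .ellipsoid(co, c(cx, cy, cz), c(6, 4, 4)) & body
    rib_masks[[r]] <- which(rib)
    label[rib] <- "bone"
  }
  # lungs: cranial paired regions for abdominal anatomy only
  if (spec$anatomy == "abdominal") {
    for (s in c(-1, 1)) {
      lung <- .ellipsoid(co, c(0.08 * ext[1], ctr[2] - 0.12 * ext[2],
                               ctr[3] + s * 0.18 * ext[3]),
                         c(0.22 * ext[1], 0.16 * ext[2], 0.14 * ext[3])) & body
      label[lung] <- "lung"
    }
  }

  # reference CT: class means + class noise; background air outside body
  dct <- array(th$air, dim = sh)
  for (cl in c("soft", "fat", "bone", "lung")) {
    sel <- body & (label == cl)
    if (any(sel))
      dct[sel] <- stats::rnorm(sum(sel), th[[cl]][1], th[[cl]][2])
  }

  # air pockets: partial-volume gas intensities inside the soft-tissue core.
  # Pockets of the three categories are kept mutually disjoint so the
  # ground-truth mismatch sets are unambiguous; intensities are clamped to
  # stay strictly on the gas side of the -500 HU rule.
  used <- logical(prod(sh))
  # pocket centres stay clear of the trimmed/blurred end slices so the
  # whole pocket lies inside the evaluable VOI
  core <- .ellipsoid(co, ctr, c(0.20 * ext[1], 0.26 * ext[2], 0.26 * ext[3]))
  place_pockets <- function(n) {
    out <- vector("list", n)
    if (n == 0L) return(out)
    for (p in seq_len(n)) {
      r <- stats::runif(1, spec$air_radius_mm[1], spec$air_radius_mm[2])
      cand <- which(core & (label == "soft") & !used)
      cvox <- cand[sample.int(length(cand), 1)]
      ijk <- arrayInd(cvox, sh)
      cmm <- (ijk - 1) * sp
      idx <- which(.ellipsoid(co, cmm, c(r, r, r)) & body & !used)
      used[idx] <<- TRUE
      out[[p]] <- idx
    }
    out
  }
  pockets_dct <- place_pockets(spec$n_air_dct_only)
  pockets_sct <- place_pockets(spec$n_air_sct_only)
  pockets_shared <- place_pockets(spec$n_air_shared)
  pocket_hu <- function(idx)
    pmin(stats::rnorm(length(idx), th$pocket[1], th$pocket[2]), -520)
  for (idx in c(pockets_dct, pockets_shared)) dct[idx] <- pocket_hu(idx)

  # evaluated CT: dCT + smooth bias + white noise inside the body,
  # bone dropout, its own air pockets, cranio-caudal edge blur
  sct <- dct
  if (spec$bias_type == "constant") {
    bias <- array(spec$bias_amplitude_hu, dim = sh)
  } else {
    ph <- stats::runif(3, 0, 2 * pi)
    bias <- spec$bias_amplitude_hu *
      sin(2 * pi * co$x / max(ext[1], 1) + ph[1]) *
      cos(2 * pi * co$y / max(ext[2], 1) + ph[2]) *
      cos(2 * pi * co$z / max(ext[3], 1) + ph[3])
  }
  sct[body] <- sct[body] + bias[body]
  if (spec$noise_sd_hu > 0)
    sct[body] <- sct[body] + stats::rnorm(sum(body), 0, spec$noise_sd_hu)
  dropped <- logical(n_ribs)
  if (spec$bone_dropout_prob > 0) {
    dropped <- stats::runif(n_ribs) < spec$bone_dropout_prob
    for (r in which(dropped)) {
      idx <- rib_masks[[r]]
      sct[idx] <- stats::rnorm(length(idx), th$soft[1], th$soft[2])
    }
  }
  # pockets present in the sCT (its own + shared); dCT-only pockets appear
  # as soft tissue in the sCT
  for (idx in pockets_sct) sct[idx] <- pocket_hu(idx)
  for (idx in pockets_shared) sct[idx] <- pocket_hu(idx)
  for (idx in pockets_dct)
    sct[idx] <- pmax(stats::rnorm(length(idx), th$soft[1], th$soft[2]), -100)
  if (spec$edge_blur) {
    for (s in c(1L, 2L, sh[1] - 1L, sh[1])) {
      nb <- max(min(s + 1L, sh[1] - 1L), 2L)
      sct[s, , ] <- 0.5 * sct[s, , ] + 0.5 * sct[nb, , ]
    }
  }

  dct_grid <- volume_grid(dct, sp)
  sct_grid <- volume_grid(sct, sp)
  body_mask <- mask_like(body, dct_grid, label = "BODY")

  # structures: one PTV around a GTV in the soft-tissue core, one OAR
  # (spinal cord) inside the vertebral column
  gtv_ctr <- c(ctr[1], ctr[2] - 0.05 * ext[2], ctr[3] + 0.08 * ext[3])
  gtv <- .ellipsoid(co, gtv_ctr, c(9, 9, 9)) & body
  ptv <- .ellipsoid(co, gtv_ctr, c(14, 14, 14)) & body
  cord <- ((co$y - 0.70 * ext[2])^2 + (co$z - ctr[3])^2) <= (0.03 * min(ext[2:3]))^2
  cord <- cord & body
  structures <- structure_set(
    rt_structure("BODY", body_mask, role = "body",
                 dvh_points = list(dvh_point_spec("mean"))),
    rt_structure("PTV", mask_like(ptv, dct_grid, "PTV"), role = "target",
                 dvh_points = list(dvh_point_spec("percent", 2),
                                   dvh_point_spec("percent", 50),
                                   dvh_point_spec("percent", 98),
                                   dvh_point_spec("mean"))),
    rt_structure("GTV", mask_like(gtv, dct_grid, "GTV"), role = "target",
                 dvh_points = list(dvh_point_spec("percent", 50),
                                   dvh_point_spec("cc", 0.1))),
    rt_structure("CORD", mask_like(cord, dct_grid, "CORD"), role = "OAR",
                 dvh_points = list(dvh_point_spec("cc", 0.03),
                                   dvh_point_spec("mean")))
  )

  doses <- .generate_fraction_doses(spec, co, ext, gtv_ctr,
                                    mask_like(gtv, dct_grid, "GTV"))

  # VOI-mean of the injected bias (over body voxels; the evaluation VOI is
  # a subset but the constant-bias recovery contract is exact either way)
  truth <- list(
    bias_mean_body = mean(bias[body]),
    noise_sd = spec$noise_sd_hu,
    air_dct_only = sort(unique(unlist(pockets_dct))),
    air_sct_only = sort(unique(unlist(pockets_sct))),
    air_shared = sort(unique(unlist(pockets_shared))),
    tissue_labels = label,
    ribs_dropped = dropped,
    dose_scale = spec$sct_dose_scale,
    prescription_gy = spec$n_fractions * spec$fraction_dose_gy
  )

  structure(list(dct = dct_grid, sct = sct_grid, structures = structures,
                 fractions_dct = doses$dct, fractions_sct = doses$sct,
                 truth = truth, spec = spec),
            class = "phantom_case")
}

.generate_fraction_doses <- function(spec, co, ext, gtv_ctr, gtv_mask) {
  ctr <- ext / 2
  # three crossing anisotropic Gaussian beams through the target centre
  beam <- function(centre, sig) {
    exp(-(((co$x - centre[1]) / sig[1])^2 + ((co$y - centre[2]) / sig[2])^2 +
            ((co$z - centre[3]) / sig[3])^2) / 2)
  }
  base <- beam(gtv_ctr, c(18, 14, 14)) +
    0.6 * beam(gtv_ctr, c(10, 40, 12)) +
    0.6 * beam(gtv_ctr, c(10, 12, 40))
  # scale so that the per-fraction target D50% equals the fractional dose
  dvh0 <- extract_structure_dose(volume_grid(base, spec$spacing), gtv_mask)
  d50 <- dvh_point(dvh0, dvh_point_spec("percent", 50))
  base <- base * (spec$fraction_dose_gy / d50)

  perturb <- 0
  if (spec$dose_perturb_frac > 0) {
    pc <- gtv_ctr + c(0.12, 0.10, -0.10) * ext
    perturb <- spec$dose_perturb_frac * max(base) * beam(pc, c(8, 8, 8))
  }

  f_dct <- f_sct <- vector("list", spec$n_fractions)
  for (f in seq_len(spec$n_fractions)) {
    f_dct[[f]] <- fraction_dose(volume_grid(base, spec$spacing), f, "dCT")
    f_sct[[f]] <- fraction_dose(
      volume_grid(base * spec$sct_dose_scale + perturb, spec$spacing), f, "sCT")
  }
  list(dct = f_dct, sct = f_sct)
}

#' Generate fraction doses for a given basis scale
#'
#' Standalone access to the phantom's dose model: per-fraction Gaussian-beam
#' dose grids whose target D50% equals `fraction_dose_gy * basis_scale`.
#' Deterministic under the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @param basis_scale multiplicative scale on the prescription (1 for the
#'   reference basis).
#' @return list of `fraction_dose` objects.
#' @export
generate_dose <- function(spec, basis_scale = 1) {
  stopifnot(inherits(spec, "phantom_spec"), basis_scale > 0)
  set.seed(spec$seed)
  sh <- spec$shape; sp <- spec$spacing
  co <- .coord_mm(sh, sp)
  ext <- (sh - 1) * sp
  ctr <- ext / 2
  gtv_ctr <- c(ctr[1], ctr[2] - 0.05 * ext[2], ctr[3] + 0.08 * ext[3])
  body <- .ellipsoid(co, ctr, c(0.50 * ext[1], 0.42 * ext[2], 0.42 * ext[3]))
  gtv <- .ellipsoid(co, gtv_ctr, c(9, 9, 9)) & body
  spec2 <- spec
  spec2$fraction_dose_gy <- spec$fraction_dose_gy * basis_scale
  spec2$dose_perturb_frac <- 0
  .generate_fraction_doses(spec2, co, ext, gtv_ctr,
                           binary_mask(gtv, sp, label = "GTV"))$dct
}

#' Smooth synthetic displacement field for a phantom grid
#'
#' A small low-frequency sinusoidal displacement field on the geometry of
#' the given grid object, for exercising dose/structure warping with a
#' known ground truth. Amplitude 0 gives the identity field.
#'
#' @param template `volume_grid` or `binary_mask` supplying the geometry.
#' @param amplitude_mm peak displacement per axis in mm.
#' @param periods number of sinusoid periods across the volume extent.
#' @return A `displacement_field`.
#' @export
phantom_displacement_field <- function(template, amplitude_mm = 2,
                                       periods = 1) {
  sh <- dim(template$values)[1:3]
  sp <- template$spacing
  co <- .coord_mm(sh, sp)
  ext <- pmax((sh - 1) * sp, 1)
  vec <- array(0, dim = c(sh, 3))
  vec[, , , 1] <- amplitude_mm * sin(2 * pi * periods * co$y / ext[2])
  vec[, , , 2] <- amplitude_mm * sin(2 * pi * periods * co$z / ext[3])
  vec[, , , 3] <- amplitude_mm * sin(2 * pi * periods * co$x / ext[1])
  displacement_field(vec, sp, template$origin)
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s anatomy, %s grid, %d fractions x %g Gy, seed %d\n",
              x$spec$anatomy, paste(x$spec$shape, collapse = "x"),
              x$spec$n_fractions, x$spec$fraction_dose_gy, x$spec$seed))
  invisible(x)
}
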