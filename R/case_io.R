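#' Write / read an evaluation case directory
#'
#' A case directory holds the paired CT volumes, structure masks and
#' per-fraction dose grids as NIfTI files plus a JSON manifest with the
#' grid geometry, structure metadata (role, alpha/beta, DVH points) and the
#' ground-truth record. The voxel-level tissue label map in the in-memory
#' ground truth is not serialized (it is reconstructable by regenerating
#' the case from its spec and seed).
#'
#' Layout: `dct.nii.gz`, `sct.nii.gz`, `structures/<NAME>.nii.gz`,
#' `dose_<basis>_f<i>.nii.gz`, `manifest.json`.
#'
#' @param case a `phantom_case` (or a list with the same fields).
#' @param dir directory to create/fill.
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "structures"), showWarnings = FALSE)
  write_volume(case$dct, file.path(dir, "dct.nii.gz"))
  write_volume(case$sct, file.path(dir, "sct.nii.gz"))
  st_meta <- lapply(case$structures, function(s) {
    write_mask(s$mask, file.path(dir, "structures", paste0(s$name, ".nii.gz")))
    list(name = s$name, role = s$role, alpha_beta = s$alpha_beta,
         dvh_points = lapply(s$dvh_points, function(p)
           list(kind = p$kind, value = p$value)))
  })
  for (f in seq_along(case$fractions_dct))
    write_volume(case$fractions_dct[[f]]$dose,
                 file.path(dir, sprintf("dose_dct_f%02d.nii.gz", f)))
  for (f in seq_along(case$fractions_sct))
    write_volume(case$fractions_sct[[f]]$dose,
                 file.path(dir, sprintf("dose_sct_f%02d.nii.gz", f)))
  truth <- case$truth
  truth$tissue_labels <- NULL
  manifest <- list(
    spacing = case$dct$spacing,
    origin = case$dct$origin,
    n_fractions = length(case$fractions_dct),
    structures = unname(st_meta),
    truth = truth,
    spec = if (!is.null(case$spec)) unclass(case$spec)[setdiff(names(case$spec), "tissue_hu")]
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_case
#' @export
read_case <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  missing <- character(0)
  if (!file.exists(man_path)) missing <- c(missing, "manifest.json")
  for (f in c("dct.nii.gz", "sct.nii.gz"))
    if (!file.exists(file.path(dir, f))) missing <- c(missing, f)
  if (length(missing))
    stop("case directory '", dir, "' is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  origin <- as.numeric(man$origin)
  dct <- read_volume(file.path(dir, "dct.nii.gz"), origin = origin)
  sct <- read_volume(file.path(dir, "sct.nii.gz"), origin = origin)
  if (!same_geometry(dct, sct))
    stop("dCT and sCT in '", dir, "' do not share geometry", call. = FALSE)
  structures <- lapply(man$structures, function(sm) {
    p <- file.path(dir, "structures", paste0(sm$name, ".nii.gz"))
    if (!file.exists(p))
      stop("case directory '", dir, "' is missing structure file: ",
           basename(p), call. = FALSE)
    rt_structure(sm$name, read_mask(p, origin = origin, label = sm$name),
                 role = sm$role, alpha_beta = sm$alpha_beta,
                 dvh_points = lapply(sm$dvh_points, function(pp)
                   dvh_point_spec(pp$kind, pp$value)))
  })
  read_fr <- function(basis) {
    lapply(seq_len(man$n_fractions), function(f) {
      p <- file.path(dir, sprintf("dose_%s_f%02d.nii.gz", basis, f))
      if (!file.exists(p))
        stop("case directory '", dir, "' is missing dose file: ",
             basename(p), call. = FALSE)
      fraction_dose(read_volume(p, origin = origin), f,
                    if (basis == "dct") "dCT" else "sCT")
    })
  }
  truth <- man$truth
  for (nm in c("air_dct_only", "air_sct_only", "air_shared"))
    truth[[nm]] <- as.integer(unlist(truth[[nm]]))
  structure(list(dct = dct, sct = sct,
                 structures = structure_set(structures),
                 fractions_dct = read_fr("dct"), fractions_sct = read_fr("sct"),
                 truth = truth, spec = man$spec),
            class = "phantom_case")
}
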