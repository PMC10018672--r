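#' Evaluation configuration
#'
#' Bundles the tunable parameters of the full per-case evaluation:
#' preprocessing thresholds, tissue mask specifications, gamma criteria and
#' the DVH read-off method.
#'
#' @param body_threshold HU threshold for the two body masks (strict `>`).
#' @param trim_slices axial slices removed at each cranial/caudal end.
#' @param air_cut,tissue_cut,fill air-pocket overwrite parameters (HU).
#' @param tissue_specs named list of [tissue_mask_spec()]s.
#' @param min_lung_voxels minimum lung-mask size for a reported lung Dice.
#' @param gamma_criteria list of [gamma_criteria()] to evaluate.
#' @param dvh_method `"interpolate"` or `"step"`.
#' @param report_daily logical; also report per-fraction DVH differences.
#' @return An `evaluation_config` list.
#' @export
evaluation_config <- function(body_threshold = -950, trim_slices = 3,
                              air_cut = -500, tissue_cut = -200, fill = 0,
                              tissue_specs = tissue_thresholds(),
                              min_lung_voxels = 100,
                              gamma_criteria = list(
                                sctqa::gamma_criteria(1, 1),
                                sctqa::gamma_criteria(2, 2),
                                sctqa::gamma_criteria(3, 3)),
                              dvh_method = c("interpolate", "step"),
                              report_daily = TRUE) {
  dvh_method <- match.arg(dvh_method)
  structure(list(body_threshold = body_threshold, trim_slices = trim_slices,
                 air_cut = air_cut, tissue_cut = tissue_cut, fill = fill,
                 tissue_specs = tissue_specs, min_lung_voxels = min_lung_voxels,
                 gamma_criteria = gamma_criteria, dvh_method = dvh_method,
                 report_daily = report_daily),
            class = "evaluation_config")
}

.row <- function(case, category, metric, structure = NA_character_,
                 point = NA_character_, fraction = NA_integer_, value) {
  data.frame(case = case, category = category, metric = metric,
             structure = structure, point = point,
             fraction = as.integer(fraction), value = as.numeric(value),
             stringsAsFactors = FALSE)
}

#' Evaluate one case end to end
#'
#' Runs the complete evaluation on a case: VOI construction and air-pocket
#' overwrite; mean error, MAE and binned MAE; tissue Dice scores; physical
#' and biologically-effective dose accumulation with DVH-point differences
#' relative to the reference-based dose (accumulated and, optionally, per
#' fraction); and local gamma pass rates on the accumulated physical doses.
#' Deterministic: re-running on the same inputs is bit-identical.
#'
#' @param case a `phantom_case` or a case directory path (see
#'   [read_case()]).
#' @param config an [evaluation_config()].
#' @param case_id label used in the output rows (defaults to the directory
#'   name or "case").
#' @return A tidy data.frame with columns `case`, `category`, `metric`,
#'   `structure`, `point`, `fraction`, `value` (one row per case x metric).
#' @export
evaluate_case <- function(case, config = evaluation_config(),
                          case_id = NULL) {
  if (is.character(case)) {
    if (is.null(case_id)) case_id <- basename(normalizePath(case, mustWork = FALSE))
    case <- read_case(case)
  }
  if (is.null(case_id)) case_id <- "case"
  stopifnot(inherits(config, "evaluation_config"))

  body <- case$structures[["BODY"]]
  if (is.null(body)) stop("case has no BODY structure", call. = FALSE)
  voi <- build_voi(body$mask, case$dct, case$sct,
                   threshold = config$body_threshold,
                   trim_slices = config$trim_slices)
  dct_o <- overwrite_air_pockets(case$dct, case$sct, voi,
                                 air_cut = config$air_cut,
                                 tissue_cut = config$tissue_cut,
                                 fill = config$fill)

  rows <- list()
  rows[[length(rows) + 1L]] <-
    .row(case_id, "geometry", "ME", value = mean_error(dct_o, case$sct, voi))
  rows[[length(rows) + 1L]] <-
    .row(case_id, "geometry", "MAE", value = mean_absolute_error(dct_o, case$sct, voi))
  bm <- binned_mae(dct_o, case$sct, voi)
  occ <- bm[bm$n > 0, , drop = FALSE]
  if (nrow(occ))
    rows[[length(rows) + 1L]] <- .row(case_id, "geometry", "MAE_bin",
                                      point = sprintf("%g", occ$mid),
                                      value = occ$mae)
  dsc <- tissue_dice(dct_o, case$sct, body$mask,
                     specs = config$tissue_specs,
                     min_lung_voxels = config$min_lung_voxels)
  rows[[length(rows) + 1L]] <- .row(case_id, "geometry", "DSC",
                                    structure = names(dsc), value = dsc)

  # dosimetry: accumulated physical and BED doses per basis
  acc_phys <- list(dCT = accumulate_dose(case$fractions_dct),
                   sCT = accumulate_dose(case$fractions_sct))
  for (s in case$structures) {
    if (length(s$dvh_points) == 0L || !any(s$mask$values)) next
    acc_bed <- list(dCT = accumulate_bed(case$fractions_dct, s$alpha_beta),
                    sCT = accumulate_bed(case$fractions_sct, s$alpha_beta))
    for (p in s$dvh_points) {
      lab <- format(p)
      gp <- function(vol) dvh_point(extract_structure_dose(vol, s$mask), p,
                                    method = config$dvh_method)
      d_ref <- gp(acc_phys$dCT); d_ev <- gp(acc_phys$sCT)
      b_ref <- gp(acc_bed$dCT); b_ev <- gp(acc_bed$sCT)
      rows[[length(rows) + 1L]] <- .row(case_id, "dose", "phys_dct_gy", s$name, lab, value = d_ref)
      rows[[length(rows) + 1L]] <- .row(case_id, "dose", "phys_sct_gy", s$name, lab, value = d_ev)
      rows[[length(rows) + 1L]] <- .row(case_id, "dose", "phys_rel_pct", s$name, lab,
                                        value = relative_difference(d_ref, d_ev))
      rows[[length(rows) + 1L]] <- .row(case_id, "dose", "bed_dct_gy", s$name, lab, value = b_ref)
      rows[[length(rows) + 1L]] <- .row(case_id, "dose", "bed_sct_gy", s$name, lab, value = b_ev)
      rows[[length(rows) + 1L]] <- .row(case_id, "dose", "bed_rel_pct", s$name, lab,
                                        value = relative_difference(b_ref, b_ev))
      if (isTRUE(config$report_daily)) {
        for (f in seq_along(case$fractions_dct)) {
          fr <- gp(case$fractions_dct[[f]]$dose)
          fe <- gp(case$fractions_sct[[f]]$dose)
          rows[[length(rows) + 1L]] <-
            .row(case_id, "dose", "phys_rel_pct_daily", s$name, lab, f,
                 relative_difference(fr, fe))
        }
      }
    }
  }

  for (cr in config$gamma_criteria) {
    g <- gamma_map(acc_phys$dCT, acc_phys$sCT, cr)
    rows[[length(rows) + 1L]] <- .row(case_id, "gamma", "gamma_pass_pct",
                                      point = format(cr), value = pass_rate(g))
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary of per-case evaluation rows
#'
#' Mean, sample (n-1) standard deviation, minimum and maximum per metric
#' (grouped by category, metric, structure, point and fraction). With a
#' single case the SD is reported not-applicable (`NA`).
#'
#' @param rows data.frame as returned by [evaluate_case()] (rows of several
#'   cases concatenated with `rbind`).
#' @return data.frame with one row per metric group and columns `n`,
#'   `mean`, `sd`, `min`, `max`.
#' @export
summarize_cases <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0)
  key <- interaction(rows$category, rows$metric,
                     addNA(factor(rows$structure)), addNA(factor(rows$point)),
                     addNA(factor(rows$fraction)), drop = TRUE, lex.order = TRUE)
  parts <- split(rows, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    v <- p$value[!is.na(p$value)]
    data.frame(category = p$category[1], metric = p$metric[1],
               structure = p$structure[1], point = p$point[1],
               fraction = p$fraction[1], n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' DVH-difference table in the conventional reporting layout
#'
#' Reshapes a cohort summary into one row per structure and DVH point with
#' mean (1SD) and \[min, max\] of the physical and BED relative differences,
#' the layout in which synthetic-CT dosimetric comparisons are reported.
#'
#' @param summary data.frame from [summarize_cases()].
#' @return data.frame with columns `structure`, `point`, `phys_mean`,
#'   `phys_sd`, `phys_min`, `phys_max`, `bed_mean`, `bed_sd`, `bed_min`,
#'   `bed_max`.
#' @export
dvh_difference_table <- function(summary) {
  ph <- summary[summary$metric == "phys_rel_pct", ]
  be <- summary[summary$metric == "bed_rel_pct", ]
  key <- c("structure", "point")
  m <- merge(ph[, c(key, "mean", "sd", "min", "max")],
             be[, c(key, "mean", "sd", "min", "max")],
             by = key, suffixes = c("_phys", "_bed"))
  names(m) <- c("structure", "point",
                "phys_mean", "phys_sd", "phys_min", "phys_max",
                "bed_mean", "bed_sd", "bed_min", "bed_max")
  m[order(m$structure, m$point), ]
}

#' Write evaluation outputs as CSV and JSON
#'
#' @param rows per-case rows from [evaluate_case()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(rows, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rows, file.path(dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(rows, file.path(dir, "report.json"),
                       dataframe = "rows", digits = NA, na = "null")
  invisible(dir)
}
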