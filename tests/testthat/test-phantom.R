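test_that("identical specs and seeds reproduce a case bit for bit", {
  a <- generate_case(phantom_spec(seed = 42))
  b <- generate_case(phantom_spec(seed = 42))
  expect_identical(a$dct$values, b$dct$values)
  expect_identical(a$sct$values, b$sct$values)
  expect_identical(a$truth$air_dct_only, b$truth$air_dct_only)
  expect_identical(a$fractions_sct[[1]]$dose$values,
                   b$fractions_sct[[1]]$dose$values)
  c <- generate_case(phantom_spec(seed = 43))
  expect_false(identical(a$sct$values, c$sct$values))
})

test_that("a zero-error spec collapses every metric to its trivial value", {
  case <- generate_case(null_error_spec(seed = 2))
  expect_identical(case$sct$values, case$dct$values)
  body <- case$structures[["BODY"]]$mask
  voi <- build_voi(body, case$dct, case$sct)
  expect_equal(mean_error(case$dct, case$sct, voi), 0)
  expect_equal(mean_absolute_error(case$dct, case$sct, voi), 0)
  d <- tissue_dice(case$dct, case$sct, body)
  expect_equal(unname(d[c("bone", "fat", "lung")]), c(100, 100, 100))
  g <- gamma_map(accumulate_dose(case$fractions_dct),
                 accumulate_dose(case$fractions_sct), gamma_criteria(1, 1))
  expect_equal(pass_rate(g), 100)
})

test_that("the ground-truth record is recoverable from the generated case", {
  spec <- phantom_spec(seed = 8)
  case <- generate_case(spec)
  voi <- build_voi(case$structures[["BODY"]]$mask, case$dct, case$sct)
  out <- overwrite_air_pockets(case$dct, case$sct, voi)
  expect_setequal(attr(out, "changed"), case$truth$air_dct_only)
  # dose scale recovered through any DVH point
  acc_d <- accumulate_dose(case$fractions_dct)
  spec_np <- phantom_spec(seed = 8, dose_perturb_frac = 0)
  case_np <- generate_case(spec_np)
  gtv <- case_np$structures[["GTV"]]$mask
  d_ref <- dvh_point(extract_structure_dose(accumulate_dose(case_np$fractions_dct), gtv),
                     dvh_point_spec("percent", 50))
  d_ev <- dvh_point(extract_structure_dose(accumulate_dose(case_np$fractions_sct), gtv),
                    dvh_point_spec("percent", 50))
  expect_equal(relative_difference(d_ref, d_ev),
               100 * (1 - case_np$truth$dose_scale), tolerance = 1e-9)
})

test_that("prescription arithmetic holds: fractions x fractional dose at the target median", {
  spec <- phantom_spec(seed = 5, n_fractions = 5, fraction_dose_gy = 10)
  fr <- generate_dose(spec, basis_scale = 1)
  expect_length(fr, 5)
  case <- generate_case(spec)
  acc <- accumulate_dose(fr)
  d50 <- dvh_point(extract_structure_dose(acc, case$structures[["GTV"]]$mask),
                   dvh_point_spec("percent", 50))
  expect_equal(d50, 50, tolerance = 1e-6)
  # different fractionation pattern: 3 x 8 Gy
  spec2 <- phantom_spec(seed = 5, n_fractions = 3, fraction_dose_gy = 8)
  acc2 <- accumulate_dose(generate_dose(spec2, 1))
  d50_2 <- dvh_point(extract_structure_dose(acc2, case$structures[["GTV"]]$mask),
                     dvh_point_spec("percent", 50))
  expect_equal(d50_2, 24, tolerance = 1e-6)
})

test_that("abdominal phantoms carry lung tissue and pelvic ones do not", {
  abd <- generate_case(null_error_spec(seed = 6))
  pel <- generate_case(null_error_spec(seed = 6, anatomy = "pelvic"))
  specs <- tissue_thresholds()
  body_a <- abd$structures[["BODY"]]$mask
  body_p <- pel$structures[["BODY"]]$mask
  expect_gt(sum(tissue_mask(abd$dct, specs$lung, body_a)$values), 100)
  expect_lt(sum(tissue_mask(pel$dct, specs$lung, body_p)$values), 100)
  # pelvic lung Dice reported not-applicable
  expect_true(is.na(tissue_dice(pel$dct, pel$sct, body_p)[["lung"]]))
})

test_that("degenerate geometry is rejected at spec construction", {
  expect_error(phantom_spec(shape = c(6, 48, 48)), "trim")
})

test_that("cases survive a round trip through the case directory format", {
  case <- generate_case(phantom_spec(seed = 12))
  dir <- file.path(tempdir(), "sctqa-case-roundtrip")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_case(case, dir)
  back <- read_case(dir)
  expect_equal(back$dct$values, case$dct$values, tolerance = 1e-6)
  expect_identical(back$structures[["PTV"]]$mask$values,
                   case$structures[["PTV"]]$mask$values)
  expect_equal(back$structures[["CORD"]]$alpha_beta, 3)
  expect_identical(sort(back$truth$air_dct_only),
                   as.integer(sort(case$truth$air_dct_only)))
  expect_length(back$fractions_sct, case$spec$n_fractions)
  # missing files produce a hard, named error
  unlink(file.path(dir, "sct.nii.gz"))
  expect_error(read_case(dir), "sct.nii.gz")
})
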