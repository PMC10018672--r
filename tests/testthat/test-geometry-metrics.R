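test_that("ME and MAE follow their definitions and sign convention", {
  dim3 <- c(4, 4, 4)
  voi <- block_mask(dim3, 1, 1, 1:2)
  dct <- const_volume(0, dim3); sct <- const_volume(0, dim3)
  expect_identical(mean_error(dct, sct, voi), 0)
  expect_identical(mean_absolute_error(dct, sct, voi), 0)

  dct$values[1, 1, 1] <- 100
  expect_equal(mean_error(dct, sct, voi), 50)      # {100, 0} vs {0, 0}
  sct$values[1, 1, 2] <- 100
  expect_equal(mean_error(dct, sct, voi), 0)       # cancellation
  expect_equal(mean_absolute_error(dct, sct, voi), 100)

  empty <- binary_mask(array(FALSE, dim3))
  expect_error(mean_error(dct, sct, empty), "empty")
  expect_error(mean_absolute_error(dct, sct, empty), "empty")
})

test_that("MAE dominates |ME| over random volume pairs", {
  set.seed(123)
  for (r in 1:100) {
    dim3 <- c(5, 5, 5)
    dct <- volume_grid(array(rnorm(125, 0, 300), dim3))
    sct <- volume_grid(array(rnorm(125, 0, 300), dim3))
    voi <- binary_mask(array(runif(125) > 0.3, dim3))
    if (!any(voi$values)) next
    expect_gte(mean_absolute_error(dct, sct, voi),
               abs(mean_error(dct, sct, voi)))
  }
  # equality iff all signed errors share one sign
  dct <- const_volume(30, c(4, 4, 4)); sct <- const_volume(0, c(4, 4, 4))
  voi <- full_mask(c(4, 4, 4))
  expect_equal(mean_absolute_error(dct, sct, voi),
               abs(mean_error(dct, sct, voi)))
})

test_that("binned MAE partitions the VOI and matches the global MAE when weighted", {
  dim3 <- c(6, 6, 6)
  voi <- full_mask(dim3)
  dct <- const_volume(10, dim3)
  sct <- const_volume(60, dim3)
  bm <- binned_mae(dct, sct, voi)
  occ <- bm[bm$n > 0, ]
  expect_identical(nrow(occ), 1L)
  expect_equal(occ$lower, 0); expect_equal(occ$upper, 20)
  expect_equal(occ$mae, 50)
  expect_identical(occ$n, as.integer(prod(dim3)))

  # count-weighted mean over occupied bins == global MAE when all in range
  set.seed(5)
  dct <- volume_grid(array(runif(216, -999, 1499), dim3))
  sct <- volume_grid(array(dct$values + rnorm(216, 0, 80), dim3))
  bm <- binned_mae(dct, sct, voi)
  expect_identical(attr(bm, "n_out_of_range"), 0L)
  expect_identical(sum(bm$n), as.integer(sum(voi$values)))
  occ <- bm[bm$n > 0, ]
  expect_lt(abs(sum(occ$mae * occ$n) / sum(occ$n) -
                  mean_absolute_error(dct, sct, voi)), 1e-9)

  # half-open bins: a reference voxel exactly at 1500 HU is out of range
  dct$values[1, 1, 1] <- 1500
  bm2 <- binned_mae(dct, sct, voi)
  expect_identical(attr(bm2, "n_out_of_range"), 1L)
})

test_that("tissue masks use strict threshold inequalities within the body", {
  specs <- tissue_thresholds()
  dim3 <- c(2, 2, 2)
  body <- full_mask(dim3)
  v <- volume_grid(array(c(150, 151, -100, -60, -20, -700, -701, 0), dim3))
  bone <- tissue_mask(v, specs$bone, body)
  fat <- tissue_mask(v, specs$fat, body)
  lung <- tissue_mask(v, specs$lung, body)
  expect_identical(as.vector(bone$values)[1:2], c(FALSE, TRUE))
  expect_identical(as.vector(fat$values)[3:5], c(FALSE, TRUE, FALSE))
  expect_identical(as.vector(lung$values)[6:7], c(FALSE, TRUE))
  # body outline restricts the mask
  body$values[2, 1, 1] <- FALSE   # the voxel holding 151
  expect_false(any(tissue_mask(v, specs$bone, body)$values))
})

test_that("Dice matches its closed form and handles empty masks as specified", {
  dim3 <- c(6, 6, 6)
  a <- block_mask(dim3, 1:2, 1:2, 1:2)          # 8 voxels
  expect_equal(dice(a, a), 100)
  b <- block_mask(dim3, 4:5, 4:5, 4:5)          # disjoint
  expect_equal(dice(a, b), 0)
  # |a| = |b| = 8 with 4 shared voxels -> 50%
  c <- block_mask(dim3, 1:2, 1:2, 2:3)
  expect_equal(sum(a$values & c$values), 4)
  expect_equal(dice(a, c), 50)
  expect_equal(dice(a, c), dice(c, a))
  empty <- binary_mask(array(FALSE, dim3))
  expect_equal(dice(a, empty), 0)
  expect_true(is.na(dice(empty, empty)))
})

test_that("lung Dice is suppressed below the minimum voxel count", {
  dim3 <- c(8, 8, 8)
  body <- full_mask(dim3)
  dct <- const_volume(40, dim3)
  sct <- const_volume(40, dim3)
  dct$values[1:2, 1:2, 1:2] <- -750             # 8 lung voxels only
  sct$values[1:2, 1:2, 1:2] <- -750
  d <- tissue_dice(dct, sct, body, min_lung_voxels = 100)
  expect_true(is.na(d[["lung"]]))
  d2 <- tissue_dice(dct, sct, body, min_lung_voxels = 5)
  expect_equal(d2[["lung"]], 100)
})

test_that("a constant sCT offset is recovered exactly; noise SD within 3 SE", {
  spec <- null_error_spec(seed = 3, bias_amplitude_hu = 30,
                          bias_type = "constant")
  case <- generate_case(spec)
  voi <- build_voi(case$structures[["BODY"]]$mask, case$dct, case$sct)
  expect_equal(mean_error(case$dct, case$sct, voi), -30)
  expect_equal(mean_absolute_error(case$dct, case$sct, voi), 30)

  spec_n <- null_error_spec(seed = 4, noise_sd_hu = 60)
  case_n <- generate_case(spec_n)
  voi_n <- build_voi(case_n$structures[["BODY"]]$mask, case_n$dct, case_n$sct)
  resid <- case_n$dct$values[voi_n$values] - case_n$sct$values[voi_n$values]
  n <- length(resid)
  se <- 60 / sqrt(2 * n)
  expect_lt(abs(sd(resid) - 60), 3 * se)
  expect_lt(abs(mean_error(case_n$dct, case_n$sct, voi_n)), 3 * 60 / sqrt(n))
})
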