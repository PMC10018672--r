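test_that("body threshold uses a strict inequality", {
  v <- volume_grid(array(c(-960, -950, -940, 0, -980, 100, -950, -949),
                         dim = c(2, 2, 2)))
  m <- threshold_body_mask(v, -950)
  expect_identical(as.vector(m$values),
                   c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_true(all(threshold_body_mask(const_volume(0))$values))
  expect_false(any(threshold_body_mask(const_volume(-980))$values))
})

test_that("VOI trims cranial/caudal slices and intersects all three masks", {
  dim3 <- c(10, 6, 6)
  dct <- const_volume(0, dim3)
  sct <- const_volume(0, dim3)
  body <- full_mask(dim3)
  voi <- build_voi(body, dct, sct, trim_slices = 3)
  kept <- apply(voi$values, 1, any)
  expect_identical(kept, c(rep(FALSE, 3), rep(TRUE, 4), rep(FALSE, 3)))
  expect_true(all(voi$values[4:7, , ]))

  # intersection annihilator
  empty_body <- binary_mask(array(FALSE, dim3))
  expect_false(any(build_voi(empty_body, dct, sct)$values))

  # a voxel below threshold in either image is excluded
  sct2 <- sct
  sct2$values[5, 3, 3] <- -960
  voi2 <- build_voi(body, dct, sct2)
  expect_false(voi2$values[5, 3, 3])
  expect_true(voi2$values[5, 3, 4])
})

test_that("VOI construction is idempotent and order-invariant", {
  set.seed(42)
  dim3 <- c(12, 8, 8)
  dct <- volume_grid(array(rnorm(prod(dim3), -500, 400), dim3))
  sct <- volume_grid(array(rnorm(prod(dim3), -500, 400), dim3))
  body <- binary_mask(array(runif(prod(dim3)) > 0.2, dim3))
  voi1 <- build_voi(body, dct, sct)
  # re-application with the VOI as the body structure changes nothing
  voi2 <- build_voi(voi1, dct, sct)
  expect_identical(voi1$values, voi2$values)
  # swapping the two thresholded volumes changes nothing
  voi3 <- build_voi(body, sct, dct)
  expect_identical(voi1$values, voi3$values)
})

test_that("VOI requires more than 2 x trim slices", {
  dim3 <- c(6, 4, 4)
  expect_error(build_voi(full_mask(dim3), const_volume(0, dim3),
                         const_volume(0, dim3), trim_slices = 3),
               "trim_slices")
})

test_that("air-pocket overwrite follows the two-threshold rule exactly", {
  dim3 <- c(8, 4, 4)
  dct <- const_volume(0, dim3)
  sct <- const_volume(0, dim3)
  voi <- full_mask(dim3)
  dct$values[4, 1, 1] <- -600; sct$values[4, 1, 1] <- -100  # pocket: overwrite
  dct$values[4, 2, 1] <- -600; sct$values[4, 2, 1] <- -600  # air in both: keep
  dct$values[4, 3, 1] <- -400; sct$values[4, 3, 1] <- -100  # not air enough: keep
  dct$values[4, 4, 1] <- -500; sct$values[4, 4, 1] <- 0     # boundary: keep (strict <)
  dct$values[5, 1, 1] <- -600; sct$values[5, 1, 1] <- -200  # boundary: keep (strict >)
  out <- overwrite_air_pockets(dct, sct, voi)
  expect_identical(out$values[4, 1, 1], 0)
  expect_identical(out$values[4, 2, 1], -600)
  expect_identical(out$values[4, 3, 1], -400)
  expect_identical(out$values[4, 4, 1], -500)
  expect_identical(out$values[5, 1, 1], -600)
  expect_identical(attr(out, "changed"),
                   which(dct$values < -500 & sct$values > -200))
  # inputs not mutated
  expect_identical(dct$values[4, 1, 1], -600)
})

test_that("overwrite never touches voxels outside the VOI and matches the rule set", {
  set.seed(7)
  dim3 <- c(10, 10, 10)
  dct <- volume_grid(array(runif(1000, -1000, 200), dim3))
  sct <- volume_grid(array(runif(1000, -1000, 200), dim3))
  voi <- binary_mask(array(runif(1000) > 0.5, dim3))
  out <- overwrite_air_pockets(dct, sct, voi)
  expected <- which(voi$values & dct$values < -500 & sct$values > -200)
  expect_identical(attr(out, "changed"), expected)
  expect_identical(out$values[-expected], dct$values[-expected])
  expect_true(all(out$values[expected] == 0))
  # triggered voxels are never lowered below the fill value
  expect_true(all(out$values[expected] >= 0))
})

test_that("overwrite cannot increase the VOI MAE when air mismatch is the only error", {
  spec <- null_error_spec(seed = 11, n_air_dct_only = 2)
  case <- generate_case(spec)
  voi <- build_voi(case$structures[["BODY"]]$mask, case$dct, case$sct)
  before <- mean_absolute_error(case$dct, case$sct, voi)
  after <- mean_absolute_error(overwrite_air_pockets(case$dct, case$sct, voi),
                               case$sct, voi)
  expect_lte(after, before)
})
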