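test_that("structure dose extraction carries voxel volume and descending order", {
  dim3 <- c(10, 10, 10)
  dose <- const_volume(10, dim3, spacing = c(2, 2, 2))
  mask <- full_mask(dim3, spacing = c(2, 2, 2))
  dvh <- extract_structure_dose(fraction_dose(dose), mask)
  expect_length(dvh$dose, 1000)
  expect_equal(dvh$total_cc, 8)
  expect_equal(dvh$voxel_cc, 0.008)

  d3 <- const_volume(0, c(3, 1, 1))
  d3$values[] <- c(1, 2, 3)
  dvh3 <- extract_structure_dose(d3, full_mask(c(3, 1, 1)))
  expect_identical(dvh3$dose, c(3, 2, 1))

  single <- block_mask(dim3, 1, 1, 1, spacing = c(2, 2, 2))
  expect_length(extract_structure_dose(dose, single)$dose, 1)

  empty <- binary_mask(array(FALSE, dim3), spacing = c(2, 2, 2),
                       label = "DUODENUM")
  expect_error(extract_structure_dose(dose, empty), "DUODENUM")
})

test_that("dose accumulation is an element-wise linear sum", {
  dim3 <- c(6, 6, 6)
  f <- lapply(1:5, function(i) fraction_dose(const_volume(10, dim3), i))
  acc <- accumulate_dose(f)
  expect_true(all(acc$values == 50))
  expect_identical(accumulate_dose(f[1])$values, f[[1]]$dose$values)

  v1 <- const_volume(2, dim3); v2 <- const_volume(3, dim3)
  acc2 <- accumulate_dose(list(fraction_dose(v1, 1), fraction_dose(v2, 2)))
  expect_true(all(acc2$values == 5))
  # linearity over a partition of the fraction list
  set.seed(9)
  fr <- lapply(1:4, function(i)
    fraction_dose(volume_grid(array(runif(216, 0, 5), dim3)), i))
  expect_equal(accumulate_dose(fr)$values,
               accumulate_dose(fr[1:2])$values + accumulate_dose(fr[3:4])$values)
  bad <- fraction_dose(const_volume(1, c(5, 5, 5)), 1)
  expect_error(accumulate_dose(list(fr[[1]], bad)), "geometry")
})

test_that("BED closed forms hold per fraction and accumulate linearly", {
  dim3 <- c(4, 4, 4)
  f10 <- fraction_dose(const_volume(10, dim3))
  expect_true(all(bed_fraction(f10, 10)$values == 20))
  acc <- accumulate_bed(rep(list(f10), 5), 10)
  expect_true(all(acc$values == 100))
  f3 <- fraction_dose(const_volume(3, dim3))
  expect_true(all(bed_fraction(f3, 3)$values == 6))
  # alpha/beta -> infinity recovers the physical dose
  expect_true(all(abs(bed_fraction(f10, 1e12)$values - 10) < 1e-9))
  expect_error(bed_fraction(f10, 0), "positive")
  expect_error(bed_fraction(f10, -3), "positive")
})

test_that("BED dominates physical dose and its accumulation is order-independent", {
  set.seed(21)
  dim3 <- c(5, 5, 5)
  fr <- lapply(1:4, function(i)
    fraction_dose(volume_grid(array(runif(125, 0, 12), dim3)), i))
  bed <- accumulate_bed(fr, 3)
  phys <- accumulate_dose(fr)
  expect_true(all(bed$values >= phys$values))
  expect_equal(accumulate_bed(rev(fr), 3)$values, bed$values)
  # infinite-ab limit across an accumulated course
  expect_true(all(abs(accumulate_bed(fr, 1e12)$values - phys$values) < 1e-9))
})

test_that("per-fraction BED differs from BED of the accumulated dose when fractions vary", {
  dim3 <- c(3, 3, 3)
  fr <- list(fraction_dose(const_volume(2, dim3), 1),
             fraction_dose(const_volume(8, dim3), 2))
  per_fraction <- accumulate_bed(fr, 10)          # 2(1+.2) + 8(1+.8) = 16.8
  expect_true(all(abs(per_fraction$values - 16.8) < 1e-12))
  acc <- accumulate_dose(fr)                       # 10 Gy
  from_total <- acc$values * (1 + acc$values / 10) # 20 Gy: not the same
  expect_gt(min(abs(per_fraction$values - from_total)), 1)
})

test_that("DVH points follow the hottest-volume convention with interpolation", {
  dim3 <- c(4, 5, 5)
  uniform <- extract_structure_dose(const_volume(12, dim3), full_mask(dim3))
  for (v in c(2, 50, 98, 100))
    expect_equal(dvh_point(uniform, dvh_point_spec("percent", v)), 12)
  expect_equal(dvh_point(uniform, dvh_point_spec("mean")), 12)

  ramp <- const_volume(0, c(100, 1, 1))
  ramp$values[] <- 1:100
  dvh <- extract_structure_dose(ramp, full_mask(c(100, 1, 1)))
  expect_equal(dvh_point(dvh, dvh_point_spec("percent", 50)), 50.5)
  expect_equal(dvh_point(dvh, dvh_point_spec("percent", 100)), 1)  # minimum dose
  mean_d <- dvh_point(dvh, dvh_point_spec("mean"))
  expect_gte(mean_d, 1); expect_lte(mean_d, 100)

  # monotone non-increasing in v
  vs <- c(1, 2, 5, 25, 50, 75, 98, 100)
  ds <- vapply(vs, function(v) dvh_point(dvh, dvh_point_spec("percent", v)),
               numeric(1))
  expect_true(all(diff(ds) <= 0))
})

test_that("interpolated DVH points agree with the step-function oracle within one voxel increment", {
  set.seed(31)
  doses <- sort(runif(100, 0, 60), decreasing = TRUE)
  vol <- const_volume(0, c(100, 1, 1), spacing = c(2, 2, 2))
  vol$values[] <- doses[100:1]
  dvh <- extract_structure_dose(vol, full_mask(c(100, 1, 1), spacing = c(2, 2, 2)))
  max_step <- max(abs(diff(sort(doses))))
  for (v in c(2, 10, 33.3, 50, 77, 98)) {
    interp <- dvh_point(dvh, dvh_point_spec("percent", v))
    oracle <- dvh_step_oracle(doses, dvh$voxel_cc, v / 100 * dvh$total_cc)
    expect_lt(abs(interp - oracle), max_step + 1e-12)
    # the package's own step method must match the oracle exactly
    expect_equal(dvh_point(dvh, dvh_point_spec("percent", v), method = "step"),
                 oracle)
  }
})

test_that("absolute-volume points approach the maximum and clamp when oversized", {
  dim3 <- c(5, 5, 5)
  vol <- const_volume(10, dim3, spacing = c(2, 2, 2))   # 0.008 cc voxels
  vol$values[3, 3, 3] <- 40
  dvh <- extract_structure_dose(vol, full_mask(dim3, spacing = c(2, 2, 2)))
  d003 <- dvh_point(dvh, dvh_point_spec("cc", 0.03))
  expect_gte(d003, 10)
  expect_lte(d003, 40)
  # a request in the hottest half-voxel reads the maximum exactly
  expect_equal(dvh_point(dvh, dvh_point_spec("cc", 0.003)), 40)
  # between the first two cumulative-volume midpoints the read-off is the
  # closed-form linear blend of the two hottest voxel doses
  expect_equal(dvh_point(dvh, dvh_point_spec("cc", 0.01)),
               40 + (10 - 40) * (0.01 - 0.004) / 0.008)
  expect_warning(big <- dvh_point(dvh, dvh_point_spec("cc", 99)), "clamped")
  expect_equal(big, 10)  # minimum dose
})

test_that("relative difference is signed towards the reference", {
  expect_equal(relative_difference(50, 50), 0)
  expect_equal(relative_difference(50, 49), 2)
  expect_equal(relative_difference(49, 50), -100 / 49)
  expect_true(is.na(relative_difference(0, 5)))
})

test_that("accumulation commutes with structure masking", {
  set.seed(13)
  dim3 <- c(6, 6, 6)
  fr <- lapply(1:3, function(i)
    fraction_dose(volume_grid(array(runif(216, 0, 4), dim3)), i))
  mask <- binary_mask(array(runif(216) > 0.5, dim3))
  acc_then_mask <- accumulate_dose(fr)$values[mask$values]
  mask_then_acc <- Reduce(`+`, lapply(fr, function(f) f$dose$values[mask$values]))
  expect_equal(acc_then_mask, mask_then_acc)
})
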