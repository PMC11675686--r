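test_that("phantom_spec validates ranges and intensity ordering", {
  expect_s3_class(test_spec(), "phantom_spec")
  expect_error(phantom_spec(tl_radius_mm = c(14, 8)), "low must be <= high")
  expect_error(phantom_spec(tl_radius_mm = c(-1, 8)), "positive|nonnegative")
  expect_error(phantom_spec(thrombus_fraction = c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(phantom_spec(intensity_lumen = c(0.3, 0.4),
                            intensity_thrombus = c(0.4, 0.5)),
               "intensity_lumen")
  expect_error(phantom_spec(noise_sd = -0.1), "nonnegative")
  expect_error(phantom_spec(voxel_spacing_mm = c(0.7, 0.5, 1)), "isotropic")
})

test_that("NO_FL slices have no thrombus and no false lumen", {
  set.seed(1)
  s <- make_phantom_slice(test_spec(), "NO_FL")
  expect_equal(sum(s$thrombus_mask), 0)
  expect_equal(sum(s$fl_mask), 0)
  expect_gt(sum(s$lumen_mask), 0)
})

test_that("dissected slices have a septum stripe separating TL and FL", {
  set.seed(2)
  for (label in c("PATENT_FL", "PARTIAL_FL", "THROMBOSED_FL")) {
    s <- make_phantom_slice(test_spec(), label)
    fl_all <- s$fl_mask
    tl <- s$lumen_mask & !fl_all
    expect_gt(sum(tl), 0)
    expect_gt(sum(fl_all), 0)
    # no TL pixel is 8-adjacent to an FL pixel: the septum stripe intervenes
    idx <- which(fl_all, arr.ind = TRUE)
    for (dr in -1:1) for (dc in -1:1) {
      shifted <- cbind(pmin(pmax(idx[, 1] + dr, 1), 64),
                       pmin(pmax(idx[, 2] + dc, 1), 64))
      expect_false(any(tl[shifted]))
    }
  }
})

test_that("thrombus pixel fraction tracks the analytic sector fraction", {
  set.seed(3)
  spec_hi <- test_spec(thrombus_fraction = c(0.9, 1.0))
  for (i in 1:10) {
    s <- make_phantom_slice(spec_hi, "THROMBOSED_FL")
    ratio <- sum(s$thrombus_mask) / sum(s$fl_mask)
    # one-pixel discretization tolerance on the requested sector fraction
    expect_lt(abs(ratio - s$thrombus_fraction), 1 / sum(s$fl_mask) + 1e-12)
    expect_gte(ratio, 0.9 - 0.01)
    expect_lte(ratio, 1.0)
  }
})

test_that("partial slices are strictly partially thrombosed", {
  coh <- make_phantom_cohort(test_spec(), c(PARTIAL_FL = 3), seed = 4)
  for (s in coh$slices) {
    frac <- sum(s$thrombus_mask) / sum(s$fl_mask)
    expect_gt(frac, 0)
    expect_lt(frac, test_spec()$thrombus_fraction[2])
  }
})

test_that("lumen is hyperintense relative to thrombus on every slice", {
  set.seed(5)
  for (i in 1:20) {
    label <- sample(c("PARTIAL_FL", "THROMBOSED_FL"), 1)
    s <- make_phantom_slice(test_spec(), label)
    expect_gt(mean(s$pixels[s$lumen_mask]), mean(s$pixels[s$thrombus_mask]))
    validate_cross_section(s)
  }
})

test_that("cohorts have the requested composition and are seed-deterministic", {
  counts <- c(NO_FL = 5, THROMBOSED_FL = 5)
  a <- make_phantom_cohort(test_spec(), counts, seed = 9)
  b <- make_phantom_cohort(test_spec(), counts, seed = 9)
  expect_length(a$slices, 10)
  expect_equal(table(a$labels$label)[["NO_FL"]], 5)
  expect_equal(table(a$labels$label)[["THROMBOSED_FL"]], 5)
  expect_identical(a, b)  # bit-identical reproduction from the seed
  c <- make_phantom_cohort(test_spec(), counts, seed = 10)
  expect_false(identical(a$slices[[1]]$pixels, c$slices[[1]]$pixels))
  expect_error(make_phantom_cohort(test_spec(), c(NO_FL = 0), seed = 1),
               "empty cohort")
  expect_error(make_phantom_cohort(test_spec(), c(FOO = 3), seed = 1),
               "labels among")
})

test_that("straight volumes have an axis-aligned centerline inside the lumen", {
  spec0 <- test_spec(curvature_amplitude_mm = 0)
  vp <- make_phantom_volume(spec0, n_slices = 20, seed = 3)
  # zero curvature: x and y of the truth centerline are constant
  expect_equal(diff(range(vp$centerline_truth[, 1])), 0)
  expect_equal(diff(range(vp$centerline_truth[, 2])), 0)
  # every centerline point maps to a lumen voxel
  vox <- sweep(vp$centerline_truth, 2, vp$spacing_mm, "/") + 1
  for (i in seq_len(nrow(vox))) {
    expect_true(vp$lumen_mask[round(vox[i, 1]), round(vox[i, 2]),
                              round(vox[i, 3])])
  }
  expect_true(all(!(vp$lumen_mask & vp$thrombus_mask)))
})

test_that("curved volumes keep the centerline inside the lumen", {
  vp <- make_phantom_volume(test_spec(), n_slices = 30, seed = 8,
                            labels = "THROMBOSED_FL")
  vox <- sweep(vp$centerline_truth, 2, vp$spacing_mm, "/") + 1
  for (i in seq_len(nrow(vox))) {
    expect_true(vp$lumen_mask[round(vox[i, 1]), round(vox[i, 2]),
                              round(vox[i, 3])])
  }
})

test_that("per-slice lumen area of a constant-radius tube matches pi r^2", {
  # a degenerate radius range pins the caliber profile to a constant
  spec0 <- test_spec(curvature_amplitude_mm = 0, noise_sd = 0,
                     tl_radius_mm = c(10, 10))
  vp <- make_phantom_volume(spec0, n_slices = 12, seed = 6)
  r <- vp$geometry$r_tl
  expect_equal(diff(range(r)), 0)
  px_area <- prod(vp$spacing_mm[1:2])
  for (k in 2:11) {  # away from the end caps
    area <- sum(vp$lumen_mask[, , k]) * px_area
    expect_lt(abs(area - pi * r[k]^2) / (pi * r[k]^2), 0.05)
  }
  # a non-degenerate range still matches the analytic area slice by slice
  vp2 <- make_phantom_volume(test_spec(curvature_amplitude_mm = 0,
                                       noise_sd = 0), 12, seed = 6)
  r2 <- vp2$geometry$r_tl
  for (k in 2:11) {
    area <- sum(vp2$lumen_mask[, , k]) * px_area
    expect_lt(abs(area - pi * r2[k]^2) / (pi * r2[k]^2), 0.05)
  }
})

test_that("a tube that exits the grid fails naming the offending slice", {
  expect_error(
    make_phantom_volume(test_spec(curvature_amplitude_mm = 30),
                        n_slices = 40, seed = 2, dim_xy = 48L),
    "exits volume bounds at slice [0-9]+")
})

test_that("volume phantoms round-trip through NIfTI and text sidecars", {
  vp <- make_phantom_volume(test_spec(), n_slices = 8, seed = 12,
                            labels = c(rep("NO_FL", 4),
                                       rep("THROMBOSED_FL", 4)),
                            subject_id = "RT")
  dir <- withr::local_tempdir()
  write_volume_phantom(vp, dir)
  back <- read_volume_phantom(dir, "RT")
  expect_equal(back$spacing_mm, vp$spacing_mm, tolerance = 1e-6)
  expect_equal(dim(back$intensities), dim(vp$intensities))
  expect_equal(back$intensities, vp$intensities, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$lumen_mask, vp$lumen_mask)
  expect_equal(back$centerline_truth, vp$centerline_truth, tolerance = 1e-9)
  expect_identical(back$labels, vp$labels)
})
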