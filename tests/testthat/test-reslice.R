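test_that("resampling a straight segment gives floor(L/step) + 1 points", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0))
  cl <- resample_centerline(pts, 1)
  expect_equal(nrow(cl$points), 11)
  expect_equal(cl$points[, 1], 0:10)
  expect_equal(cl$arclength, 0:10)
  # endpoints preserved even when the last segment is shorter
  cl2 <- resample_centerline(rbind(c(0, 0, 0), c(10.5, 0, 0)), 1)
  expect_equal(nrow(cl2$points), 12)
  expect_equal(cl2$points[12, 1], 10.5)
})

test_that("degenerate centerlines are rejected", {
  expect_error(resample_centerline(rbind(c(1, 2, 3), c(1, 2, 3)), 1),
               "degenerate centerline")
  expect_error(resample_centerline(matrix(c(1, 2, 3), 1, 3), 1),
               "degenerate centerline")
})

test_that("resampled points sit on the input path at uniform arc spacing", {
  set.seed(21)
  dist_to_segment <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }
  for (rep in 1:5) {
    pts <- apply(matrix(rnorm(12, sd = 20), 4, 3), 2, cumsum)
    cl <- resample_centerline(pts, 0.8)
    # uniform arc-length spacing, final segment possibly shorter
    gaps <- diff(cl$arclength)
    if (length(gaps) > 1)
      expect_equal(gaps[-length(gaps)], rep(0.8, length(gaps) - 1),
                   tolerance = 1e-9)
    expect_lte(gaps[length(gaps)], 0.8 + 1e-9)
    # every output point lies on the piecewise-linear input path
    for (i in seq_len(nrow(cl$points))) {
      d <- min(vapply(seq_len(nrow(pts) - 1), function(j)
        dist_to_segment(cl$points[i, ], pts[j, ], pts[j + 1, ]), 1.0))
      expect_lt(d, 1e-9)
    }
    # endpoints preserved
    expect_equal(cl$points[1, ], pts[1, ], tolerance = 1e-12)
    expect_equal(cl$points[nrow(cl$points), ], pts[4, ], tolerance = 1e-9)
  }
})

test_that("resampling is idempotent when vertices sit on step multiples", {
  # legs of integer length: every sample lands on the polyline vertices, so a
  # second resample at the same step reproduces the points exactly
  pts <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 4, 0), c(5, 4, 3))
  cl1 <- resample_centerline(pts, 1)
  cl2 <- resample_centerline(cl1$points, 1)
  expect_lt(max(abs(cl1$points - cl2$points)), 1e-9)
  expect_equal(cl1$arclength, cl2$arclength, tolerance = 1e-12)
})

test_that("straight centerlines carry identical frames along their length", {
  cl <- resample_centerline(rbind(c(0, 0, 0), c(0, 0, 20)), 1)
  fr <- compute_frames(cl)
  for (f in fr) {
    expect_equal(max(abs(sweep(f, 2, f[1, ]))), 0, tolerance = 1e-12)
  }
})

test_that("frames are orthonormal right-handed triads everywhere", {
  set.seed(31)
  for (rep in 1:4) {
    pts <- apply(matrix(rnorm(30, sd = 8), 10, 3), 2, cumsum)
    fr <- compute_frames(resample_centerline(pts, 0.5))
    for (i in seq_len(nrow(fr$tangent))) {
      M <- rbind(fr$tangent[i, ], fr$normal_u[i, ], fr$normal_v[i, ])
      expect_equal(M %*% t(M), diag(3), tolerance = 1e-6, ignore_attr = TRUE)
      expect_equal(det(M), 1, tolerance = 1e-6)
    }
  }
})

test_that("frames on a quarter-circle arc match the closed form", {
  R <- 30
  # dense sampling: one-sided endpoint tangents err by ~ dtheta/2, so the
  # 1e-3 comparison needs dtheta below 2e-3 rad
  theta <- seq(0, pi / 2, length.out = 1201)
  pts <- cbind(R * cos(theta), R * sin(theta), 0)
  fr <- compute_frames(as_centerline(pts))
  n <- length(theta)
  # tangent rotates 90 degrees from +y to -x
  expect_equal(fr$tangent[1, ], c(0, 1, 0), tolerance = 1e-3)
  expect_equal(fr$tangent[n, ], c(-1, 0, 0), tolerance = 1e-3)
  # rotation-minimizing transport on a planar curve: the out-of-plane normal
  # stays fixed while the in-plane one follows the radial direction
  out_of_plane <- which.max(abs(c(fr$normal_u[1, 3], fr$normal_v[1, 3])))
  oop <- if (out_of_plane == 1) fr$normal_u else fr$normal_v
  inp <- if (out_of_plane == 1) fr$normal_v else fr$normal_u
  expect_lt(max(abs(abs(oop[, 3]) - 1)), 1e-3)
  radial <- cbind(cos(theta), sin(theta), 0)
  sgn <- sign(sum(inp[1, ] * radial[1, ]))
  expect_lt(max(abs(inp - sgn * radial)), 1e-3)
})

test_that("a straight cylinder reslices to the analytic disk area", {
  spec0 <- test_spec(curvature_amplitude_mm = 0, noise_sd = 0,
                     tl_radius_mm = c(10, 10))
  vp <- make_phantom_volume(spec0, n_slices = 30, seed = 13)
  cl <- resample_centerline(vp$centerline_truth, 1)
  secs <- extract_cross_sections(vp, cl, fov_mm = 40)
  expect_true(all(vapply(secs, function(s) all(dim(s$pixels) == c(64, 64)),
                         TRUE)))
  px_area <- (40 / 64)^2
  inner <- secs[3:(length(secs) - 2)]
  for (s in inner) {
    area <- sum(s$lumen_mask) * px_area
    expect_lt(abs(area - pi * 100) / (pi * 100), 0.05)
  }
  # intensity-thresholded area agrees too (lumen 0.85+, background <= 0.30)
  for (s in inner[c(1, 10, 20)]) {
    area <- sum(s$pixels > 0.55) * px_area
    expect_lt(abs(area - pi * 100) / (pi * 100), 0.05)
  }
})

test_that("sampling outside the volume fills with zero instead of failing", {
  arr <- array(1, dim = c(10, 10, 10))
  cl <- as_centerline(rbind(c(0, 0, 0), c(0, 0, 9)))  # along the volume edge
  secs <- extract_cross_sections(arr, cl, fov_mm = 20, spacing = c(1, 1, 1))
  s <- secs[[1]]
  expect_true(any(s$pixels == 0))   # out-of-bounds region
  expect_true(any(s$pixels == 1))   # in-bounds region
})

test_that("empty centerline input errors", {
  arr <- array(0, dim = c(5, 5, 5))
  cl <- structure(list(points = matrix(0, 0, 3), arclength = numeric(0)),
                  class = "centerline")
  expect_error(extract_cross_sections(arr, cl, fov_mm = 10,
                                      spacing = c(1, 1, 1)),
               "empty centerline")
})

test_that("auto-centering moves the mask centroid to the grid center", {
  px <- matrix(0, 64, 64)
  mask <- matrix(FALSE, 64, 64)
  # off-center disk at (20, 40), radius 9 px
  for (r in 1:64) for (c in 1:64)
    if ((r - 20)^2 + (c - 40)^2 <= 81) { mask[r, c] <- TRUE; px[r, c] <- 0.9 }
  cs <- cross_section(px, 0.7, lumen_mask = mask)
  cen <- apply_mask_and_center(cs)
  m <- cen$lumen_mask
  cr <- sum((row(m) - 1)[m]) / sum(m)
  cc <- sum((col(m) - 1)[m]) / sum(m)
  expect_lte(abs(cr - 31.5), 0.5)
  expect_lte(abs(cc - 31.5), 0.5)
  # pixels outside the mask were zeroed, inside preserved exactly
  expect_equal(sort(unique(as.numeric(cen$pixels))), c(0, 0.9))
  expect_equal(sum(cen$pixels > 0), sum(mask))
})

test_that("an already-centered image is unchanged and centering is idempotent", {
  set.seed(41)
  s <- make_phantom_slice(test_spec(), "THROMBOSED_FL")
  once <- apply_mask_and_center(s)
  twice <- apply_mask_and_center(once)
  expect_identical(once$pixels, twice$pixels)
  expect_identical(once$lumen_mask, twice$lumen_mask)
  # a symmetric centered disk mask: no shift at all
  mask <- matrix(FALSE, 64, 64)
  for (r in 1:64) for (c in 1:64)
    if ((r - 32.5)^2 + (c - 32.5)^2 <= 100) mask[r, c] <- TRUE
  px <- matrix(runif(64 * 64), 64, 64)
  cs <- cross_section(px, 0.7, lumen_mask = mask)
  cen <- apply_mask_and_center(cs)
  expect_identical(cen$pixels[mask], px[mask])
  expect_identical(cen$lumen_mask, mask)
})

test_that("empty segmentation errors name the subject and slice", {
  cs <- cross_section(matrix(0.5, 64, 64), 0.7,
                      lumen_mask = matrix(FALSE, 64, 64),
                      subject_id = "S9", slice_index = 17L)
  expect_error(apply_mask_and_center(cs), "S9.*17")
})

test_that("window normalization maps lo -> 0, hi -> 1, midpoint -> 0.5", {
  expect_equal(normalize_intensity(c(-100, 300, 100), -100, 300),
               c(0, 1, 0.5))
  expect_equal(normalize_intensity(c(-200, 500), -100, 300), c(0, 1))  # clamp
  expect_error(normalize_intensity(1, 5, 5), "strictly less")
  cs <- cross_section(matrix(0.5, 64, 64), 0.7)
  expect_equal(normalize_intensity(cs, 0, 0.5)$pixels,
               matrix(1, 64, 64))
})

test_that("resliced phantom sections satisfy the cross-section contract", {
  vp <- make_phantom_volume(test_spec(), n_slices = 100, seed = 17,
                            labels = c(rep("NO_FL", 40),
                                       rep("THROMBOSED_FL", 60)))
  secs <- reslice_phantom(vp)
  expect_gt(length(secs), 0)
  idx <- vapply(secs, `[[`, 1L, "slice_index")
  expect_identical(idx, seq_along(secs))
  for (s in secs) {
    validate_cross_section(s)
    expect_true(all(dim(s$pixels) == c(64, 64)))
    m <- s$lumen_mask | s$thrombus_mask
    cr <- sum((row(m) - 1)[m]) / sum(m)
    cc <- sum((col(m) - 1)[m]) / sum(m)
    expect_lte(abs(cr - 31.5), 0.5)
    expect_lte(abs(cc - 31.5), 0.5)
  }
})

test_that("section stacks round-trip through NIfTI + manifest CSV", {
  vp <- make_phantom_volume(test_spec(), n_slices = 10, seed = 19,
                            labels = "PARTIAL_FL", subject_id = "RT2")
  secs <- reslice_phantom(vp)
  dir <- withr::local_tempdir()
  write_section_stack(secs, dir, "RT2")
  back <- read_section_stack(dir, "RT2")
  expect_length(back, length(secs))
  expect_equal(back[[3]]$pixels, secs[[3]]$pixels, tolerance = 1e-6)
  expect_identical(back[[3]]$lumen_mask, secs[[3]]$lumen_mask)
  expect_identical(back[[3]]$subject_id, "RT2")
  expect_equal(back[[3]]$arclength_mm, secs[[3]]$arclength_mm,
               tolerance = 1e-6)
})
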