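#' Resample an ordered 3D polyline at uniform arc-length spacing
#'
#' Output points lie on the piecewise-linear input path, spaced `step_mm` apart
#' in arc length; the final segment may be shorter so both endpoints are
#' preserved.
#'
#' @param points n x 3 matrix of ordered 3D coordinates (mm).
#' @param step_mm positive arc-length step (mm).
#' @return An object of class `centerline`: list with `points` (m x 3) and
#'   `arclength` (cumulative arc length, mm, starting at 0).
#' @export
resample_centerline <- function(points, step_mm) {
  if (!is.numeric(step_mm) || step_mm <= 0) stop("step_mm must be positive")
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be an n x 3 matrix")
  # drop consecutive duplicates
  if (nrow(points) > 1) {
    keep <- c(TRUE, rowSums((points[-1, , drop = FALSE] -
                             points[-nrow(points), , drop = FALSE])^2) > 1e-24)
    points <- points[keep, , drop = FALSE]
  }
  if (nrow(points) < 2)
    stop("degenerate centerline: fewer than 2 distinct points")

  seg <- sqrt(rowSums(diff(points)^2))
  s_in <- c(0, cumsum(seg))
  L <- s_in[length(s_in)]
  s_out <- seq(0, L, by = step_mm)
  if (L - s_out[length(s_out)] > 1e-9) s_out <- c(s_out, L)

  idx <- findInterval(s_out, s_in, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(points) - 1L)
  tloc <- (s_out - s_in[idx]) / seg[idx]
  pts <- points[idx, , drop = FALSE] +
    tloc * (points[idx + 1L, , drop = FALSE] - points[idx, , drop = FALSE])
  structure(list(points = pts, arclength = s_out), class = "centerline")
}

#' Treat an already-sampled point list as a centerline
#'
#' @param points n x 3 matrix (mm); consecutive points must be distinct.
#' @return A `centerline` with cumulative arc length computed from the points.
#' @export
as_centerline <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("degenerate centerline: fewer than 2 points")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg < 1e-12)) stop("consecutive centerline points must be distinct")
  structure(list(points = points, arclength = c(0, cumsum(seg))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.2f mm\n",
              nrow(x$points), max(x$arclength)))
  invisible(x)
}

normalize_rows <- function(m) m / sqrt(rowSums(m^2))

#' Rotation-minimizing frames along a centerline
#'
#' Computes per-point orthonormal right-handed triads (tangent, normal_u,
#' normal_v). Tangents use central differences (one-sided at the endpoints);
#' the in-plane basis is transported by the double-reflection method, so it
#' carries no spin about the tangent beyond what curvature forces. Frenet
#' frames are deliberately avoided: their normals flip at inflection points.
#'
#' @param centerline a `centerline` (from [resample_centerline()] or
#'   [as_centerline()]).
#' @return An object of class `frame_field`: list of n x 3 matrices `tangent`,
#'   `normal_u`, `normal_v`.
#' @export
compute_frames <- function(centerline) {
  stopifnot(inherits(centerline, "centerline"))
  p <- centerline$points
  n <- nrow(p)
  tg <- matrix(0, n, 3)
  tg[1, ] <- p[2, ] - p[1, ]
  tg[n, ] <- p[n, ] - p[n - 1, ]
  if (n > 2) tg[2:(n - 1), ] <- p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]
  tg <- normalize_rows(tg)

  # initial normal: axis least aligned with the first tangent, orthogonalized
  e <- diag(3)[, which.min(abs(tg[1, ]))]
  u <- matrix(0, n, 3)
  v <- matrix(0, n, 3)
  u0 <- e - sum(e * tg[1, ]) * tg[1, ]
  u[1, ] <- u0 / sqrt(sum(u0^2))
  v[1, ] <- cross3(tg[1, ], u[1, ])

  for (i in seq_len(n - 1)) {
    # double reflection (reflection in the chord bisector plane, then in the
    # bisector of the reflected and next tangents)
    v1 <- p[i + 1, ] - p[i, ]
    c1 <- sum(v1 * v1)
    uL <- u[i, ] - (2 / c1) * sum(v1 * u[i, ]) * v1
    tL <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    v2 <- tg[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    ui <- if (c2 > 1e-24) uL - (2 / c2) * sum(v2 * uL) * v2 else uL
    # re-orthogonalize against the tangent to keep triads orthonormal
    ui <- ui - sum(ui * tg[i + 1, ]) * tg[i + 1, ]
    u[i + 1, ] <- ui / sqrt(sum(ui^2))
    v[i + 1, ] <- cross3(tg[i + 1, ], u[i + 1, ])
  }
  structure(list(tangent = tg, normal_u = u, normal_v = v),
            class = "frame_field")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Vectorized trilinear interpolation. arr is a 3D array with voxel centers at
# world (index - 1) * spacing (0-based centers); pts is m x 3 in mm.
# Samples outside the volume contribute `fill`.
trilinear_sample <- function(arr, spacing, pts, fill = 0) {
  d <- dim(arr)
  g <- sweep(pts, 2, spacing, "/")  # continuous 0-based voxel coordinates
  i0 <- floor(g)
  fr <- g - i0
  out <- numeric(nrow(pts))
  for (corner in 0:7) {
    dx <- corner %% 2
    dy <- (corner %/% 2) %% 2
    dz <- corner %/% 4
    ii <- i0[, 1] + dx
    jj <- i0[, 2] + dy
    kk <- i0[, 3] + dz
    w <- (if (dx == 1) fr[, 1] else 1 - fr[, 1]) *
         (if (dy == 1) fr[, 2] else 1 - fr[, 2]) *
         (if (dz == 1) fr[, 3] else 1 - fr[, 3])
    inside <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
    vals <- rep(fill, nrow(pts))
    if (any(inside)) {
      lin <- ii[inside] + 1 + jj[inside] * d[1] + kk[inside] * d[1] * d[2]
      vals[inside] <- arr[lin]
    }
    out <- out + w * vals
  }
  out
}

#' Extract perpendicular cross-sections from a volume along a centerline
#'
#' For each centerline point, samples a `grid_n` x `grid_n` plane spanned by
#' the frame's (normal_u, normal_v) and centered at the point, using trilinear
#' interpolation; samples outside the volume fill with 0. Pixel (r, c) of the
#' output maps to world point `center + off[c] * normal_u + off[r] * normal_v`,
#' with pixel-center offsets `off = ((0:(n-1)) - (n-1)/2) * fov_mm / n`, i.e.
#' normal_u runs along columns and normal_v along rows.
#'
#' @param volume a `volume_phantom`, or a 3D array (then `spacing` required).
#' @param centerline a `centerline`.
#' @param frames a `frame_field`; computed from `centerline` when `NULL`.
#' @param fov_mm in-plane field of view (mm).
#' @param grid_n output grid size (default 64).
#' @param spacing voxel spacing (mm), required when `volume` is a bare array.
#' @param masks optional named list of 3D logical arrays resliced alongside the
#'   intensities (sampled trilinearly, thresholded at 0.5). For a
#'   `volume_phantom` the ground-truth masks are used automatically.
#' @param subject_id subject identifier for the output slices.
#' @param labels optional per-centerline-point labels carried to the output.
#' @return list of [cross_section()]s, one per centerline point.
#' @export
extract_cross_sections <- function(volume, centerline, frames = NULL,
                                   fov_mm, grid_n = 64L, spacing = NULL,
                                   masks = NULL, subject_id = NULL,
                                   labels = NULL) {
  if (inherits(volume, "volume_phantom")) {
    arr <- volume$intensities
    spacing <- volume$spacing_mm
    if (is.null(masks))
      masks <- list(lumen_mask = volume$lumen_mask,
                    thrombus_mask = volume$thrombus_mask)
    if (is.null(subject_id)) subject_id <- volume$subject_id
  } else {
    arr <- volume
    if (is.null(spacing)) stop("spacing required for a bare array volume")
  }
  subject_id <- subject_id %||% "unknown"
  stopifnot(inherits(centerline, "centerline"))
  if (nrow(centerline$points) == 0) stop("empty centerline")
  if (!is.numeric(fov_mm) || fov_mm <= 0) stop("fov_mm must be positive")
  if (is.null(frames)) frames <- compute_frames(centerline)

  n <- as.integer(grid_n)
  off <- ((seq_len(n) - 1) - (n - 1) / 2) * (fov_mm / n)
  # pixel (r, c): offsets along v for rows, along u for columns
  off_u <- rep(off, each = n)   # column index varies slowly in col-major
  off_v <- rep(off, times = n)
  # column-major order: element (r, c) at r + (c-1)*n -> off_v = off[r], off_u = off[c]

  m <- nrow(centerline$points)
  sections <- vector("list", m)
  for (i in seq_len(m)) {
    ctr <- centerline$points[i, ]
    u <- frames$normal_u[i, ]
    v <- frames$normal_v[i, ]
    pts <- cbind(ctr[1] + off_u * u[1] + off_v * v[1],
                 ctr[2] + off_u * u[2] + off_v * v[2],
                 ctr[3] + off_u * u[3] + off_v * v[3])
    px <- matrix(trilinear_sample(arr, spacing, pts), n, n)
    ms <- list(lumen_mask = NULL, thrombus_mask = NULL)
    for (nm in names(masks)) {
      ms[[nm]] <- matrix(trilinear_sample(masks[[nm]] * 1, spacing, pts) > 0.5,
                         n, n)
    }
    sections[[i]] <- cross_section(
      pixels = px, pixel_spacing_mm = fov_mm / n,
      lumen_mask = ms$lumen_mask, thrombus_mask = ms$thrombus_mask,
      subject_id = subject_id, slice_index = i,
      arclength_mm = centerline$arclength[i],
      label = if (!is.null(labels)) labels[i] else NA_character_)
  }
  sections
}

#' Apply a segmentation mask and auto-center the result
#'
#' Sets pixels outside the mask to 0, then translates the image by an integer
#' pixel shift so the mask centroid lands within half a pixel of the grid
#' center ((n-1)/2, (n-1)/2) under the 0-based pixel-center convention. The
#' integer shift preserves intensities exactly; masks are shifted identically.
#' The operation is idempotent.
#'
#' @param cs a [cross_section()].
#' @param mask logical matrix congruent with the image; defaults to the union
#'   of the slice's lumen and thrombus masks.
#' @return The masked, centered [cross_section()].
#' @export
apply_mask_and_center <- function(cs, mask = NULL) {
  stopifnot(inherits(cs, "cross_section"))
  if (is.null(mask)) mask <- segmentation_mask(cs)
  if (is.null(mask))
    stop("no segmentation mask available on this cross-section")
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(cs$pixels)))
    stop("mask must be congruent with the image")
  npx <- sum(mask)
  if (npx == 0)
    stop(sprintf("empty segmentation for subject %s slice %d",
                 cs$subject_id, cs$slice_index))

  n <- nrow(cs$pixels)
  target <- (n - 1) / 2
  r0 <- row(mask) - 1
  c0 <- col(mask) - 1
  cr <- sum(r0[mask]) / npx
  cc <- sum(c0[mask]) / npx
  dr <- round(target - cr)
  dc <- round(target - cc)

  px <- cs$pixels
  px[!mask] <- 0
  cs$pixels <- shift_matrix(px, dr, dc)
  for (nm in c("lumen_mask", "thrombus_mask", "fl_mask")) {
    if (!is.null(cs[[nm]]))
      cs[[nm]] <- shift_matrix(cs[[nm]] & mask, dr, dc, fill = FALSE)
  }
  cs
}

shift_matrix <- function(m, dr, dc, fill = 0) {
  n <- nrow(m)
  p <- ncol(m)
  out <- matrix(fill, n, p)
  src_r <- seq_len(n) - dr
  src_c <- seq_len(p) - dc
  ok_r <- src_r >= 1 & src_r <= n
  ok_c <- src_c >= 1 & src_c <= p
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Window-normalize intensities into \[0, 1\]
#'
#' Affine map sending `window_lo` to 0 and `window_hi` to 1, clamped to \[0, 1\].
#'
#' @param x numeric array/matrix or a [cross_section()].
#' @param window_lo,window_hi window bounds; `window_lo < window_hi`.
#' @return Same shape as `x`, values in \[0, 1\].
#' @export
normalize_intensity <- function(x, window_lo, window_hi) {
  if (!is.numeric(window_lo) || !is.numeric(window_hi) ||
      window_lo >= window_hi)
    stop("window_lo must be strictly less than window_hi")
  if (inherits(x, "cross_section")) {
    x$pixels <- clamp01((x$pixels - window_lo) / (window_hi - window_lo))
    return(x)
  }
  clamp01((x - window_lo) / (window_hi - window_lo))
}

#' Reslice a phantom volume into masked, centered, normalized sections
#'
#' Convenience wrapper chaining [resample_centerline()], [compute_frames()],
#' [extract_cross_sections()] and [apply_mask_and_center()] on a
#' `volume_phantom`. Slices whose resliced segmentation is empty (possible at
#' the very ends of the tube) are dropped.
#'
#' @param volume a `volume_phantom`.
#' @param step_mm centerline resampling step; default = axial voxel spacing.
#' @param fov_mm in-plane field of view (mm); default covers the 64-pixel grid
#'   at the volume's in-plane spacing.
#' @param grid_n output grid size.
#' @return list of [cross_section()]s.
#' @export
reslice_phantom <- function(volume, step_mm = NULL, fov_mm = NULL,
                            grid_n = 64L) {
  stopifnot(inherits(volume, "volume_phantom"))
  step_mm <- step_mm %||% volume$spacing_mm[3]
  fov_mm <- fov_mm %||% (grid_n * volume$spacing_mm[1])
  cl <- resample_centerline(volume$centerline_truth, step_mm)
  frames <- compute_frames(cl)
  # carry ground-truth labels by nearest original slice (z spacing known)
  zsp <- volume$spacing_mm[3]
  src_idx <- pmin(pmax(round(cl$points[, 3] / zsp) + 1L, 1L),
                  length(volume$labels))
  sections <- extract_cross_sections(volume, cl, frames, fov_mm = fov_mm,
                                     grid_n = grid_n,
                                     labels = volume$labels[src_idx])
  out <- list()
  for (cs in sections) {
    m <- segmentation_mask(cs)
    if (is.null(m) || sum(m) == 0) next
    out[[length(out) + 1]] <- apply_mask_and_center(cs)
  }
  # reindex so slice_index stays unique and ordered
  for (i in seq_along(out)) out[[i]]$slice_index <- i
  out
}
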