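#' Slice label levels for false-lumen status
#'
#' The four-category classification of the false lumen (FL) on a single
#' cross-section: no FL present, patent (fully perfused) FL, partially
#' thrombosed FL, or fully thrombosed FL.
#'
#' @export
SLICE_LABELS <- c("NO_FL", "PATENT_FL", "PARTIAL_FL", "THROMBOSED_FL")

DISSECTED_LABELS <- c("PATENT_FL", "PARTIAL_FL", "THROMBOSED_FL")

#' Specification of the synthetic aorta phantom
#'
#' Collects the geometric and intensity parameters used by the phantom
#' generators. The cross-section geometry is two disk sectors (true lumen TL
#' and false lumen FL) separated by a straight septum stripe; thrombus fills an
#' angular fraction of the FL sector. Intensities emulate windowed CT
#' angiography: patent lumen hyperintense, thrombus isointense (mid-range, near
#' soft tissue), background mid-low. All intensities are on the normalized
#' \[0, 1\] scale the VAE consumes.
#'
#' @param voxel_spacing_mm positive length-3 voxel spacing (x, y, z) in mm; the
#'   in-plane spacing must be isotropic.
#' @param tl_radius_mm length-2 range (mm) for the true-lumen radius. Dissected
#'   slices draw from the upper half of the range, non-dissected from the lower
#'   half, so dissected aortas are systematically larger.
#' @param fl_radius_mm length-2 range (mm) for the false-lumen radius.
#' @param septum_thickness_mm thickness (mm) of the septum stripe between TL
#'   and FL.
#' @param thrombus_fraction length-2 range in \[0, 1\]: fraction of the FL sector
#'   filled by thrombus. `THROMBOSED_FL` slices draw from this range directly;
#'   `PARTIAL_FL` slices draw from it and clamp into \[0.05, 0.95\] so they stay
#'   strictly partial.
#' @param intensity_lumen,intensity_thrombus,intensity_background length-2
#'   ranges for the per-slice intensity draws; the range means must satisfy
#'   lumen > thrombus >= background.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param curvature_amplitude_mm amplitude (mm) of the single-axis sinusoidal
#'   centerline bend used by [make_phantom_volume()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_spacing_mm = c(0.7, 0.7, 1.0),
                         tl_radius_mm = c(8, 14),
                         fl_radius_mm = c(6, 12),
                         septum_thickness_mm = 1.5,
                         thrombus_fraction = c(0.9, 1.0),
                         intensity_lumen = c(0.85, 0.95),
                         intensity_thrombus = c(0.35, 0.50),
                         intensity_background = c(0.15, 0.30),
                         noise_sd = 0.03,
                         curvature_amplitude_mm = 8) {
  chk_range <- function(r, nm, lo_ok = 0) {
    if (length(r) != 2 || !is.numeric(r) || any(!is.finite(r)))
      stop(sprintf("%s must be a finite length-2 numeric range", nm))
    if (r[1] > r[2]) stop(sprintf("%s: low must be <= high", nm))
    if (r[1] < lo_ok && lo_ok == 0 && any(r < 0))
      stop(sprintf("%s must be nonnegative", nm))
    r
  }
  if (length(voxel_spacing_mm) != 3 || any(voxel_spacing_mm <= 0))
    stop("voxel_spacing_mm must be a positive 3-vector")
  if (abs(voxel_spacing_mm[1] - voxel_spacing_mm[2]) > 1e-9)
    stop("in-plane voxel spacing must be isotropic")
  chk_range(tl_radius_mm, "tl_radius_mm")
  if (any(tl_radius_mm <= 0)) stop("tl_radius_mm must be positive")
  chk_range(fl_radius_mm, "fl_radius_mm")
  if (any(fl_radius_mm <= 0)) stop("fl_radius_mm must be positive")
  if (!is.numeric(septum_thickness_mm) || septum_thickness_mm <= 0)
    stop("septum_thickness_mm must be a positive scalar")
  chk_range(thrombus_fraction, "thrombus_fraction")
  if (thrombus_fraction[1] < 0 || thrombus_fraction[2] > 1)
    stop("thrombus_fraction must lie within [0, 1]")
  chk_range(intensity_lumen, "intensity_lumen")
  chk_range(intensity_thrombus, "intensity_thrombus")
  chk_range(intensity_background, "intensity_background")
  if (!(mean(intensity_lumen) > mean(intensity_thrombus)))
    stop("mean(intensity_lumen) must exceed mean(intensity_thrombus)")
  if (!(mean(intensity_thrombus) >= mean(intensity_background)))
    stop("mean(intensity_thrombus) must be >= mean(intensity_background)")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (curvature_amplitude_mm < 0)
    stop("curvature_amplitude_mm must be nonnegative")

  structure(list(
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    tl_radius_mm = as.numeric(tl_radius_mm),
    fl_radius_mm = as.numeric(fl_radius_mm),
    septum_thickness_mm = as.numeric(septum_thickness_mm),
    thrombus_fraction = as.numeric(thrombus_fraction),
    intensity_lumen = as.numeric(intensity_lumen),
    intensity_thrombus = as.numeric(intensity_thrombus),
    intensity_background = as.numeric(intensity_background),
    noise_sd = as.numeric(noise_sd),
    curvature_amplitude_mm = as.numeric(curvature_amplitude_mm)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  cat(sprintf("  voxel spacing: %s mm\n", paste(x$voxel_spacing_mm, collapse = " x ")))
  cat(sprintf("  TL radius: [%g, %g] mm; FL radius: [%g, %g] mm; septum %g mm\n",
              x$tl_radius_mm[1], x$tl_radius_mm[2],
              x$fl_radius_mm[1], x$fl_radius_mm[2], x$septum_thickness_mm))
  cat(sprintf("  thrombus fraction: [%g, %g]; noise sd %g; curvature %g mm\n",
              x$thrombus_fraction[1], x$thrombus_fraction[2],
              x$noise_sd, x$curvature_amplitude_mm))
  invisible(x)
}

draw_range <- function(r) runif(1, r[1], r[2])
upper_half <- function(r) c(mean(r), r[2])
lower_half <- function(r) c(r[1], mean(r))

# Smooth per-slice radius profile inside [rng[1], rng[2]]: a low-frequency
# sinusoid with random frequency and phase, emulating caliber variation along
# the aorta. A degenerate range yields an exactly constant radius.
smooth_radius_profile <- function(rng, n) {
  if (diff(rng) < 1e-12) return(rep(rng[1], n))
  f <- sample(1:2, 1)
  phase <- runif(1, 0, 2 * pi)
  z <- seq(0, 1, length.out = n)
  rng[1] + diff(rng) * (0.5 + 0.5 * sin(2 * pi * f * z + phase))
}

# Geometry on coordinate grids X, Y (mm, relative to the section center).
# TL occupies the half-disk x < -t/2 of radius r_tl; FL the half-disk x > t/2
# of radius r_fl; thrombus fills the angular fraction `frac` of the FL sector,
# sweeping from theta = -pi/2. Returns logical masks.
dissection_masks <- function(X, Y, label, r_tl, r_fl, septum_t, frac) {
  rr <- X^2 + Y^2
  if (label == "NO_FL") {
    lumen <- rr <= r_tl^2
    empty <- array(FALSE, dim = dim(X))
    return(list(tl = lumen, fl = empty, thrombus = empty, septum = empty,
                lumen = lumen))
  }
  half <- septum_t / 2
  tl <- X < -half & rr <= r_tl^2
  fl <- X > half & rr <= r_fl^2
  septum <- abs(X) <= half & rr <= max(r_tl, r_fl)^2
  thrombus <- array(FALSE, dim = dim(X))
  n_fl <- sum(fl)
  if (frac > 0 && n_fl > 0) {
    # thrombus sweeps the FL sector from theta = -pi/2 upward; the cut is the
    # empirical angular quantile, so the pixel-count fraction matches `frac`
    # to within one pixel of the analytic sector area
    k <- round(frac * n_fl)
    if (k > 0) {
      theta <- atan2(Y[fl], X[fl])
      idx_fl <- which(fl)
      thrombus[idx_fl[order(theta)[seq_len(k)]]] <- TRUE
    }
  }
  list(tl = tl, fl = fl, thrombus = thrombus, septum = septum,
       lumen = tl | (fl & !thrombus))
}

label_fraction <- function(spec, label) {
  switch(label,
    NO_FL = 0,
    PATENT_FL = 0,
    PARTIAL_FL = clamp01(draw_range(spec$thrombus_fraction), 0.05, 0.95),
    THROMBOSED_FL = draw_range(spec$thrombus_fraction))
}

label_radii <- function(spec, label) {
  if (label %in% DISSECTED_LABELS) {
    list(r_tl = draw_range(upper_half(spec$tl_radius_mm)),
         r_fl = draw_range(upper_half(spec$fl_radius_mm)))
  } else {
    list(r_tl = draw_range(lower_half(spec$tl_radius_mm)), r_fl = NA_real_)
  }
}

render_slice <- function(spec, masks, grid_dim) {
  lum <- draw_range(spec$intensity_lumen)
  thr <- draw_range(spec$intensity_thrombus)
  bg <- draw_range(spec$intensity_background)
  px <- array(bg, dim = grid_dim)
  px[masks$lumen] <- lum
  px[masks$thrombus] <- thr
  if (spec$noise_sd > 0)
    px <- px + rnorm(length(px), 0, spec$noise_sd)
  clamp01(px)
}

#' Generate one synthetic aortic cross-section
#'
#' Draws geometry and intensities from `spec` (using the current RNG state) and
#' renders a 64x64 image with ground-truth lumen and thrombus masks. The patent
#' lumen is hyperintense and thrombus isointense relative to background, as in
#' contrast-enhanced CT.
#'
#' @param spec a [phantom_spec()].
#' @param label one of [SLICE_LABELS].
#' @param grid_n image size in pixels (default 64).
#' @param subject_id,slice_index metadata stored on the result.
#' @return A [cross_section()] with `lumen_mask`, `thrombus_mask`, `fl_mask`
#'   and the drawn `thrombus_fraction` attached.
#' @export
make_phantom_slice <- function(spec, label, grid_n = 64L,
                               subject_id = "phantom", slice_index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  label <- match.arg(label, SLICE_LABELS)
  sp <- spec$voxel_spacing_mm[1]
  ctr <- (grid_n - 1) / 2
  ax <- (seq_len(grid_n) - 1 - ctr) * sp
  X <- matrix(ax, grid_n, grid_n, byrow = TRUE)  # x along columns
  Y <- matrix(ax, grid_n, grid_n)                # y along rows

  radii <- label_radii(spec, label)
  frac <- label_fraction(spec, label)
  masks <- dissection_masks(X, Y, label, radii$r_tl, radii$r_fl,
                            spec$septum_thickness_mm, frac)
  px <- render_slice(spec, masks, c(grid_n, grid_n))

  cross_section(pixels = px, pixel_spacing_mm = sp,
                lumen_mask = masks$lumen, thrombus_mask = masks$thrombus,
                subject_id = subject_id, slice_index = as.integer(slice_index),
                label = label, fl_mask = masks$fl,
                thrombus_fraction = if (label %in% c("PARTIAL_FL", "THROMBOSED_FL")) frac else 0)
}

#' Generate a labelled cohort of synthetic cross-sections
#'
#' @param spec a [phantom_spec()].
#' @param class_counts named integer vector mapping labels in [SLICE_LABELS] to
#'   nonnegative counts.
#' @param seed integer seed; the cohort is fully reproducible from
#'   `(spec, class_counts, seed)`.
#' @param subject_id subject identifier stored on every slice.
#' @return list with `slices` (list of [cross_section()]) and `labels`
#'   (data.frame with subject_id, slice_index, label).
#' @export
make_phantom_cohort <- function(spec, class_counts, seed, subject_id = "S1") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(names(class_counts)) || !all(names(class_counts) %in% SLICE_LABELS))
    stop("class_counts must be named with labels among: ",
         paste(SLICE_LABELS, collapse = ", "))
  if (any(class_counts < 0)) stop("class counts must be nonnegative")
  if (sum(class_counts) == 0) stop("empty cohort: all class counts are zero")

  set.seed(as.integer(seed))
  labels <- rep(names(class_counts), times = class_counts)
  slices <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    slices[[i]] <- make_phantom_slice(spec, labels[i],
                                      subject_id = subject_id,
                                      slice_index = i)
  }
  list(slices = slices,
       labels = data.frame(subject_id = subject_id,
                           slice_index = seq_along(labels),
                           label = labels,
                           stringsAsFactors = FALSE))
}

#' Generate a 3D tube phantom with known centerline and masks
#'
#' Builds a volume containing a (optionally curved) vessel whose cross-section
#' follows the TL/FL disk-sector geometry. The centerline bends sinusoidally
#' along one axis with amplitude `spec$curvature_amplitude_mm` over one full
#' period. Radii follow smooth per-slice caliber profiles within their allowed
#' subranges (constant when the range is degenerate): dissected segments draw
#' from the upper half of the radius ranges, no-FL segments from the lower
#' half — the aorta is wide where the false lumen adds width. Per-slice labels
#' control where the false lumen and thrombus are present; the ground-truth
#' centerline always runs inside the patent true lumen.
#'
#' @param spec a [phantom_spec()].
#' @param n_slices number of axial slices (>= 2).
#' @param seed integer seed.
#' @param labels per-slice labels (recycled scalar or length `n_slices`);
#'   default all `"NO_FL"`.
#' @param dim_xy optional in-plane grid dimension (single integer). When given
#'   and the tube would leave the grid, generation fails naming the offending
#'   slice; when `NULL` the grid is sized to fit.
#' @param subject_id subject identifier.
#' @return An object of class `volume_phantom`: list with `intensities`,
#'   `spacing_mm`, `centerline_truth` (n x 3, mm), `lumen_mask`,
#'   `thrombus_mask`, `labels`.
#' @export
make_phantom_volume <- function(spec, n_slices, seed, labels = "NO_FL",
                                dim_xy = NULL, subject_id = "S1") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_slices < 2) stop("n_slices must be >= 2")
  labels <- rep(labels, length.out = n_slices)
  if (!all(labels %in% SLICE_LABELS))
    stop("labels must be among: ", paste(SLICE_LABELS, collapse = ", "))

  set.seed(as.integer(seed))
  spx <- spec$voxel_spacing_mm[1]
  spz <- spec$voxel_spacing_mm[3]
  A <- spec$curvature_amplitude_mm
  dissected <- any(labels %in% DISSECTED_LABELS)

  # Radii vary smoothly along the vessel (aortic caliber is not constant),
  # each profile staying within its allowed subrange; a degenerate range
  # gives an exactly constant radius. Dissected segments are wide because the
  # false lumen adds width; no-FL segments are normal-caliber patent aorta
  # even in a dissected subject, so they always use the lower half of the TL
  # radius range.
  r_tl_norm <- smooth_radius_profile(lower_half(spec$tl_radius_mm), n_slices)
  r_tl_diss <- if (dissected)
    smooth_radius_profile(upper_half(spec$tl_radius_mm), n_slices) else
    rep(NA_real_, n_slices)
  r_fl <- if (dissected)
    smooth_radius_profile(upper_half(spec$fl_radius_mm), n_slices) else
    rep(NA_real_, n_slices)
  frac_thromb <- draw_range(spec$thrombus_fraction)
  frac_partial <- clamp01(draw_range(spec$thrombus_fraction), 0.05, 0.95)

  # the centerline tracks the patent true lumen; dissected geometry is placed
  # so the TL half-disk centroid sits on the centerline, which keeps the line
  # inside the lumen and continuous across label changes
  gc_off <- if (dissected)
    spec$septum_thickness_mm / 2 + 4 * r_tl_diss / (3 * pi) else
    rep(0, n_slices)
  reach <- if (dissected)
    max(r_tl_norm, gc_off + pmax(r_tl_diss, r_fl)) else max(r_tl_norm)

  margin <- 3 * spx
  if (is.null(dim_xy)) {
    half_extent <- A + reach + margin
    dim_xy <- 2L * as.integer(ceiling(half_extent / spx)) + 1L
  }
  nx <- as.integer(dim_xy)
  cx <- (nx - 1) / 2 * spx  # volume center, mm

  intens <- array(0, dim = c(nx, nx, n_slices))
  lmask <- array(FALSE, dim = c(nx, nx, n_slices))
  tmask <- array(FALSE, dim = c(nx, nx, n_slices))
  cl <- matrix(0, n_slices, 3)

  xmm <- (seq_len(nx) - 1) * spx
  Lz <- (n_slices - 1) * spz
  for (k in seq_len(n_slices)) {
    zmm <- (k - 1) * spz
    clx <- cx + (if (A > 0) A * sin(2 * pi * zmm / Lz) else 0)
    diss_k <- labels[k] %in% DISSECTED_LABELS
    gcx <- clx + (if (diss_k) gc_off[k] else 0)
    reach_k <- if (diss_k) max(r_tl_diss[k], r_fl[k]) else r_tl_norm[k]
    if (gcx - reach_k < 0 || gcx + reach_k > xmm[nx] ||
        cx - reach_k < 0 || cx + reach_k > xmm[nx])
      stop(sprintf("tube exits volume bounds at slice %d", k))
    X <- matrix(xmm - gcx, nx, nx)        # x along rows (first array index)
    Y <- matrix(xmm - cx, nx, nx, byrow = TRUE)  # y along columns
    frac <- switch(labels[k], THROMBOSED_FL = frac_thromb,
                   PARTIAL_FL = frac_partial, 0)
    masks <- dissection_masks(X, Y, labels[k],
                              if (diss_k) r_tl_diss[k] else r_tl_norm[k],
                              r_fl[k], spec$septum_thickness_mm, frac)
    intens[, , k] <- render_slice(spec, masks, c(nx, nx))
    lmask[, , k] <- masks$lumen
    tmask[, , k] <- masks$thrombus
    cl[k, ] <- c(clx, cx, zmm)
  }

  structure(list(
    intensities = intens,
    spacing_mm = c(spx, spx, spz),
    centerline_truth = cl,
    lumen_mask = lmask,
    thrombus_mask = tmask,
    labels = labels,
    subject_id = subject_id,
    geometry = list(r_tl = r_tl_norm, r_tl_dissected = r_tl_diss, r_fl = r_fl,
                    geometry_offset_mm = gc_off,
                    frac_thromb = frac_thromb, frac_partial = frac_partial)
    # r_tl / r_tl_dissected / r_fl are per-slice profiles (length n_slices)
  ), class = "volume_phantom")
}

#' @export
print.volume_phantom <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume_phantom> %s: %d x %d x %d voxels @ %s mm\n",
              x$subject_id, d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 3), collapse = " x ")))
  cat(sprintf("  labels: %s\n", paste(unique(x$labels), collapse = ", ")))
  invisible(x)
}

#' Write / read a volume phantom as NIfTI plus plain-text sidecars
#'
#' Intensities and masks are written as separate NIfTI files, the ground-truth
#' centerline as whitespace-delimited `x y z` (mm) text, and the slice labels
#' as CSV (subject_id, slice_index, label).
#'
#' @param vp a `volume_phantom`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_volume_phantom <- function(vp, dir, prefix = vp$subject_id) {
  stopifnot(inherits(vp, "volume_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    intensities = file.path(dir, paste0(prefix, "_intensities.nii.gz")),
    lumen_mask = file.path(dir, paste0(prefix, "_lumen_mask.nii.gz")),
    thrombus_mask = file.path(dir, paste0(prefix, "_thrombus_mask.nii.gz")),
    centerline = file.path(dir, paste0(prefix, "_centerline.txt")),
    labels = file.path(dir, paste0(prefix, "_labels.csv"))
  )
  write_nifti_array(vp$intensities, vp$spacing_mm, paths["intensities"])
  write_nifti_array(vp$lumen_mask * 1, vp$spacing_mm, paths["lumen_mask"])
  write_nifti_array(vp$thrombus_mask * 1, vp$spacing_mm, paths["thrombus_mask"])
  write_centerline_points(vp$centerline_truth, paths["centerline"])
  write.csv(data.frame(subject_id = vp$subject_id,
                       slice_index = seq_along(vp$labels),
                       label = vp$labels),
            paths["labels"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' @rdname write_volume_phantom
#' @param dir directory holding files written by [write_volume_phantom()].
#' @export
read_volume_phantom <- function(dir, prefix) {
  f <- function(suffix) file.path(dir, paste0(prefix, suffix))
  intens <- read_nifti_array(f("_intensities.nii.gz"))
  lmask <- read_nifti_array(f("_lumen_mask.nii.gz"))
  tmask <- read_nifti_array(f("_thrombus_mask.nii.gz"))
  labels <- read.csv(f("_labels.csv"), stringsAsFactors = FALSE)
  structure(list(
    intensities = intens$data,
    spacing_mm = intens$spacing,
    centerline_truth = read_centerline_points(f("_centerline.txt")),
    lumen_mask = lmask$data > 0.5,
    thrombus_mask = tmask$data > 0.5,
    labels = labels$label,
    subject_id = labels$subject_id[1],
    geometry = NULL
  ), class = "volume_phantom")
}

write_nifti_array <- function(arr, spacing, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), spacing = RNifti::pixdim(img)[1:3])
}

#' Write / read a centerline as whitespace-delimited x y z text (mm)
#'
#' @param points n x 3 matrix of points in mm.
#' @param path file path.
#' @export
write_centerline_points <- function(points, path) {
  write.table(format(points, digits = 12, trim = TRUE, scientific = FALSE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_centerline_points
#' @export
read_centerline_points <- function(path) {
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  if (ncol(m) != 3) stop("centerline file must have 3 columns (x y z in mm)")
  m
}
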