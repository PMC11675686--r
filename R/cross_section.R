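#' Construct a cross-section image object
#'
#' One aortic cross-section: a square pixel grid (normally 64x64, the VAE's
#' input size) with optional congruent lumen/thrombus masks and slice metadata.
#'
#' @param pixels square numeric matrix of intensities.
#' @param pixel_spacing_mm positive in-plane pixel spacing in mm.
#' @param lumen_mask,thrombus_mask optional logical matrices congruent with
#'   `pixels`.
#' @param subject_id subject identifier.
#' @param slice_index integer slice index, unique within a subject.
#' @param arclength_mm arc-length position along the centerline (mm).
#' @param label optional ground-truth label (see [SLICE_LABELS]).
#' @param fl_mask optional logical matrix of the whole false-lumen region.
#' @param thrombus_fraction optional scalar, fraction of FL filled by thrombus.
#' @return An object of class `cross_section`.
#' @export
cross_section <- function(pixels, pixel_spacing_mm,
                          lumen_mask = NULL, thrombus_mask = NULL,
                          subject_id = "unknown", slice_index = 1L,
                          arclength_mm = NA_real_, label = NA_character_,
                          fl_mask = NULL, thrombus_fraction = NA_real_) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels)) stop("pixels must be square")
  if (!is.numeric(pixels) || any(!is.finite(pixels)))
    stop("pixels must be finite numeric")
  if (!is.numeric(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    stop("pixel_spacing_mm must be positive")
  chk_mask <- function(m, nm) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!identical(dim(m), dim(pixels)))
      stop(sprintf("%s must be congruent with pixels", nm))
    storage.mode(m) <- "logical"
    m
  }
  structure(list(
    pixels = pixels,
    pixel_spacing_mm = as.numeric(pixel_spacing_mm),
    lumen_mask = chk_mask(lumen_mask, "lumen_mask"),
    thrombus_mask = chk_mask(thrombus_mask, "thrombus_mask"),
    fl_mask = chk_mask(fl_mask, "fl_mask"),
    subject_id = as.character(subject_id),
    slice_index = as.integer(slice_index),
    arclength_mm = as.numeric(arclength_mm),
    label = as.character(label),
    thrombus_fraction = as.numeric(thrombus_fraction)
  ), class = "cross_section")
}

#' Validate cross-section invariants
#'
#' Checks that pixels lie in \[0, 1\] (within tolerance) and that masks, when
#' present, are congruent and disjoint where that is meaningful.
#'
#' @param cs a [cross_section()].
#' @param tol numeric tolerance on the \[0, 1\] range.
#' @return `cs`, invisibly; errors on violation.
#' @export
validate_cross_section <- function(cs, tol = 1e-9) {
  stopifnot(inherits(cs, "cross_section"))
  if (min(cs$pixels) < -tol || max(cs$pixels) > 1 + tol)
    stop(sprintf("pixels out of [0, 1] for subject %s slice %d",
                 cs$subject_id, cs$slice_index))
  if (!is.null(cs$lumen_mask) && !is.null(cs$thrombus_mask) &&
      any(cs$lumen_mask & cs$thrombus_mask))
    stop("lumen_mask and thrombus_mask overlap")
  invisible(cs)
}

#' @export
print.cross_section <- function(x, ...) {
  n <- nrow(x$pixels)
  cat(sprintf("<cross_section> %s #%d: %dx%d @ %.3g mm/px",
              x$subject_id, x$slice_index, n, n, x$pixel_spacing_mm))
  if (!is.na(x$label)) cat(sprintf(" [%s]", x$label))
  cat("\n")
  invisible(x)
}

# segmentation = union of available masks; NULL if none
segmentation_mask <- function(cs) {
  m <- NULL
  for (nm in c("lumen_mask", "thrombus_mask")) {
    if (!is.null(cs[[nm]])) m <- if (is.null(m)) cs[[nm]] else m | cs[[nm]]
  }
  m
}

#' Convert cross-sections to the pixel matrix consumed by the VAE
#'
#' @param images a list of [cross_section()]s, a 64x64xN array, or an
#'   N-column matrix with 4096 rows.
#' @return numeric matrix (4096 x N), one image per column.
#' @export
images_to_matrix <- function(images) {
  if (is.list(images) && !is.data.frame(images)) {
    if (length(images) == 0) stop("empty image list")
    mats <- lapply(images, function(cs) {
      if (inherits(cs, "cross_section")) cs$pixels else as.matrix(cs)
    })
    n <- nrow(mats[[1]])
    if (any(vapply(mats, function(m) !identical(dim(m), c(n, n)), TRUE)))
      stop("all images must share the same square size")
    return(vapply(mats, as.numeric, numeric(n * n)))
  }
  if (is.array(images) && length(dim(images)) == 3) {
    d <- dim(images)
    return(matrix(images, d[1] * d[2], d[3]))
  }
  if (is.matrix(images)) return(images)
  stop("unsupported image container")
}

#' Write / read a stack of cross-sections as NIfTI plus a CSV manifest
#'
#' Images (and masks, when present on every slice) become 64x64xN NIfTI files;
#' the manifest CSV records subject_id, slice_index, arclength_mm and label.
#'
#' @param sections list of [cross_section()]s.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Invisibly, named vector of paths written.
#' @export
write_section_stack <- function(sections, dir, prefix) {
  stopifnot(length(sections) > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(sections[[1]]$pixels)
  sp <- sections[[1]]$pixel_spacing_mm
  stack_of <- function(field, as01 = FALSE) {
    if (any(vapply(sections, function(s) is.null(s[[field]]), TRUE)))
      return(NULL)
    arr <- array(0, dim = c(n, n, length(sections)))
    for (i in seq_along(sections))
      arr[, , i] <- if (as01) sections[[i]][[field]] * 1 else sections[[i]][[field]]
    arr
  }
  paths <- c(images = file.path(dir, paste0(prefix, "_images.nii.gz")),
             manifest = file.path(dir, paste0(prefix, "_manifest.csv")))
  write_nifti_array(stack_of("pixels"), c(sp, sp, 1), paths["images"])
  for (field in c("lumen_mask", "thrombus_mask")) {
    arr <- stack_of(field, as01 = TRUE)
    if (!is.null(arr)) {
      p <- file.path(dir, paste0(prefix, "_", field, ".nii.gz"))
      write_nifti_array(arr, c(sp, sp, 1), p)
      paths[field] <- p
    }
  }
  manifest <- data.frame(
    subject_id = vapply(sections, `[[`, "", "subject_id"),
    slice_index = vapply(sections, `[[`, 1L, "slice_index"),
    arclength_mm = vapply(sections, `[[`, 1.0, "arclength_mm"),
    label = vapply(sections, `[[`, "", "label"))
  write.csv(manifest, paths["manifest"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' @rdname write_section_stack
#' @export
read_section_stack <- function(dir, prefix) {
  img <- read_nifti_array(file.path(dir, paste0(prefix, "_images.nii.gz")))
  manifest <- read.csv(file.path(dir, paste0(prefix, "_manifest.csv")),
                       stringsAsFactors = FALSE)
  masks <- list()
  for (field in c("lumen_mask", "thrombus_mask")) {
    p <- file.path(dir, paste0(prefix, "_", field, ".nii.gz"))
    if (file.exists(p)) masks[[field]] <- read_nifti_array(p)$data > 0.5
  }
  n <- dim(img$data)[3]
  sections <- vector("list", n)
  for (i in seq_len(n)) {
    sections[[i]] <- cross_section(
      pixels = img$data[, , i], pixel_spacing_mm = img$spacing[1],
      lumen_mask = if (!is.null(masks$lumen_mask)) masks$lumen_mask[, , i],
      thrombus_mask = if (!is.null(masks$thrombus_mask)) masks$thrombus_mask[, , i],
      subject_id = manifest$subject_id[i],
      slice_index = manifest$slice_index[i],
      arclength_mm = manifest$arclength_mm[i],
      label = manifest$label[i])
  }
  sections
}
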