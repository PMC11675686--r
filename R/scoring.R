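#' Construct a latent-space partition
#'
#' The latent space is split into thrombus / no-thrombus subspaces by a
#' straight line at x = `x0` (x being the first latent component). `xmin` is
#' the extreme x among the reference cohort on the thrombus side; together they
#' define the per-slice thrombus score ts = (x - x0) / (xmin - x0).
#'
#' @param x0 boundary x-coordinate (latent units).
#' @param xmin reference extreme on the thrombus side, or `NA` when degenerate.
#' @param orientation `"thrombus_below_x0"` (thrombus at x < x0, the reference
#'   convention) or `"thrombus_above_x0"`.
#' @param degenerate `TRUE` when no reference point fell on the thrombus side;
#'   a degenerate partition scores every point 0.
#' @param fingerprint optional fingerprint of the model whose latent space this
#'   partition belongs to.
#' @param axis which latent component plays the role of x (default 1, the
#'   convention used throughout; latent axes carry no intrinsic meaning, so a
#'   partition fitted on another axis records it here).
#' @return An object of class `latent_partition`.
#' @export
latent_partition <- function(x0, xmin = NA_real_,
                             orientation = c("thrombus_below_x0",
                                             "thrombus_above_x0"),
                             degenerate = FALSE, fingerprint = NULL,
                             axis = 1L) {
  orientation <- match.arg(orientation)
  if (!is.finite(x0)) stop("x0 must be finite")
  if (degenerate && !is.na(xmin))
    stop("a degenerate partition has no xmin")
  if (!degenerate) {
    if (!is.finite(xmin)) stop("xmin must be finite unless degenerate")
    if (orientation == "thrombus_below_x0" && !(xmin < x0))
      stop("with thrombus_below_x0, xmin must be < x0")
    if (orientation == "thrombus_above_x0" && !(xmin > x0))
      stop("with thrombus_above_x0, xmin must be > x0")
  }
  if (!is.numeric(axis) || axis < 1) stop("axis must be a positive integer")
  structure(list(x0 = as.numeric(x0), xmin = as.numeric(xmin),
                 orientation = orientation, degenerate = isTRUE(degenerate),
                 fingerprint = fingerprint, axis = as.integer(axis)),
            class = "latent_partition")
}

#' @export
print.latent_partition <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<latent_partition> degenerate (x0 = %.4g, %s)\n",
                x$x0, x$orientation))
  } else {
    cat(sprintf("<latent_partition> x0 = %.4g, xmin = %.4g, %s\n",
                x$x0, x$xmin, x$orientation))
  }
  invisible(x)
}

#' Embed a dataset into the latent space
#'
#' Encodes every image and returns the posterior means (the deterministic
#' latent coordinates used for classification and scoring), order-preserving.
#'
#' @param params a trained `vae_params`.
#' @param images images as in [vae_train()].
#' @return N x latent_dim matrix of posterior means, with the log-variances in
#'   `attr(, "logvar")`.
#' @export
embed_dataset <- function(params, images) {
  if (is.list(images) && length(images) == 0) stop("empty image list")
  enc <- vae_encode(params, images)
  structure(enc$mu, logvar = enc$logvar)
}

# Deterministic 1D 2-means: centers initialized at the data extremes, Lloyd
# iterations to convergence, ties assigned to the lower center.
kmeans1d_two <- function(x, max_iter = 200L) {
  c_lo <- min(x)
  c_hi <- max(x)
  assign_lo <- rep(TRUE, length(x))
  for (it in seq_len(max_iter)) {
    d_lo <- abs(x - c_lo)
    d_hi <- abs(x - c_hi)
    new_assign <- d_lo <= d_hi  # tie -> lower center
    if (identical(new_assign, assign_lo) && it > 1) break
    assign_lo <- new_assign
    if (any(assign_lo)) c_lo <- mean(x[assign_lo])
    if (any(!assign_lo)) c_hi <- mean(x[!assign_lo])
    if (c_lo > c_hi) { tmp <- c_lo; c_lo <- c_hi; c_hi <- tmp }
  }
  list(centers = c(c_lo, c_hi), lower = assign_lo)
}

#' Fit a latent partition from embedded points
#'
#' In `"fixed"` mode the boundary is placed at `x0_fixed` (default -0.8, the
#' reference convention) with thrombus below the boundary. In `"auto"` mode a
#' deterministic 1D 2-means on the x-coordinates places the boundary at the
#' midpoint of the two cluster centers; the thrombus side is the cluster whose
#' members have the larger mean segmented foreground area (thrombosed aortas
#' are larger), falling back to thrombus-below when no areas are supplied.
#' `xmin` is the extreme x-coordinate on the thrombus side among the supplied
#' points; if no point lies on that side the partition is degenerate.
#'
#' @param points N x latent_dim matrix (e.g. from [embed_dataset()]) or a
#'   numeric vector of x-coordinates.
#' @param mode `"auto"` or `"fixed"`.
#' @param x0_fixed boundary used in fixed mode.
#' @param foreground_area optional numeric vector (one value per point) of
#'   segmented foreground pixel counts, used by the auto orientation rule.
#' @param orientation optional manual override of the orientation.
#' @param fingerprint optional model fingerprint stored on the partition.
#' @param axis latent component to partition on: an integer (default 1, the
#'   x-axis convention) or `"best"` (auto mode only) to pick the axis whose
#'   2-means clustering separates best, measured by the between-center gap
#'   over the pooled within-cluster spread. Latent axes are exchangeable
#'   training artifacts, so the discriminative direction can land on either.
#' @return A [latent_partition()].
#' @export
fit_partition <- function(points, mode = c("auto", "fixed"), x0_fixed = -0.8,
                          foreground_area = NULL, orientation = NULL,
                          fingerprint = NULL, axis = 1L) {
  mode <- match.arg(mode)
  if (!is.matrix(points)) points <- matrix(as.numeric(points), ncol = 1)
  if (nrow(points) == 0) stop("empty point set")
  if (any(!is.finite(points))) stop("non-finite latent coordinates")
  if (identical(axis, "best")) {
    if (mode != "auto") stop("axis = 'best' requires mode = 'auto'")
    sep <- vapply(seq_len(ncol(points)), function(j) {
      km <- kmeans1d_two(points[, j])
      within <- c(points[km$lower, j] - km$centers[1],
                  points[!km$lower, j] - km$centers[2])
      (km$centers[2] - km$centers[1]) / (sqrt(mean(within^2)) + 1e-12)
    }, 1.0)
    axis <- which.max(sep)  # ties break toward the lower axis index
  }
  axis <- as.integer(axis)
  if (axis < 1 || axis > ncol(points)) stop("axis out of range")
  x <- points[, axis]

  if (mode == "fixed") {
    x0 <- x0_fixed
    orient <- orientation %||% "thrombus_below_x0"
  } else {
    km <- kmeans1d_two(x)
    x0 <- mean(km$centers)
    if (!is.null(orientation)) {
      orient <- orientation
    } else if (!is.null(foreground_area)) {
      if (length(foreground_area) != length(x))
        stop("foreground_area must align with points")
      a_lo <- mean(foreground_area[km$lower])
      a_hi <- mean(foreground_area[!km$lower])
      orient <- if (isTRUE(a_lo >= a_hi) || all(km$lower))
        "thrombus_below_x0" else "thrombus_above_x0"
    } else {
      orient <- "thrombus_below_x0"
    }
  }

  side <- if (orient == "thrombus_below_x0") x < x0 else x > x0
  if (!any(side)) {
    return(latent_partition(x0, NA_real_, orient, degenerate = TRUE,
                            fingerprint = fingerprint, axis = axis))
  }
  xmin <- if (orient == "thrombus_below_x0") min(x[side]) else max(x[side])
  latent_partition(x0, xmin, orient, degenerate = FALSE,
                   fingerprint = fingerprint, axis = axis)
}

#' Per-slice thrombus score
#'
#' For a latent x inside the thrombus subspace, ts = (x - x0) / (xmin - x0),
#' clamped into \[0, 1\] (clamping only affects new points beyond the reference
#' extreme); outside the subspace, and for degenerate partitions, ts = 0.
#'
#' @param points latent coordinates: an N x latent_dim matrix, or a numeric
#'   vector of x-coordinates.
#' @param partition a [latent_partition()].
#' @return Numeric vector of scores in \[0, 1\].
#' @export
thrombus_score <- function(points, partition) {
  stopifnot(inherits(partition, "latent_partition"))
  ax <- partition$axis %||% 1L
  x <- if (is.matrix(points)) points[, ax] else as.numeric(points)
  if (any(!is.finite(x))) stop("non-finite latent x-coordinate")
  ts <- numeric(length(x))
  if (partition$degenerate) return(ts)
  side <- if (partition$orientation == "thrombus_below_x0")
    x < partition$x0 else x > partition$x0
  ts[side] <- clamp01((x[side] - partition$x0) /
                      (partition$xmin - partition$x0))
  ts
}

#' Score every slice of a subject
#'
#' @param points N x latent_dim matrix of posterior means for one subject.
#' @param partition a [latent_partition()].
#' @param subject_id subject identifier.
#' @param slice_index integer indices (default 1..N).
#' @param arclength_mm optional arc-length positions.
#' @return data.frame with subject_id, slice_index, arclength_mm, x, y, ts.
#' @export
slice_scores <- function(points, partition, subject_id = "S1",
                         slice_index = NULL, arclength_mm = NULL) {
  x <- if (is.matrix(points)) points[, 1] else as.numeric(points)
  y <- if (is.matrix(points) && ncol(points) > 1) points[, 2] else NA_real_
  n <- length(x)
  data.frame(
    subject_id = subject_id,
    slice_index = slice_index %||% seq_len(n),
    arclength_mm = arclength_mm %||% NA_real_,
    x = x, y = y,
    ts = thrombus_score(points, partition))
}

#' Per-dataset (per-subject) thrombus score
#'
#' The dataset score is the arithmetic mean of the per-slice scores; it is
#' invariant to slice order.
#'
#' @param scores data.frame from [slice_scores()] (columns subject_id and ts),
#'   for a single subject.
#' @return An object of class `dataset_score`: list(subject_id, n_slices,
#'   mean_ts, per_slice).
#' @export
dataset_score <- function(scores) {
  if (!is.data.frame(scores) || nrow(scores) == 0)
    stop("empty score list")
  if (length(unique(scores$subject_id)) != 1)
    stop("dataset_score expects slices from a single subject")
  if (any(!is.finite(scores$ts)) || any(scores$ts < 0 | scores$ts > 1))
    stop("per-slice scores must lie in [0, 1]")
  structure(list(subject_id = scores$subject_id[1],
                 n_slices = nrow(scores),
                 mean_ts = mean(scores$ts),
                 per_slice = scores),
            class = "dataset_score")
}

#' @export
print.dataset_score <- function(x, ...) {
  cat(sprintf("<dataset_score> %s: mean ts = %.4f over %d slices\n",
              x$subject_id, x$mean_ts, x$n_slices))
  invisible(x)
}

#' Pseudo-color score track
#'
#' Maps per-slice scores to color-bin indices: bin = floor(ts * bins), capped
#' at bins - 1, so ts = 1 falls in the top bin.
#'
#' @param ts numeric vector of per-slice scores in \[0, 1\].
#' @param bins number of color bins (>= 2).
#' @return list with `bin` (integer vector, 0-based) and `legend` (data.frame
#'   mapping each bin to its \[lo, hi) score interval).
#' @export
score_track <- function(ts, bins = 10L) {
  if (length(ts) == 0) stop("empty score list")
  if (bins < 2) stop("bins must be >= 2")
  bin <- pmin(floor(ts * bins), bins - 1)
  legend <- data.frame(bin = 0:(bins - 1),
                       lo = (0:(bins - 1)) / bins,
                       hi = (1:bins) / bins)
  list(bin = as.integer(bin), legend = legend)
}

#' Render a score track as a PNG strip
#'
#' One colored column per slice, aligned with slice index, plus a color legend.
#'
#' @param ts per-slice scores in \[0, 1\].
#' @param path output PNG path.
#' @param bins number of color bins.
#' @param title plot title.
#' @export
plot_score_track <- function(ts, path, bins = 10L, title = "thrombus score") {
  trk <- score_track(ts, bins)
  cols <- grDevices::hcl.colors(bins, "YlOrRd", rev = TRUE)
  grDevices::png(path, width = max(480, length(ts) + 120), height = 160)
  on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mar = c(3, 1, 2, 8))
  graphics::image(x = seq_along(ts), y = 1, z = matrix(trk$bin, ncol = 1),
                  zlim = c(0, bins - 1), col = cols, axes = FALSE,
                  xlab = "", ylab = "", useRaster = TRUE, main = title)
  graphics::axis(1)
  graphics::mtext("slice index", side = 1, line = 2)
  graphics::legend("topright", inset = c(-0.18, 0), xpd = TRUE, bty = "n",
                   fill = cols,
                   legend = sprintf("[%.1f, %.1f)", trk$legend$lo,
                                    trk$legend$hi),
                   cex = 0.6)
  graphics::par(op)
  invisible(path)
}

#' Serialize / read a latent partition as JSON
#'
#' @param partition a [latent_partition()].
#' @param path JSON file path.
#' @export
write_partition_json <- function(partition, path) {
  stopifnot(inherits(partition, "latent_partition"))
  jsonlite::write_json(
    list(x0 = partition$x0,
         xmin = if (partition$degenerate) NULL else partition$xmin,
         orientation = partition$orientation,
         degenerate = partition$degenerate,
         axis = partition$axis,
         fingerprint = partition$fingerprint),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_partition_json
#' @export
read_partition_json <- function(path) {
  j <- jsonlite::read_json(path)
  latent_partition(x0 = j$x0,
                   xmin = if (isTRUE(j$degenerate)) NA_real_ else j$xmin,
                   orientation = j$orientation,
                   degenerate = isTRUE(j$degenerate),
                   fingerprint = j$fingerprint,
                   axis = j$axis %||% 1L)
}
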