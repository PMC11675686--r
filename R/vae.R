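#' Configuration for the convolutional variational autoencoder
#'
#' The canonical model encodes 64x64 images in \[0, 1\] into a 2D latent space:
#' two stride-2 convolutions, a small dense layer, and linear heads for the
#' posterior mean and log-variance; the decoder mirrors the encoder with
#' transpose convolutions and a sigmoid output. Training maximizes the ELBO:
#' pixel-summed reconstruction loss plus the closed-form KL divergence to a
#' standard-normal prior, averaged over the batch.
#'
#' @param latent_dim latent dimensionality; 2 is the canonical choice for this
#'   method (other values are accepted but flagged as non-canonical).
#' @param epochs number of training epochs (default 100).
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param conv_channels length-2 integer vector of encoder channel counts.
#' @param kernel_size odd convolution kernel size.
#' @param stride convolution stride; the architecture requires 2.
#' @param dense_units width of the dense bottleneck layer.
#' @param seed integer seed controlling weight initialization and training
#'   stochasticity (shuffling, reparameterization noise).
#' @param recon_loss `"bernoulli"` (pixel cross-entropy, the default for
#'   \[0, 1\] images) or `"gaussian"` (pixel squared error).
#' @return An object of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 2L, epochs = 100L, batch_size = 32L,
                       learning_rate = 1e-3, conv_channels = c(16L, 32L),
                       kernel_size = 3L, stride = 2L, dense_units = 16L,
                       seed = 42L, recon_loss = c("bernoulli", "gaussian")) {
  recon_loss <- match.arg(recon_loss)
  if (latent_dim < 1) stop("latent_dim must be >= 1")
  if (latent_dim != 2)
    message("latent_dim != 2 is non-canonical for this method")
  if (epochs < 1) stop("epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (length(conv_channels) != 2 || any(conv_channels < 1))
    stop("conv_channels must be two positive integers")
  if (stride != 2)
    stop("the 64 -> 32 -> 16 architecture requires stride = 2")
  if (kernel_size < 1 || kernel_size %% 2 == 0)
    stop("kernel_size must be odd (so 'same' padding reconstructs 64x64)")
  if (dense_units < 1) stop("dense_units must be >= 1")
  structure(list(
    latent_dim = as.integer(latent_dim),
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    learning_rate = as.numeric(learning_rate),
    conv_channels = as.integer(conv_channels),
    kernel_size = as.integer(kernel_size),
    stride = as.integer(stride),
    dense_units = as.integer(dense_units),
    seed = as.integer(seed),
    recon_loss = recon_loss
  ), class = "vae_config")
}

vae_fingerprint <- function(config) {
  sprintf("convvae2d/k%ds%d/c%d-%d/d%d/L%d/%s",
          config$kernel_size, config$stride,
          config$conv_channels[1], config$conv_channels[2],
          config$dense_units, config$latent_dim, config$recon_loss)
}

#' Initialize VAE parameters deterministically from the config seed
#'
#' He-style Gaussian initialization for ReLU layers, scaled-down Gaussian for
#' the linear heads, zero biases. The same config (including seed) always
#' yields identical weights.
#'
#' @param config a [vae_config()].
#' @return An object of class `vae_params` holding the weight list, the config,
#'   an architecture fingerprint, and (after training) the loss history.
#' @export
vae_init <- function(config = vae_config()) {
  stopifnot(inherits(config, "vae_config"))
  set.seed(config$seed)
  k <- config$kernel_size
  c1 <- config$conv_channels[1]
  c2 <- config$conv_channels[2]
  d <- config$dense_units
  L <- config$latent_dim
  flat <- c2 * 16 * 16
  gm <- function(nr, nc, sd) matrix(rnorm(nr * nc, 0, sd), nr, nc)
  w <- list(
    conv1_W = gm(c1, k * k, sqrt(2 / (k * k))),       conv1_b = numeric(c1),
    conv2_W = gm(c2, c1 * k * k, sqrt(2 / (c1 * k * k))), conv2_b = numeric(c2),
    enc_fc_W = gm(d, flat, sqrt(2 / flat)),           enc_fc_b = numeric(d),
    mu_W = gm(L, d, sqrt(1 / d)),                     mu_b = numeric(L),
    logvar_W = gm(L, d, sqrt(1 / d)),                 logvar_b = numeric(L),
    dec_fc1_W = gm(d, L, sqrt(2 / L)),                dec_fc1_b = numeric(d),
    dec_fc2_W = gm(flat, d, sqrt(2 / d)),             dec_fc2_b = numeric(flat),
    tconv1_W = gm(c2, c1 * k * k, sqrt(2 / c2)),      tconv1_b = numeric(c1),
    tconv2_W = gm(c1, k * k, sqrt(1 / c1)),           tconv2_b = numeric(1)
  )
  structure(list(weights = w, config = config,
                 fingerprint = vae_fingerprint(config),
                 loss_history = NULL, trained = FALSE),
            class = "vae_params")
}

#' @export
print.vae_params <- function(x, ...) {
  cat(sprintf("<vae_params> %s seed=%d %s\n", x$fingerprint, x$config$seed,
              if (x$trained) sprintf("trained %d epochs (final loss %.2f)",
                                     nrow(x$loss_history),
                                     x$loss_history$total[nrow(x$loss_history)])
              else "untrained"))
  invisible(x)
}

cfg_for_cpp <- function(config) {
  list(kernel_size = config$kernel_size,
       conv_channels = config$conv_channels,
       dense_units = config$dense_units,
       latent_dim = config$latent_dim,
       epochs = config$epochs,
       batch_size = config$batch_size,
       learning_rate = config$learning_rate,
       recon_loss = config$recon_loss)
}

check_image_matrix <- function(X) {
  if (nrow(X) != 64 * 64)
    stop("images must be 64 x 64 (got ", sqrt(nrow(X)), " pixels per side)")
  if (min(X) < -1e-9 || max(X) > 1 + 1e-9)
    stop("image intensities must lie in [0, 1]; apply normalize_intensity()")
  X
}

#' Train the VAE
#'
#' Runs minibatch Adam for `config$epochs` epochs. All stochastic draws
#' (shuffling and reparameterization noise) come from R's RNG seeded with
#' `config$seed`, so the same (images, config) pair reproduces the training
#' run, including the loss history, bit for bit on the same platform.
#'
#' @param images training images: list of [cross_section()]s, 64x64xN array,
#'   or 4096 x N matrix, values in \[0, 1\].
#' @param config a [vae_config()].
#' @param params optional initialized/pre-trained `vae_params` to continue
#'   from; its config takes precedence.
#' @return A trained `vae_params` whose `loss_history` data.frame has one row
#'   per epoch with columns epoch, total, recon, kl (per-image sums averaged
#'   over the epoch).
#' @export
vae_train <- function(images, config = vae_config(), params = NULL) {
  X <- check_image_matrix(images_to_matrix(images))
  if (ncol(X) == 0) stop("empty training set")
  if (is.null(params)) {
    stopifnot(inherits(config, "vae_config"))
    params <- vae_init(config)
  } else {
    stopifnot(inherits(params, "vae_params"))
    config <- params$config
  }
  set.seed(config$seed + 1L)  # training stream, distinct from init stream
  res <- vae_train_cpp(X, params$weights, cfg_for_cpp(config))
  params$weights <- res$weights
  params$loss_history <- data.frame(
    epoch = seq_len(config$epochs),
    total = res$loss_total, recon = res$loss_recon, kl = res$loss_kl)
  params$trained <- TRUE
  params
}

#' Encode images to latent posterior parameters
#'
#' Deterministic: returns the posterior mean and log-variance (no sampling).
#'
#' @param params a `vae_params`.
#' @param images images as in [vae_train()] (a single `cross_section` or
#'   64x64 matrix is also accepted).
#' @return list with `mu` and `logvar`, each an N x latent_dim matrix,
#'   row-aligned with the input order.
#' @export
vae_encode <- function(params, images) {
  stopifnot(inherits(params, "vae_params"))
  if (inherits(images, "cross_section")) images <- list(images)
  if (is.matrix(images) && all(dim(images) == c(64, 64)))
    images <- array(images, c(64, 64, 1))
  X <- check_image_matrix(images_to_matrix(images))
  res <- vae_encode_cpp(X, params$weights, cfg_for_cpp(params$config))
  list(mu = t(res$mu), logvar = t(res$logvar))
}

#' Decode latent points into images
#'
#' @param params a `vae_params`.
#' @param z a latent point (length `latent_dim` vector) or an N x latent_dim
#'   matrix.
#' @return A 64x64 matrix for a single point, else a 64x64xN array; values are
#'   sigmoid outputs in \[0, 1\].
#' @export
vae_decode <- function(params, z) {
  stopifnot(inherits(params, "vae_params"))
  L <- params$config$latent_dim
  if (is.vector(z)) {
    if (length(z) != L) stop("z must have length ", L)
    z <- matrix(z, 1, L)
  }
  if (ncol(z) != L) stop("z must have ", L, " columns")
  if (any(!is.finite(z))) stop("z must be finite")
  out <- vae_decode_cpp(t(z), params$weights, cfg_for_cpp(params$config))
  if (ncol(out) == 1) return(matrix(out[, 1], 64, 64))
  array(out, c(64, 64, ncol(out)))
}

#' Reparameterization: z = mu + exp(logvar / 2) * noise
#'
#' @param mu,logvar posterior mean and log-variance (equal-length vectors).
#' @param noise standard-normal draws of the same length.
#' @return The latent sample z.
#' @export
reparameterize <- function(mu, logvar, noise) {
  stopifnot(length(mu) == length(logvar), length(mu) == length(noise))
  mu + exp(logvar / 2) * noise
}

#' Evidence lower bound loss for one image
#'
#' `kl = -1/2 * sum(1 + logvar - mu^2 - exp(logvar))` (closed form against the
#' standard-normal prior, always nonnegative); the reconstruction term is the
#' pixel-summed Bernoulli cross-entropy or squared error.
#'
#' @param image,reconstruction matrices of equal shape; `image` in \[0, 1\].
#' @param mu,logvar latent posterior parameters.
#' @param recon_loss `"bernoulli"` or `"gaussian"`.
#' @return list(total, recon, kl).
#' @export
elbo_loss <- function(image, reconstruction, mu, logvar,
                      recon_loss = c("bernoulli", "gaussian")) {
  recon_loss <- match.arg(recon_loss)
  if (any(!is.finite(image)) || any(!is.finite(reconstruction)) ||
      any(!is.finite(mu)) || any(!is.finite(logvar)))
    stop("non-finite inputs to elbo_loss")
  if (!identical(dim(image), dim(reconstruction)))
    stop("image and reconstruction shapes differ")
  kl <- -0.5 * sum(1 + logvar - mu^2 - exp(logvar))
  if (recon_loss == "bernoulli") {
    p <- clamp01(reconstruction, 1e-7, 1 - 1e-7)
    recon <- -sum(image * log(p) + (1 - image) * log(1 - p))
  } else {
    recon <- sum((image - reconstruction)^2)
  }
  list(total = recon + kl, recon = recon, kl = kl)
}

#' Decoder grid panel over the latent square
#'
#' Decodes an n x n uniform grid over \[lo, hi\]^2 (the first two latent axes)
#' into a single montage. Tile (i, j) decodes latent (x = gx[j], y = gy[i])
#' with gx and gy both `seq(lo, hi, length.out = n)`: x increases rightward
#' across columns, y increases downward across rows.
#'
#' @param params a trained `vae_params`.
#' @param lo,hi latent range (defaults -3, 3).
#' @param n grid resolution per axis (>= 2).
#' @return An object of class `latent_panel`: list with `montage`
#'   ((n*64) x (n*64) matrix), `grid_x`, `grid_y`, and `tiles` (64x64xn^2
#'   array in row-major tile order).
#' @export
latent_grid_panel <- function(params, lo = -3, hi = 3, n = 15L) {
  stopifnot(inherits(params, "vae_params"))
  if (!(lo < hi)) stop("lo must be < hi")
  if (n < 2) stop("n must be >= 2")
  g <- seq(lo, hi, length.out = n)
  # z row (i-1)*n + j holds tile (row i, column j): latent (x = g[j], y = g[i])
  z <- cbind(x = rep(g, times = n), y = rep(g, each = n))
  L <- params$config$latent_dim
  if (L > 2) z <- cbind(z, matrix(0, nrow(z), L - 2))
  imgs <- vae_decode(params, z)
  montage <- matrix(0, n * 64, n * 64)
  tiles <- array(0, c(64, 64, n * n))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      t_idx <- (i - 1) * n + j
      img <- imgs[, , t_idx]
      tiles[, , t_idx] <- img
      montage[(i - 1) * 64 + 1:64, (j - 1) * 64 + 1:64] <- img
    }
  }
  structure(list(montage = montage, grid_x = g, grid_y = g, n = n,
                 tiles = tiles),
            class = "latent_panel")
}

#' Export a latent grid panel (or any image matrix) as PNG
#'
#' @param panel a `latent_panel` or a numeric matrix in \[0, 1\].
#' @param path output PNG path.
#' @export
export_panel_png <- function(panel, path) {
  m <- if (inherits(panel, "latent_panel")) panel$montage else panel
  grDevices::png(path, width = ncol(m), height = nrow(m))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::image(t(m[nrow(m):1, ]), col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, useRaster = TRUE)
  invisible(path)
}

#' Save / load a VAE checkpoint
#'
#' The checkpoint embeds the weights, config, seed and architecture
#' fingerprint; loading verifies the fingerprint matches the stored config.
#'
#' @param params a `vae_params`.
#' @param path checkpoint path (RDS).
#' @export
save_vae <- function(params, path) {
  stopifnot(inherits(params, "vae_params"))
  saveRDS(params, path)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  params <- readRDS(path)
  if (!inherits(params, "vae_params")) stop("not a VAE checkpoint: ", path)
  if (!identical(params$fingerprint, vae_fingerprint(params$config)))
    stop("checkpoint fingerprint does not match its config")
  params
}
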