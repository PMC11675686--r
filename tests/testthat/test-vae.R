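test_that("KL term matches its closed form", {
  l0 <- elbo_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 2), c(0, 0), c(0, 0))
  expect_equal(l0$kl, 0)
  l1 <- elbo_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 2), c(1, 0), c(0, 0))
  expect_equal(l1$kl, 0.5)
  l2 <- elbo_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 2), c(0, 0), c(log(2), 0))
  expect_equal(l2$kl, (1 - log(2)) / 2)
})

test_that("KL is nonnegative over a random sweep, zero only at the prior", {
  set.seed(51)
  mu <- matrix(rnorm(2e4, sd = 3), ncol = 2)
  lv <- matrix(rnorm(2e4, sd = 2), ncol = 2)
  kl <- -0.5 * rowSums(1 + lv - mu^2 - exp(lv))
  expect_true(all(kl >= 0))
  # zero iff mu = 0, logvar = 0: anything bounded away from it is positive
  off <- rowSums(abs(mu)) + rowSums(abs(lv)) > 0.1
  expect_true(all(kl[off] > 0))
})

test_that("bernoulli and gaussian reconstruction terms behave as documented", {
  x <- matrix(c(0, 1, 0.5, 1), 2, 2)
  p <- matrix(c(0.1, 0.9, 0.5, 0.8), 2, 2)
  lb <- elbo_loss(x, p, c(0, 0), c(0, 0), "bernoulli")
  expect_equal(lb$recon,
               -sum(x * log(p) + (1 - x) * log(1 - p)))
  lg <- elbo_loss(x, p, c(0, 0), c(0, 0), "gaussian")
  expect_equal(lg$recon, sum((x - p)^2))
  expect_equal(lb$total, lb$recon + lb$kl)
  expect_error(elbo_loss(x, p[1, , drop = FALSE], c(0, 0), c(0, 0)),
               "shapes")
  expect_error(elbo_loss(x * NA, p, c(0, 0), c(0, 0)), "non-finite")
})

test_that("reparameterization is mu + exp(logvar/2) * noise", {
  expect_equal(reparameterize(c(1, 2), c(0, 0), c(0, 0)), c(1, 2))
  expect_equal(reparameterize(c(1, 2), c(0, 0), c(1, 1)), c(2, 3))
  expect_equal(reparameterize(c(0, 5), c(2 * log(2), 0), c(1, 0)), c(2, 5))
})

test_that("initialization is deterministic and encode/decode obey contracts", {
  cfg <- vae_config(epochs = 1, seed = 33)
  a <- vae_init(cfg)
  b <- vae_init(cfg)
  expect_identical(a$weights, b$weights)
  expect_identical(a$fingerprint, b$fingerprint)

  img <- matrix(runif(64 * 64), 64, 64)
  enc <- vae_encode(a, img)
  expect_equal(dim(enc$mu), c(1, 2))
  expect_equal(dim(enc$logvar), c(1, 2))
  expect_true(all(is.finite(enc$mu)))
  expect_identical(enc, vae_encode(a, img))  # deterministic, no sampling

  dec <- vae_decode(a, c(0, 0))
  expect_equal(dim(dec), c(64, 64))
  expect_true(all(dec >= 0 & dec <= 1))
  expect_identical(dec, vae_decode(a, c(0, 0)))
  expect_error(vae_encode(a, matrix(0.5, 32, 32)), "64")
  expect_error(vae_decode(a, c(0, 0, 0)), "length")
})

test_that("batch encoding equals encoding images singly", {
  fix <- trained_fixture()
  imgs <- fix$images[c(1, 50, 200)]
  batch <- vae_encode(fix$model, imgs)
  for (i in seq_along(imgs)) {
    single <- vae_encode(fix$model, imgs[[i]])
    expect_equal(batch$mu[i, ], single$mu[1, ], tolerance = 1e-6)
    expect_equal(batch$logvar[i, ], single$logvar[1, ], tolerance = 1e-6)
  }
})

test_that("training records one loss per epoch, improves, and is reproducible", {
  coh <- masked_cohort(c(THROMBOSED_FL = 24, NO_FL = 24), seed = 3)
  cfg <- vae_config(epochs = 6, seed = 21)
  p1 <- vae_train(coh$images, cfg)
  expect_equal(nrow(p1$loss_history), 6)
  expect_lt(p1$loss_history$total[6], p1$loss_history$total[1])
  expect_true(all(p1$loss_history$kl >= 0))
  p2 <- vae_train(coh$images, cfg)
  expect_identical(p1$loss_history, p2$loss_history)
  expect_identical(p1$weights, p2$weights)
  expect_error(vae_train(list(), cfg), "empty")
})

test_that("a trained model reconstructs far better than an untrained one", {
  fix <- trained_fixture()
  held <- masked_cohort(c(THROMBOSED_FL = 10, NO_FL = 10), seed = 99)$images
  X <- images_to_matrix(held)
  recon_err <- function(params) {
    mu <- vae_encode(params, held)$mu
    dec <- vae_decode(params, mu)
    mean(abs(matrix(dec, nrow = 64 * 64) - X))
  }
  untrained <- vae_init(fix$model$config)
  expect_lt(recon_err(fix$model), 0.5 * recon_err(untrained))
})

test_that("trained latent space separates thrombosed from no-FL slices", {
  fix <- trained_fixture()
  mu <- embed_dataset(fix$model, fix$images)
  thr <- fix$labels %in% c("THROMBOSED_FL", "PARTIAL_FL")
  areas <- vapply(fix$images, function(s) sum(s$pixels > 0), 1.0)
  part <- fit_partition(mu, mode = "auto", foreground_area = areas,
                        axis = "best")
  side <- if (part$orientation == "thrombus_below_x0")
    mu[, part$axis] < part$x0 else mu[, part$axis] > part$x0
  expect_gte(mean(side == thr), 0.9)
  # the two class means differ on the partition axis
  expect_gt(abs(mean(mu[thr, part$axis]) - mean(mu[!thr, part$axis])),
            4 * (sd(mu[thr, part$axis]) + sd(mu[!thr, part$axis])) / 10)
})

test_that("the prior keeps the latent embedding bounded near the origin", {
  fix <- trained_fixture()
  mu <- embed_dataset(fix$model, fix$images)
  # the KL term cannot pin the pooled mean to 0 against a 4096-pixel
  # reconstruction term, but it does keep the embedding within a few latent
  # units of the origin — the scale that makes the [-3, 3] panel meaningful
  expect_true(all(abs(colMeans(mu)) <= 3))
  expect_true(all(apply(mu, 2, stats::sd) <= 3))
  expect_true(all(is.finite(mu)))
})

test_that("the latent grid panel tiles the latent square as documented", {
  fix <- trained_fixture()
  panel <- latent_grid_panel(fix$model, n = 4)
  expect_equal(dim(panel$montage), c(4 * 64, 4 * 64))
  expect_equal(dim(panel$tiles)[3], 16)
  # corner tiles decode the corner latent points
  expect_equal(panel$tiles[, , 1], vae_decode(fix$model, c(-3, -3)),
               tolerance = 1e-12)
  expect_equal(panel$tiles[, , 4], vae_decode(fix$model, c(3, -3)),
               tolerance = 1e-12)
  expect_equal(panel$tiles[, , 13], vae_decode(fix$model, c(-3, 3)),
               tolerance = 1e-12)
  expect_equal(panel$tiles[, , 16], vae_decode(fix$model, c(3, 3)),
               tolerance = 1e-12)
  # a collapsed range yields near-identical tiles
  tiny <- latent_grid_panel(fix$model, lo = 0, hi = 1e-9, n = 2)
  expect_lt(max(abs(tiny$tiles[, , 1] - tiny$tiles[, , 4])), 1e-6)
  expect_error(latent_grid_panel(fix$model, lo = 1, hi = 0), "lo")
})

test_that("checkpoints round-trip with their fingerprint verified", {
  fix <- trained_fixture()
  path <- withr::local_tempfile(fileext = ".rds")
  save_vae(fix$model, path)
  back <- load_vae(path)
  expect_identical(back$weights, fix$model$weights)
  expect_identical(back$fingerprint, fix$model$fingerprint)
  corrupt <- fix$model
  corrupt$fingerprint <- "other-architecture"
  saveRDS(corrupt, path)
  expect_error(load_vae(path), "fingerprint")
})
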