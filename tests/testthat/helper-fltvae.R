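# Shared fixtures. Everything is generated in code; the trained model used by
# several files is memoized so the suite trains it once.

test_spec <- function(...) phantom_spec(...)

# Bimodal cohort of segmented (masked + centered) slices, as the VAE consumes
# them: clearly thrombosed dissections vs no-FL controls, plus a few partials.
masked_cohort <- function(counts = c(THROMBOSED_FL = 100, PARTIAL_FL = 30,
                                     NO_FL = 130),
                          seed = 7) {
  coh <- make_phantom_cohort(test_spec(), counts, seed = seed)
  list(images = lapply(coh$slices, apply_mask_and_center),
       labels = coh$labels$label)
}

.fixture_env <- new.env(parent = emptyenv())

# One moderately trained model shared across test files (60 epochs on a
# 260-slice bimodal cohort is enough for clear latent separation).
trained_fixture <- function() {
  if (is.null(.fixture_env$model)) {
    coh <- masked_cohort()
    cfg <- vae_config(epochs = 60L, seed = 11L)
    .fixture_env$model <- vae_train(coh$images, cfg)
    .fixture_env$cohort <- coh
  }
  list(model = .fixture_env$model,
       images = .fixture_env$cohort$images,
       labels = .fixture_env$cohort$labels)
}

# tiny pipeline config for orchestration tests
tiny_run_config <- function(dir, seed = 5L) {
  cfg <- default_run_config()
  cfg$output_dir <- dir
  cfg$phantom$n_thrombosed_subjects <- 1L
  cfg$phantom$n_control_subjects <- 1L
  cfg$phantom$slices_per_subject <- 30L
  cfg$vae$epochs <- 4L
  cfg$seed <- as.integer(seed)
  cfg
}
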