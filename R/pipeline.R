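#' Default pipeline configuration
#'
#' Returns the full configuration tree with package defaults: a six-subject
#' synthetic study (three dissected subjects with mixed thrombosed / partial /
#' patent / no-FL segments, three controls without a false lumen, ~200 slices
#' each), 64x64 reslicing, 100-epoch VAE training, and auto-fitted latent
#' partition with the fixed-mode boundary defaulting to -0.8.
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    output_dir = "fltvae_run",
    log_level = "info",
    phantom = list(
      n_thrombosed_subjects = 3L,
      n_control_subjects = 3L,
      slices_per_subject = 200L,
      voxel_spacing_mm = c(0.7, 0.7, 1.0),
      tl_radius_mm = c(8, 14),
      fl_radius_mm = c(6, 12),
      septum_thickness_mm = 1.5,
      thrombus_fraction = c(0.9, 1.0),
      intensity_lumen = c(0.85, 0.95),
      intensity_thrombus = c(0.35, 0.50),
      intensity_background = c(0.15, 0.30),
      noise_sd = 0.03,
      curvature_amplitude_mm = 8
    ),
    reslice = list(
      step_mm = 1.0,
      fov_mm = 44.8,
      grid_n = 64L
    ),
    vae = list(
      latent_dim = 2L,
      epochs = 100L,
      batch_size = 32L,
      learning_rate = 1e-3,
      conv_channels = c(16L, 32L),
      kernel_size = 3L,
      dense_units = 16L,
      recon_loss = "bernoulli"
    ),
    scoring = list(
      mode = "auto",
      x0 = -0.8,
      axis = "best",
      colormap_bins = 10L
    )
  ), class = "run_config")
}

config_types <- function() {
  list(
    seed = "integer", output_dir = "character", log_level = "character",
    phantom = list(
      n_thrombosed_subjects = "integer", n_control_subjects = "integer",
      slices_per_subject = "integer", voxel_spacing_mm = "numeric",
      tl_radius_mm = "numeric", fl_radius_mm = "numeric",
      septum_thickness_mm = "numeric", thrombus_fraction = "numeric",
      intensity_lumen = "numeric", intensity_thrombus = "numeric",
      intensity_background = "numeric", noise_sd = "numeric",
      curvature_amplitude_mm = "numeric"),
    reslice = list(step_mm = "numeric", fov_mm = "numeric",
                   grid_n = "integer"),
    vae = list(latent_dim = "integer", epochs = "integer",
               batch_size = "integer", learning_rate = "numeric",
               conv_channels = "integer", kernel_size = "integer",
               dense_units = "integer", recon_loss = "character"),
    scoring = list(mode = "character", x0 = "numeric", axis = "axis",
                   colormap_bins = "integer")
  )
}

check_config_node <- function(user, types, path = "") {
  unknown <- setdiff(names(user), names(types))
  if (length(unknown) > 0)
    stop("unknown config key(s): ",
         paste0(if (nzchar(path)) paste0(path, ".") else "", unknown,
                collapse = ", "))
  for (nm in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (is.list(types[[nm]])) {
      if (!is.list(user[[nm]]))
        stop(sprintf("config key %s must be a section", full))
      check_config_node(user[[nm]], types[[nm]], full)
    } else {
      want <- types[[nm]]
      val <- user[[nm]]
      ok <- switch(want,
        integer = is.numeric(val) && all(is.finite(val)) &&
                  all(abs(val - round(val)) < 1e-9),
        numeric = is.numeric(val) && all(is.finite(val)),
        character = is.character(val),
        axis = identical(val, "best") ||
               (is.numeric(val) && length(val) == 1 && val >= 1))
      if (!ok)
        stop(sprintf("config key %s: expected %s", full, want))
    }
  }
  invisible(TRUE)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]]))
      merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

#' Load and validate a pipeline configuration from YAML
#'
#' Unknown keys are rejected by name; missing keys fall back to
#' [default_run_config()] (so a minimal file inherits epochs = 100, a 64-pixel
#' grid, and boundary x0 = -0.8).
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  check_config_node(user, config_types())
  cfg <- merge_config(default_run_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (!cfg$log_level %in% c("debug", "info", "warn", "error"))
    stop("log_level must be one of debug, info, warn, error")
  if (!cfg$scoring$mode %in% c("auto", "fixed"))
    stop("scoring.mode must be 'auto' or 'fixed'")
  # constructors validate the rest
  do.call(phantom_spec, cfg$phantom[setdiff(names(cfg$phantom),
    c("n_thrombosed_subjects", "n_control_subjects", "slices_per_subject"))])
  invisible(cfg)
}

phantom_spec_from_config <- function(cfg) {
  do.call(phantom_spec, cfg$phantom[setdiff(names(cfg$phantom),
    c("n_thrombosed_subjects", "n_control_subjects", "slices_per_subject"))])
}

vae_config_from_config <- function(cfg, seed) {
  do.call(vae_config, c(cfg$vae, list(seed = seed)))
}

# One seed fans out to per-stage seeds via a stage-name hash, so adding or
# reordering stages does not silently shift another stage's draws.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) * 1009
  # headroom below 2^31 so small per-subject offsets never overflow R integers
  as.integer((as.numeric(seed) + h) %% 2147000000)
}

pipeline_log <- function(cfg, level, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[cfg$log_level]])
    message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    toupper(level), sprintf(fmt, ...)))
}

# Label blocks along a dissected subject's aorta: a no-FL proximal segment,
# then thrombosed, partial and patent FL segments, then a no-FL distal tail.
thrombosed_subject_labels <- function(n) {
  blocks <- c(NO_FL = 0.25, THROMBOSED_FL = 0.35, PARTIAL_FL = 0.15,
              PATENT_FL = 0.15, NO_FL = 0.10)
  counts <- floor(blocks * n)
  counts[length(counts)] <- counts[length(counts)] + (n - sum(counts))
  rep(names(blocks), times = counts)
}

PIPELINE_STAGES <- c("simulate", "reslice", "train", "score", "report")

#' Run the analysis pipeline
#'
#' Runs the requested stages against `config$output_dir`. Each stage reads its
#' inputs from disk (so stages are independently re-runnable) and writes its
#' documented outputs plus entries in a run manifest. Rerunning with identical
#' config and seed reproduces the per-slice score CSVs bit-identically.
#'
#' Stages: `simulate` (phantom volumes as NIfTI + centerline text + labels),
#' `reslice` (64x64 masked, centered section stacks + manifests), `train`
#' (VAE checkpoint + loss-history CSV), `score` (per-slice and per-subject
#' score CSVs + partition JSON), `report` (score-track PNGs + latent panel).
#'
#' @param config a `run_config` from [load_run_config()] or
#'   [default_run_config()].
#' @param stages subset of `c("simulate", "reslice", "train", "score",
#'   "report")`.
#' @return Invisibly, the run manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  spec <- phantom_spec_from_config(config)
  n_thr <- config$phantom$n_thrombosed_subjects
  n_ctl <- config$phantom$n_control_subjects
  subjects <- c(if (n_thr > 0) sprintf("T%02d", seq_len(n_thr)),
                if (n_ctl > 0) sprintf("C%02d", seq_len(n_ctl)))
  manifest <- list(seed = config$seed, stages = list(), files = character(0))
  add_files <- function(stage, inputs, outputs, t0) {
    manifest$stages[[stage]] <<- list(
      inputs = unname(inputs), outputs = unname(outputs),
      duration_s = round(as.numeric(Sys.time()) - t0, 3))
    manifest$files <<- c(manifest$files, unname(outputs))
  }

  if ("simulate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    pipeline_log(config, "info", "simulate: %d subjects", length(subjects))
    outputs <- character(0)
    nsl <- config$phantom$slices_per_subject
    for (i in seq_along(subjects)) {
      sid <- subjects[i]
      labels <- if (startsWith(sid, "T")) thrombosed_subject_labels(nsl)
                else rep("NO_FL", nsl)
      vp <- make_phantom_volume(spec, nsl,
                                seed = stage_seed(config$seed, "simulate") + i,
                                labels = labels, subject_id = sid)
      outputs <- c(outputs, write_volume_phantom(vp, file.path(out, "volumes")))
    }
    add_files("simulate", character(0), outputs, t0)
  }

  if ("reslice" %in% stages) {
    t0 <- as.numeric(Sys.time())
    outputs <- character(0)
    inputs <- character(0)
    for (sid in subjects) {
      vdir <- file.path(out, "volumes")
      if (!file.exists(file.path(vdir, paste0(sid, "_intensities.nii.gz"))))
        stop("reslice: missing upstream volume for subject ", sid,
             " (expected ", file.path(vdir, paste0(sid, "_intensities.nii.gz")),
             "; run the simulate stage first)")
      vp <- read_volume_phantom(vdir, sid)
      inputs <- c(inputs, file.path(vdir, paste0(sid, "_intensities.nii.gz")))
      sections <- reslice_phantom(vp, step_mm = config$reslice$step_mm,
                                  fov_mm = config$reslice$fov_mm,
                                  grid_n = config$reslice$grid_n)
      pipeline_log(config, "info", "reslice: %s -> %d sections", sid,
                   length(sections))
      outputs <- c(outputs,
                   write_section_stack(sections, file.path(out, "sections"),
                                       sid))
    }
    add_files("reslice", inputs, outputs, t0)
  }

  if ("train" %in% stages) {
    t0 <- as.numeric(Sys.time())
    sections <- load_all_sections(out, subjects)
    vcfg <- vae_config_from_config(config, stage_seed(config$seed, "train"))
    pipeline_log(config, "info", "train: %d images, %d epochs",
                 length(sections), vcfg$epochs)
    params <- vae_train(sections, vcfg)
    ckpt <- file.path(out, "vae_checkpoint.rds")
    save_vae(params, ckpt)
    losscsv <- file.path(out, "loss_history.csv")
    write.csv(params$loss_history, losscsv, row.names = FALSE)
    add_files("train", character(0), c(ckpt, losscsv), t0)
  }

  if ("score" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ckpt <- file.path(out, "vae_checkpoint.rds")
    if (!file.exists(ckpt))
      stop("score: missing trained checkpoint ", ckpt,
           " (run the train stage first)")
    params <- load_vae(ckpt)
    sections <- load_all_sections(out, subjects)
    mu <- embed_dataset(params, sections)
    areas <- vapply(sections, function(s) sum(s$pixels > 0), 1.0)
    partition <- fit_partition(mu, mode = config$scoring$mode,
                               x0_fixed = config$scoring$x0,
                               foreground_area = areas,
                               fingerprint = params$fingerprint,
                               axis = config$scoring$axis)
    sid <- vapply(sections, `[[`, "", "subject_id")
    per_slice <- data.frame(
      subject_id = sid,
      slice_index = vapply(sections, `[[`, 1L, "slice_index"),
      arclength_mm = vapply(sections, `[[`, 1.0, "arclength_mm"),
      label = vapply(sections, `[[`, "", "label"),
      x = mu[, 1], y = mu[, 2],
      ts = thrombus_score(mu, partition))
    per_slice$bin <- score_track(per_slice$ts,
                                 config$scoring$colormap_bins)$bin
    per_subject <- do.call(rbind, lapply(split(per_slice, per_slice$subject_id),
      function(d) data.frame(subject_id = d$subject_id[1],
                             n_slices = nrow(d), mean_ts = mean(d$ts))))
    rownames(per_subject) <- NULL
    f1 <- file.path(out, "slice_scores.csv")
    f2 <- file.path(out, "subject_scores.csv")
    f3 <- file.path(out, "partition.json")
    write.csv(per_slice, f1, row.names = FALSE)
    write.csv(per_subject, f2, row.names = FALSE)
    write_partition_json(partition, f3)
    pipeline_log(config, "info", "score: partition x0=%.3f (%s)",
                 partition$x0, partition$orientation)
    add_files("score", ckpt, c(f1, f2, f3), t0)
  }

  if ("report" %in% stages) {
    t0 <- as.numeric(Sys.time())
    f1 <- file.path(out, "slice_scores.csv")
    if (!file.exists(f1))
      stop("report: missing per-slice scores ", f1,
           " (run the score stage first)")
    per_slice <- read.csv(f1, stringsAsFactors = FALSE)
    outputs <- character(0)
    for (sid in unique(per_slice$subject_id)) {
      d <- per_slice[per_slice$subject_id == sid, ]
      p <- file.path(out, sprintf("score_track_%s.png", sid))
      plot_score_track(d$ts[order(d$slice_index)], p,
                       bins = config$scoring$colormap_bins,
                       title = sprintf("%s  mean ts = %.3f", sid, mean(d$ts)))
      outputs <- c(outputs, p)
    }
    ckpt <- file.path(out, "vae_checkpoint.rds")
    if (file.exists(ckpt)) {
      panel <- latent_grid_panel(load_vae(ckpt), n = 9)
      p <- file.path(out, "latent_panel.png")
      export_panel_png(panel, p)
      outputs <- c(outputs, p)
    }
    add_files("report", f1, outputs, t0)
  }

  manifest$config_hash <- config_hash(config)
  mpath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest$files <- c(manifest$files, mpath)
  invisible(manifest)
}

load_all_sections <- function(out, subjects) {
  sections <- list()
  for (sid in subjects) {
    p <- file.path(out, "sections", paste0(sid, "_images.nii.gz"))
    if (!file.exists(p))
      stop("missing section stack for subject ", sid, " (expected ", p,
           "; run the reslice stage first)")
    sections <- c(sections, read_section_stack(file.path(out, "sections"), sid))
  }
  sections
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}
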