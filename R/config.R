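# Run configuration and pipeline plumbing: a strict, defaulted, hashed YAML
# configuration; a single global seed fanned out to per-stage seeds through
# a stable derivation; and an idempotent stage runner whose artifacts carry
# the configuration hash that produced them.

#' Derive a per-stage seed from the global seed
#'
#' Stable, documented derivation (global seed and a module tag), so any
#' stage can be re-run in isolation and reproduce its randomness. Always
#' below 2^31.
#'
#' @param seed global integer seed.
#' @param tag stage/module tag string.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, tag) {
  u <- utf8ToInt(tag)
  h <- sum(u * seq_along(u))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

default_config <- function() {
  list(seed = 1L,
       out_dir = "runs/default",
       phantom = list(n_subjects = 20L, volume_shape = c(95L, 128L, 128L),
                      n_regions_per_slice = 9L, age_range = c(63, 87),
                      visits_per_subject = c(4L, 5L), visit_spacing = 0.75,
                      diagnosis_probs = c(0.28, 0.04, 0.54, 0.14),
                      kappa = c(0.05, 0.08, 0.15, 0.30), tau = 75, s = 5,
                      noise_sd = 0.02),
       prep = list(n_slices = 95L, n_bins = 10L, width_factor = 1,
                   radii = 1L),
       model = list(image_size = 128L, latent_dim = 200L,
                    base_filters = 32L),
       pwf = list(b_reg = 1.25, b_vox = 1.25, b_b = 0.002, b_z = 0.05,
                  b_rec = 100, d_reg = 1, d_vox = 1, d_b = 1, d_z = 1,
                  d_rec = -1, rho = 0.99, v = 10),
       train = list(epochs = 300L, batch_size = 100L, alpha = 2e-4,
                    beta1 = 0.5, common_init_iters = 100L,
                    smooth_sigma = 1.5, smooth_half_width = 2L,
                    personalize_iters = 50L),
       sr = list(n_filters = 8L, patch = 8L, epochs = 40L),
       eval = list(threshold = 0.15))
}

merge_config <- function(base, upd, path = "") {
  for (k in names(upd)) {
    key <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop("unknown configuration key: ", key)
    if (is.list(base[[k]]) && !is.list(upd[[k]]))
      stop("configuration key ", key, " must be a section")
    base[[k]] <- if (is.list(base[[k]]))
      merge_config(base[[k]], upd[[k]], key) else upd[[k]]
  }
  base
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (an empty or missing-section file yields the full
#' defaults), applies overrides, rejects unknown keys, and attaches the
#' configuration hash.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides named list merged on top of the file (same key
#'   structure).
#' @return object of class `run_config` (a named list with attribute
#'   `hash`).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    y <- yaml::read_yaml(path)
    if (!is.null(y)) cfg <- merge_config(cfg, y)
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  structure(cfg, hash = config_hash(cfg), class = "run_config")
}

pipeline_stages <- c("phantom", "prep", "regressors", "train", "sr",
                     "simulate", "evaluate")

stage_paths <- function(config, stage) {
  list(artifact = file.path(config$out_dir, paste0(stage, ".rds")),
       marker = file.path(config$out_dir, paste0(stage, ".done")))
}

load_artifact <- function(config, stage) {
  p <- stage_paths(config, stage)
  if (!file.exists(p$artifact) || !file.exists(p$marker))
    stop("dependency error: stage '", stage, "' has not been run")
  marker <- yaml::read_yaml(p$marker)
  if (!identical(unname(tools::md5sum(p$artifact)), marker$artifact_md5))
    stop("dependency error: artifact for stage '", stage,
         "' does not match its recorded checksum")
  readRDS(p$artifact)
}

stage_current <- function(config, stage) {
  p <- stage_paths(config, stage)
  if (!file.exists(p$artifact) || !file.exists(p$marker)) return(FALSE)
  marker <- yaml::read_yaml(p$marker)
  if (!identical(marker$config_hash, attr(config, "hash"))) return(FALSE)
  if (!identical(unname(tools::md5sum(p$artifact)), marker$artifact_md5))
    stop("dependency error: artifact for stage '", stage,
         "' does not match its recorded checksum")
  TRUE
}

save_artifact <- function(config, stage, value) {
  p <- stage_paths(config, stage)
  saveRDS(value, p$artifact)
  writeLines(yaml::as.yaml(list(config_hash = attr(config, "hash"),
                                artifact_md5 = unname(tools::md5sum(p$artifact)),
                                stage = stage)),
             p$marker)
  value
}

#' Run the processing pipeline
#'
#' Executes the requested stages in dependency order
#' (phantom, prep, regressors, train, sr, simulate, evaluate), writing each
#' stage's artifact and a marker carrying the configuration hash into
#' `out_dir`. Re-running with an unchanged configuration skips completed
#' stages; a tampered artifact raises a dependency error.
#'
#' @param config a `run_config` from [load_config()].
#' @param stages subset of stages to run (upstream artifacts must exist).
#' @param quiet suppress progress messages.
#' @return named list of executed/skipped status per stage, invisibly.
#' @export
run_pipeline <- function(config, stages = pipeline_stages, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(attr(config, "hash"), file.path(config$out_dir, "config.hash"))
  writeLines(yaml::as.yaml(unclass(config)),
             file.path(config$out_dir, "config.yaml"))
  status <- list()
  say <- function(...) if (!quiet) message(...)
  for (stage in stages) {
    if (stage_current(config, stage)) {
      say("[", stage, "] up to date, skipping")
      status[[stage]] <- "skipped"
      next
    }
    say("[", stage, "] running")
    value <- switch(stage,
      phantom = {
        ph <- config$phantom
        generate_cohort(cohort_spec(
          n_subjects = ph$n_subjects, volume_shape = ph$volume_shape,
          n_regions_per_slice = ph$n_regions_per_slice,
          age_range = ph$age_range,
          visits_per_subject = ph$visits_per_subject,
          visit_spacing = ph$visit_spacing,
          diagnosis_probs = ph$diagnosis_probs,
          atrophy_params = list(kappa = ph$kappa, tau = ph$tau, s = ph$s),
          noise_sd = ph$noise_sd,
          seed = derive_seed(config$seed, "phantom")))
      },
      prep = {
        cohort <- load_artifact(config, "phantom")
        prep_cohort(cohort, n_slices = config$prep$n_slices,
                    n_bins = config$prep$n_bins,
                    width_factor = config$prep$width_factor,
                    radii = config$prep$radii)
      },
      regressors = fit_regressor_bank(load_artifact(config, "prep")),
      train = {
        prepped <- load_artifact(config, "prep")
        bank <- load_artifact(config, "regressors")
        mcfg <- model_config(image_size = config$model$image_size,
                             latent_dim = config$model$latent_dim,
                             n_age_bins = config$prep$n_bins,
                             base_filters = config$model$base_filters,
                             seed = derive_seed(config$seed, "model"))
        train_all(prepped, bank, mcfg, pipeline_train_config(config),
                  pipeline_pwf(config))
      },
      sr = {
        model <- load_artifact(config, "train")
        prepped <- load_artifact(config, "prep")
        pairs <- make_sr_pairs(model, prepped)
        train_sr(pairs, n_filters = config$sr$n_filters,
                 patch = config$sr$patch, epochs = config$sr$epochs,
                 seed = derive_seed(config$seed, "sr"))
      },
      simulate = {
        model <- load_artifact(config, "train")
        srm <- load_artifact(config, "sr")
        cohort <- load_artifact(config, "phantom")
        sub <- cohort$subjects[[pipeline_subject(cohort, model)]]
        pm <- personalize(model, sub$scans[[1]]$volume,
                          sub$scans[[1]]$age, sub$dx)
        simulate_sequence(pm, sub$scans[[1]]$volume, sub$scans[[1]]$age,
                          sub$dx, sr = srm)
      },
      evaluate = {
        cohort <- load_artifact(config, "phantom")
        model <- load_artifact(config, "train")
        res <- load_artifact(config, "simulate")
        pipeline_evaluate(cohort, res, config,
                          pipeline_subject(cohort, model))
      })
    save_artifact(config, stage, value)
    status[[stage]] <- "executed"
  }
  invisible(status)
}

pipeline_train_config <- function(config) {
  tr <- config$train
  train_config(epochs = tr$epochs, batch_size = tr$batch_size,
               alpha = tr$alpha, beta1 = tr$beta1,
               common_init_iters = tr$common_init_iters,
               smooth_sigma = tr$smooth_sigma,
               smooth_half_width = tr$smooth_half_width,
               personalize_iters = tr$personalize_iters,
               seed = derive_seed(config$seed, "train"))
}

pipeline_pwf <- function(config) {
  pw <- config$pwf
  pwf_params(b = c(reg = pw$b_reg, vox = pw$b_vox, b = pw$b_b, z = pw$b_z,
                   rec = pw$b_rec),
             d = c(reg = pw$d_reg, vox = pw$d_vox, b = pw$d_b, z = pw$d_z,
                   rec = pw$d_rec),
             rho = pw$rho, v = pw$v)
}

# demonstration subject: first with a follow-up inside the simulated
# bin-centre range, else the first longitudinal subject
pipeline_subject <- function(cohort, model) {
  m <- range(model$binning$centers)
  longit <- which(vapply(cohort$subjects, function(s) length(s$scans), 0L) >=
                    2L)
  if (length(longit) == 0L) return(1L)
  for (i in longit) {
    ages <- vapply(cohort$subjects[[i]]$scans[-1], `[[`, 0, "age")
    if (any(ages >= m[1] & ages <= m[2])) return(i)
  }
  longit[1]
}

# compare the simulated sequence against the subject's real follow-up
# scans; follow-up ages are clamped into the simulated bin-centre range
pipeline_evaluate <- function(cohort, res, config, subject_index = 1L) {
  sub <- cohort$subjects[[subject_index]]
  zz <- res$slice_index          # simulated volumes cover the central slices
  atlas <- cohort$atlas[, , zz, drop = FALSE]
  labs <- sort(unique(atlas[atlas > 0]))
  brain <- atlas > 0
  th <- config$eval$threshold
  rng <- range(res$ages)
  errs <- list()
  for (v in seq_along(sub$scans)[-1]) {
    age <- min(max(sub$scans[[v]]$age, rng[1]), rng[2])
    simv <- interpolate_age(res, age)
    realv <- sub$scans[[v]]$volume[, , zz, drop = FALSE]
    for (r in labs) {
      errs[[length(errs) + 1L]] <- data.frame(
        subject = sub$subject_id, age = age, region = paste0("region", r),
        err = volumetric_error(simv, realv, atlas == r, brain, th))
    }
  }
  if (length(errs) == 0L)
    stop("dependency error: the evaluation subject has no follow-up scan")
  cohort_report(do.call(rbind, errs))
}
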