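# Top-level modelling interface: one fitting function returning a classed
# object with the usual methods. atrophynet() chains preprocessing,
# regional-regressor fitting, slice-wise adversarial training and
# (optionally) the 3D restoration stage, and the returned object simulates
# personalized, age-indexed MRI sequences.

#' Fit a brain-scan progression simulator
#'
#' Fits the full slice-wise adversarial progression model on a longitudinal
#' cohort: per-slice intensity normalization and age binning, per-region
#' sigmoid-link decline regressors, shared-initialization adversarial
#' training of the per-slice conditional autoencoders under the
#' profile-weight schedules, and an optional same-grid 3D restoration
#' network trained on the model's own reconstructions.
#'
#' @param cohort a `phantom_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param n_slices number of central axial slices T to model.
#' @param n_bins number of age bins A.
#' @param width_factor fuzzy membership width factor c.
#' @param radii morphological radii for region augmentation.
#' @param model a `model_config`; its `n_age_bins` is overridden by
#'   `n_bins`.
#' @param train a `train_config`.
#' @param pwf a `pwf_params`.
#' @param sr logical: train the 3D restoration stage; or a list of
#'   arguments to [train_sr()].
#' @return an object of class `atrophynet` wrapping the trained
#'   `progression_model`, the `sr_model` (or NULL), the regressor bank and
#'   the fitting metadata.
#' @seealso [simulate.atrophynet()], [predict.atrophynet()]
#' @export
atrophynet <- function(cohort, n_slices, n_bins = 10L, width_factor = 1,
                       radii = 1L, model = model_config(),
                       train = train_config(), pwf = pwf_params(),
                       sr = TRUE) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  prepped <- prep_cohort(cohort, n_slices, n_bins, width_factor, radii)
  model$n_age_bins <- as.integer(n_bins)
  bank <- fit_regressor_bank(prepped)
  pm <- train_all(prepped, bank, model, train, pwf)
  sr_model <- NULL
  if (!identical(sr, FALSE)) {
    pairs <- make_sr_pairs(pm, prepped)
    sr_args <- if (is.list(sr)) sr else list()
    sr_args$pairs <- pairs
    if (is.null(sr_args$seed)) sr_args$seed <- derive_seed(train$seed, "sr")
    sr_model <- do.call(train_sr, sr_args)
  }
  structure(list(model = pm, sr = sr_model, lr_bank = bank,
                 binning = prepped$binning,
                 n_scans = nrow(prepped$meta),
                 n_subjects = length(unique(prepped$meta$subject_id)),
                 call = match.call()),
            class = "atrophynet")
}

#' @export
print.atrophynet <- function(x, ...) {
  cfg <- x$model$model_config
  cat("Adversarial brain-scan progression simulator\n")
  cat(sprintf("  %d slice models (%dx%d px), latent %d, %d age bins, %d diagnoses\n",
              x$model$n_slices, cfg$image_size, cfg$image_size,
              cfg$latent_dim, cfg$n_age_bins, cfg$n_diagnoses))
  cat(sprintf("  trained on %d scans from %d subjects, %d epochs\n",
              x$n_scans, x$n_subjects, x$model$train_config$epochs))
  cat(sprintf("  restoration stage: %s\n",
              if (is.null(x$sr)) "none" else "trained"))
  invisible(x)
}

#' @export
summary.atrophynet <- function(object, ...) {
  log <- object$model$loss_log
  first <- log[log$epoch == 0, ]
  last <- log[log$epoch == max(log$epoch), ]
  out <- list(object = object,
              age_range = range(object$binning$edges),
              bin_centers = object$binning$centers,
              first_tot = mean(first$tot), last_tot = mean(last$tot),
              final_weights = pwf_weights_at(object$model$pwf,
                                             max(log$epoch)),
              n_regressors = sum(lengths(object$lr_bank$regressors)),
              n_fallback = sum(unlist(lapply(object$lr_bank$regressors,
                                             function(rs) vapply(rs, `[[`,
                                                                 TRUE,
                                                                 "fallback")))))
  class(out) <- "summary.atrophynet"
  out
}

#' @export
print.summary.atrophynet <- function(x, ...) {
  print(x$object)
  cat(sprintf("  ages %.1f-%.1f years; bin centres %s\n", x$age_range[1],
              x$age_range[2],
              paste(sprintf("%.1f", x$bin_centers), collapse = ", ")))
  cat(sprintf("  mean total loss: %.4g (first epoch) -> %.4g (final epoch)\n",
              x$first_tot, x$last_tot))
  cat(sprintf("  regional regressors: %d fitted, %d identity fallbacks\n",
              x$n_regressors, x$n_fallback))
  cat("  final-epoch loss weights:\n")
  print(round(x$final_weights, 5))
  invisible(x)
}

#' Simulate a personalized MRI sequence
#'
#' Personalizes the fitted simulator on a single baseline scan by transfer
#' learning (the restoration stage is frozen) and generates the full
#' age-indexed sequence.
#'
#' @param object an `atrophynet` fit.
#' @param nsim number of sequences (personalization is deterministic, so
#'   replicates are identical; kept for the generic's contract).
#' @param seed optional seed forwarded to the personalization RNG stream.
#' @param newdata baseline scan: height x width x depth array.
#' @param age acquisition age in years.
#' @param d diagnosis code 0-3.
#' @param personalize_iters fine-tuning iterations (default from the
#'   training configuration).
#' @param ... unused.
#' @return a `simulation_result` (list of `nsim` results when nsim > 1).
#' @export
simulate.atrophynet <- function(object, nsim = 1, seed = NULL, newdata,
                                age, d,
                                personalize_iters =
                                  object$model$train_config$personalize_iters,
                                ...) {
  if (!is.null(seed)) set.seed(seed)
  one <- function() {
    pm <- personalize(object$model, newdata, age, d,
                      iters = personalize_iters)
    simulate_sequence(pm, newdata, age, d, sr = object$sr)
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' Predict a simulated scan at arbitrary ages
#'
#' Runs [simulate.atrophynet()] and linearly interpolates the generated
#' sequence at the requested ages.
#'
#' @param object an `atrophynet` fit.
#' @param newdata baseline scan array.
#' @param age acquisition age in years.
#' @param d diagnosis code 0-3.
#' @param ages target ages (years), each within the simulated bin-centre
#'   range.
#' @param ... forwarded to [simulate.atrophynet()].
#' @return named list of interpolated volumes, one per target age.
#' @export
predict.atrophynet <- function(object, newdata, age, d, ages, ...) {
  res <- simulate.atrophynet(object, newdata = newdata, age = age, d = d,
                             ...)
  out <- lapply(ages, function(a) interpolate_age(res, a))
  names(out) <- sprintf("age_%.2f", ages)
  out
}

#' Regional regressor coefficients of a fitted simulator
#'
#' @param object an `atrophynet` fit.
#' @param ... unused.
#' @return data.frame with one row per (slice, region) regressor:
#'   intercept, baseline-age, age-gap and diagnosis coefficients, the
#'   sample count and the fallback flag.
#' @export
coef.atrophynet <- function(object, ...) {
  rows <- list()
  for (n in seq_along(object$lr_bank$regressors)) {
    for (q in seq_along(object$lr_bank$regressors[[n]])) {
      lr <- object$lr_bank$regressors[[n]][[q]]
      rows[[length(rows) + 1L]] <-
        data.frame(slice = n, region = q, intercept = lr$beta[1],
                   baseline_age = lr$beta[2], age_gap = lr$beta[3],
                   diagnosis = lr$beta[4], n_samples = lr$n_samples,
                   fallback = lr$fallback)
    }
  }
  do.call(rbind, rows)
}

#' Plot training diagnostics
#'
#' Two base-graphics panels: the per-epoch total loss (one line per slice
#' model) and the profile weight schedules on a log scale.
#'
#' @param x an `atrophynet` fit.
#' @param ... forwarded to [graphics::matplot()].
#' @export
plot.atrophynet <- function(x, ...) {
  log <- x$model$loss_log
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  tot <- stats::reshape(log[, c("epoch", "slice", "tot")],
                        direction = "wide", idvar = "epoch",
                        timevar = "slice")
  graphics::matplot(tot$epoch, as.matrix(tot[, -1]), type = "l", lty = 1,
                    xlab = "epoch", ylab = "total loss",
                    main = "training loss per slice model", ...)
  sched <- pwf_schedule(x$model$pwf, max(log$epoch) + 1L)
  graphics::matplot(sched$epoch, as.matrix(sched[, -1]), type = "l",
                    lty = 1, log = "y", xlab = "epoch", ylab = "weight",
                    main = "profile weight functions")
  graphics::legend("right", legend = names(sched)[-1], lty = 1,
                   col = seq_len(5), cex = 0.7)
  invisible(x)
}

#' @export
print.progression_model <- function(x, ...) {
  cat(sprintf("progression_model: %d slice models, %dx%d px, A = %d\n",
              x$n_slices, x$image_dim[1], x$image_dim[2],
              x$model_config$n_age_bins))
  invisible(x)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %d time points, ages %s (input age %.1f, dx %d)\n",
              length(x$volumes),
              paste(sprintf("%.1f", x$ages), collapse = ", "),
              x$theta, x$d))
  invisible(x)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  nscan <- sum(vapply(x$subjects, function(s) length(s$scans), 0L))
  cat(sprintf("phantom_cohort: %d subjects, %d scans, volume %s, %d regions/slice\n",
              length(x$subjects), nscan,
              paste(dim(x$atlas), collapse = "x"),
              length(unique(x$atlas[x$atlas > 0]))))
  invisible(x)
}
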