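# Personalization and 4D synthesis. A trained progression model is
# fine-tuned for a small number of iterations on a single baseline scan
# (transfer learning; the restoration network is left untouched), then the
# full age-indexed sequence is generated slice-wise, smoothed across
# slices, restored, and mapped back to the input's intensity scale.
# Intermediate ages are obtained by linear interpolation between the two
# nearest generated time points.

#' Personalize a trained model on one baseline scan
#'
#' Fine-tunes every slice model's four networks on the single input slice
#' with all losses active and the PWF weights at their final-epoch values;
#' the restoration network is a separate object and is untouched by
#' construction.
#'
#' @param model a trained `progression_model`.
#' @param volume baseline scan (height x width x depth array, raw
#'   intensities).
#' @param age acquisition age, years.
#' @param d diagnosis code 0-3.
#' @param iters fine-tuning iterations (default from the model's training
#'   configuration, 50 at full scale); 0 returns the model unchanged.
#' @return a personalized `progression_model`.
#' @export
personalize <- function(model, volume, age, d,
                        iters = model$train_config$personalize_iters) {
  stopifnot(inherits(model, "progression_model"))
  if (iters == 0L) return(model)
  stack <- normalize_slices(volume, model$n_slices)
  tconfig <- model$train_config
  t_final <- tconfig$epochs - 1L
  weights <- pwf_weights_at(model$pwf, t_final)
  mu <- membership_matrix(model$binning, age)
  bin <- assign_bin(model$binning, age)
  set.seed(derive_seed(tconfig$seed, "personalize"))
  for (n in seq_len(model$n_slices)) {
    models <- model$slice_models[[n]]
    opts <- new_opts(models, tconfig)
    Xb <- matrix(as.numeric(stack$slices[, , n]), ncol = 1L)
    for (it in seq_len(iters)) {
      st <- train_batch_step(models, opts, Xb, mu, bin, d, weights,
                             model$region_sets[[n]],
                             model$lr_bank$regressors[[n]],
                             model$binning$centers, model$lr_bank$eps,
                             tconfig)
      models <- st$models; opts <- st$opts
    }
    model$slice_models[[n]] <- models
  }
  model$personalized <- TRUE
  model
}

#' Simulate the full age-indexed MRI sequence for one subject
#'
#' Slice-wise: normalize the baseline scan, encode each slice, decode it at
#' every age bin, smooth each time point across slices, optionally restore
#' with the SR network, and invert the per-slice normalization so the
#' output lives on the input's intensity scale.
#'
#' @param model a (typically personalized) `progression_model`.
#' @param volume baseline scan (height x width x depth array).
#' @param age acquisition age, years.
#' @param d diagnosis code 0-3 (held fixed along the sequence).
#' @param sr optional `sr_model` applied to each simulated volume.
#' @return object of class `simulation_result`: `volumes` (list of A
#'   arrays), `ages` (bin centres), `theta`, `d`, `input_bin`.
#' @export
simulate_sequence <- function(model, volume, age, d, sr = NULL) {
  stopifnot(inherits(model, "progression_model"))
  if (length(dim(volume)) != 3L) stop("volume must be a 3D array")
  A <- model$model_config$n_age_bins
  np <- prod(model$image_dim)
  stack <- normalize_slices(volume, model$n_slices)
  seqs <- array(0, c(np, A, model$n_slices))
  for (n in seq_len(model$n_slices))
    seqs[, , n] <- generate_sequence(model$slice_models[[n]],
                                     stack$slices[, , n], d)
  volumes <- vector("list", A)
  for (i in seq_len(A)) {
    sm <- smooth_slices(matrix(seqs[, i, ], np, model$n_slices),
                        model$train_config$smooth_sigma,
                        model$train_config$smooth_half_width)
    vol <- array(sm, c(model$image_dim, model$n_slices))
    if (!is.null(sr)) vol <- apply_sr(sr, vol)
    volumes[[i]] <- denormalize_slices(stack, vol)
  }
  structure(list(volumes = volumes, ages = model$binning$centers,
                 theta = age, d = d,
                 input_bin = assign_bin(model$binning, age),
                 slice_index = stack$slice_index,
                 subject_id = stack$subject_id),
            class = "simulation_result")
}

#' Interpolate a simulated sequence at an intermediate age
#'
#' Weighted linear interpolation of the two generated time points whose bin
#' centres bracket the requested age: Y = (1 - lambda) Y_i + lambda Y_{i+1}
#' with lambda = (age - m_i) / (m_{i+1} - m_i).
#'
#' @param result a `simulation_result`.
#' @param age target age in years, within [m_1, m_A].
#' @return interpolated 3D volume.
#' @export
interpolate_age <- function(result, age) {
  stopifnot(inherits(result, "simulation_result"))
  m <- result$ages
  if (age < m[1] || age > m[length(m)])
    stop("extrapolation: age outside the simulated range [",
         signif(m[1], 4), ", ", signif(m[length(m)], 4), "]")
  i <- max(which(m <= age))
  if (i == length(m)) return(result$volumes[[i]])
  lambda <- (age - m[i]) / (m[i + 1] - m[i])
  (1 - lambda) * result$volumes[[i]] + lambda * result$volumes[[i + 1]]
}
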