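# Slice-wise adversarial training: per mini-batch a Db discriminator step,
# a Dz discriminator step, then a joint encoder+generator step on the
# PWF-weighted total loss. All slice models start from one common
# initialization (a short pre-training run on central slices) and are glued
# into a coherent 3D model by Gaussian cross-slice smoothing at inference.

#' Training configuration
#'
#' Defaults follow the full-scale setup: 300 epochs, mini-batches of 100
#' slices, Adam with alpha = 2e-4 and beta1 = 0.5, 100 common-initialization
#' iterations, cross-slice Gaussian smoothing with sigma = 1.5 slice units
#' over the +-2 nearest neighbours, and 50 personalization iterations.
#'
#' @param epochs training epochs per slice model.
#' @param batch_size mini-batch size.
#' @param alpha,beta1 Adam step size and first-moment decay.
#' @param common_init_iters mini-batch iterations of shared pre-training.
#' @param smooth_sigma,smooth_half_width Gaussian smoothing parameters
#'   (slice units / neighbour count).
#' @param personalize_iters fine-tuning iterations per test subject.
#' @param clip global gradient-norm clip.
#' @param seed integer seed for batching and prior sampling.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 300L, batch_size = 100L, alpha = 2e-4,
                         beta1 = 0.5, common_init_iters = 100L,
                         smooth_sigma = 1.5, smooth_half_width = 2L,
                         personalize_iters = 50L, clip = 10, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, smooth_sigma > 0,
            smooth_half_width >= 0, common_init_iters >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 alpha = alpha, beta1 = beta1,
                 common_init_iters = as.integer(common_init_iters),
                 smooth_sigma = smooth_sigma,
                 smooth_half_width = as.integer(smooth_half_width),
                 personalize_iters = as.integer(personalize_iters),
                 clip = clip, seed = as.integer(seed)),
            class = "train_config")
}

# conditioned generator input with per-sample age bins
gen_input_vec <- function(z, bins, d, config) {
  B <- ncol(z)
  oa <- matrix(0, config$n_age_bins, B)
  oa[cbind(bins, seq_len(B))] <- 1
  od <- matrix(0, config$n_diagnoses, B)
  od[cbind(d + 1L, seq_len(B))] <- 1
  rbind(z, oa, od)
}

new_opts <- function(models, config) {
  lapply(models[c("E", "G", "Db", "Dz")], adam_new,
         alpha = config$alpha, beta1 = config$beta1)
}

# One optimisation pass over a mini-batch: Db step, Dz step, then a joint
# E+G step on the weighted total. Returns updated models/optimisers and the
# batch loss bundle (adversarial entries are discriminator cross-entropies).
train_batch_step <- function(models, opts, Xb, mu, bins, dxb, weights,
                             region_set, regressors, centers, eps, tconfig) {
  cfg <- models$config
  B <- ncol(Xb)
  np <- nrow(Xb)
  A <- cfg$n_age_bins

  # --- discriminator on images ---
  z0 <- net_forward(models$E, Xb)$out
  fake_own <- net_forward(models$G, gen_input_vec(z0, bins, dxb, cfg))$out
  fr <- net_forward(models$Db, Xb)
  ff <- net_forward(models$Db, fake_own)
  pr <- 1 / (1 + exp(-fr$out)); pf <- 1 / (1 + exp(-ff$out))
  advb <- loss_adv_brain(pr, pf)
  gr <- net_backward(models$Db, fr$caches, (pr - 1) / length(pr))$grads
  gf <- net_backward(models$Db, ff$caches, pf / length(pf))$grads
  gsum <- mapply(function(a, b) list(dW = a$dW + b$dW, db = a$db + b$db),
                 gr, gf, SIMPLIFY = FALSE)
  st <- adam_step(models$Db, gsum, opts$Db, tconfig$clip)
  models$Db <- st$net; opts$Db <- st$opt

  # --- discriminator on latents ---
  zp <- sample_prior(cfg, B)
  fp <- net_forward(models$Dz, zp)
  fe <- net_forward(models$Dz, z0)
  pp <- 1 / (1 + exp(-fp$out)); pe <- 1 / (1 + exp(-fe$out))
  advz <- loss_adv_latent(pp, pe)
  gp <- net_backward(models$Dz, fp$caches, (pp - 1) / length(pp))$grads
  ge <- net_backward(models$Dz, fe$caches, pe / length(pe))$grads
  gsum <- mapply(function(a, b) list(dW = a$dW + b$dW, db = a$db + b$db),
                 gp, ge, SIMPLIFY = FALSE)
  st <- adam_step(models$Dz, gsum, opts$Dz, tconfig$clip)
  models$Dz <- st$net; opts$Dz <- st$opt

  # --- joint encoder + generator step ---
  fe0 <- net_forward(models$E, Xb)
  z <- fe0$out
  gseq_fw <- vector("list", A)
  Gs <- array(0, c(np, A, B))
  for (i in seq_len(A)) {
    gseq_fw[[i]] <- net_forward(models$G,
                                gen_input_vec(z, rep(i, B), dxb, cfg))
    Gs[, i, ] <- gseq_fw[[i]]$out
  }
  dG <- array(0, c(np, A, B))
  l_rec <- l_vox <- l_reg <- 0
  for (s in seq_len(B)) {
    gs <- Gs[, , s, drop = FALSE]; dim(gs) <- c(np, A)
    mus <- mu[, s]
    l_rec <- l_rec + loss_rec(Xb[, s], gs, mus)
    dG[, , s] <- dG[, , s] +
      weights["w_rec"] * grad_loss_rec(Xb[, s], gs, mus) / B
    l_vox <- l_vox + loss_vox(gs, bins[s])
    dG[, , s] <- dG[, , s] + weights["w_vox"] * grad_loss_vox(gs, bins[s]) / B
    l_reg <- l_reg + loss_reg(gs, bins[s], dxb[s], region_set, regressors,
                              centers, eps)
    dG[, , s] <- dG[, , s] +
      weights["w_reg"] * grad_loss_reg(gs, bins[s], dxb[s], region_set,
                                       regressors, centers, eps) / B
  }
  l_rec <- l_rec / B; l_vox <- l_vox / B; l_reg <- l_reg / B

  # non-saturating generator term on the own-age output
  fake_own <- matrix(0, np, B)
  for (s in seq_len(B)) fake_own[, s] <- Gs[, bins[s], s]
  ffo <- net_forward(models$Db, fake_own)
  pfo <- 1 / (1 + exp(-ffo$out))
  bdb <- net_backward(models$Db, ffo$caches,
                      weights["w_b"] * (pfo - 1) / length(pfo))
  dFake <- bdb$dX
  for (s in seq_len(B)) dG[, bins[s], s] <- dG[, bins[s], s] + dFake[, s]

  # encoder term: push encoded latents toward the prior under Dz
  fze <- net_forward(models$Dz, z)
  pze <- 1 / (1 + exp(-fze$out))
  bdz <- net_backward(models$Dz, fze$caches,
                      weights["w_z"] * (pze - 1) / length(pze))
  dz <- bdz$dX

  g_grads <- NULL
  for (i in seq_len(A)) {
    dGi <- dG[, i, , drop = FALSE]; dim(dGi) <- c(np, B)
    bw <- net_backward(models$G, gseq_fw[[i]]$caches, dGi)
    g_grads <- if (is.null(g_grads)) bw$grads else
      mapply(function(a, b) list(dW = a$dW + b$dW, db = a$db + b$db),
             g_grads, bw$grads, SIMPLIFY = FALSE)
    dz <- dz + bw$dX[seq_len(cfg$latent_dim), , drop = FALSE]
  }
  be <- net_backward(models$E, fe0$caches, dz)
  st <- adam_step(models$G, g_grads, opts$G, tconfig$clip)
  models$G <- st$net; opts$G <- st$opt
  st <- adam_step(models$E, be$grads, opts$E, tconfig$clip)
  models$E <- st$net; opts$E <- st$opt

  bundle <- list(rec = l_rec, vox = l_vox, reg = l_reg,
                 Db = advb$L_Db, Dz = advz$L_Dz)
  bundle$tot <- loss_total(bundle, weights)
  list(models = models, opts = opts, bundle = bundle)
}

#' Shared initialization for all slice models
#'
#' Builds the four networks from the configuration seed and pre-trains them
#' for a small number of mini-batch iterations on central-slice data; every
#' slice model then starts from these weights, which keeps independently
#' trained slices spatially coherent.
#'
#' @param central_data list with `X` (n_pixels x N matrix of normalized
#'   central slices), `theta` (ages), `dx` (diagnosis codes).
#' @param mconfig a `model_config`.
#' @param tconfig a `train_config`.
#' @param pwf a `pwf_params` (epoch-0 weights are used).
#' @param binning an `age_binning`.
#' @param region_set,regressors region masks and fitted regressors for the
#'   central slice.
#' @param iters iterations; `common_init_iters` from `tconfig` by default.
#' @param eps regional-loss numerical guard.
#' @return a `model_set` of shared initial weights.
#' @export
common_init <- function(central_data, mconfig, tconfig, pwf, binning,
                        region_set, regressors,
                        iters = tconfig$common_init_iters, eps = 0.1) {
  if (length(central_data$theta) == 0L) stop("empty central-slice data")
  models <- build_models(mconfig)
  if (iters == 0L) return(models)
  opts <- new_opts(models, tconfig)
  set.seed(derive_seed(tconfig$seed, "common-init"))
  weights <- pwf_weights_at(pwf, 0L)
  N <- ncol(central_data$X)
  mu_all <- membership_matrix(binning, central_data$theta)
  bins_all <- assign_bin(binning, central_data$theta)
  for (it in seq_len(iters)) {
    sel <- sample.int(N, min(tconfig$batch_size, N))
    st <- train_batch_step(models, opts, central_data$X[, sel, drop = FALSE],
                           mu_all[, sel, drop = FALSE], bins_all[sel],
                           central_data$dx[sel], weights, region_set,
                           regressors, binning$centers, eps, tconfig)
    models <- st$models; opts <- st$opts
  }
  models
}

#' Train one slice model
#'
#' Runs `epochs` passes over the slice's data with the epoch-dependent PWF
#' weights; each mini-batch performs a Db step, a Dz step, and a joint E+G
#' step. A non-finite total loss aborts with a training-divergence error
#' carrying the last finite-loss model state in its `models` field.
#'
#' @param n slice index (bookkeeping).
#' @param data list with `X` (n_pixels x N), `theta`, `dx`.
#' @param init a `model_set` to start from (cloned, not modified).
#' @param pwf a `pwf_params`.
#' @param regressors fitted `regional_lr` list for this slice.
#' @param region_set `region_set` for this slice.
#' @param binning an `age_binning`.
#' @param tconfig a `train_config`.
#' @param eps regional-loss numerical guard.
#' @return list(models, log) where `log` has one row per epoch with the five
#'   losses, the total, and the PWF weights in force.
#' @export
train_slice_model <- function(n, data, init, pwf, regressors, region_set,
                              binning, tconfig, eps = 0.1) {
  models <- init
  opts <- new_opts(models, tconfig)
  set.seed(derive_seed(tconfig$seed, paste0("slice-", n)))
  N <- ncol(data$X)
  mu_all <- membership_matrix(binning, data$theta)
  bins_all <- assign_bin(binning, data$theta)
  log <- vector("list", tconfig$epochs)
  last_good <- models
  for (t in seq_len(tconfig$epochs) - 1L) {
    weights <- pwf_weights_at(pwf, t)
    ord <- sample.int(N)
    nb <- max(1L, ceiling(N / tconfig$batch_size))
    acc <- c(rec = 0, vox = 0, reg = 0, Db = 0, Dz = 0, tot = 0)
    for (b in seq_len(nb)) {
      sel <- ord[seq((b - 1L) * tconfig$batch_size + 1L,
                     min(b * tconfig$batch_size, N))]
      st <- train_batch_step(models, opts, data$X[, sel, drop = FALSE],
                             mu_all[, sel, drop = FALSE], bins_all[sel],
                             data$dx[sel], weights, region_set, regressors,
                             binning$centers, eps, tconfig)
      models <- st$models; opts <- st$opts
      if (!is.finite(st$bundle$tot)) {
        cond <- structure(class = c("training_divergence", "error",
                                    "condition"),
                          list(message = sprintf(
                            "training diverged at slice %d, epoch %d", n, t),
                            call = sys.call(), models = last_good))
        stop(cond)
      }
      acc <- acc + unlist(st$bundle)
    }
    last_good <- models
    log[[t + 1L]] <- data.frame(epoch = t, slice = n,
                                t(acc / nb), t(weights))
  }
  list(models = models, log = do.call(rbind, log))
}

#' Train all slice models
#'
#' Builds the shared initialization on the central slice, then trains each
#' slice model from it. Slice models are statistically independent given the
#' shared initialization: each is trained under its own derived seed, so any
#' one slice can be re-trained in isolation and reproduce its weights.
#'
#' @param prepped a `prepped_cohort`.
#' @param lr_bank an `lr_bank` fitted on the same cohort.
#' @param mconfig a `model_config`; its image size must match the prepped
#'   slices.
#' @param tconfig a `train_config`.
#' @param pwf a `pwf_params`.
#' @return object of class `progression_model`.
#' @export
train_all <- function(prepped, lr_bank, mconfig, tconfig = train_config(),
                      pwf = pwf_params()) {
  stopifnot(inherits(prepped, "prepped_cohort"))
  if (!all(prepped$image_dim == mconfig$image_size))
    stop("image_size does not match prepped slices")
  if (mconfig$n_age_bins != prepped$binning$A)
    stop("model n_age_bins does not match the cohort age binning")
  T_ <- prepped$n_slices
  slice_data <- lapply(seq_len(T_), function(n)
    list(X = vapply(prepped$stacks, function(st) as.numeric(st$slices[, , n]),
                    numeric(prod(prepped$image_dim))),
         theta = prepped$meta$age, dx = prepped$meta$dx))
  ctr <- (T_ + 1L) %/% 2L
  init <- common_init(slice_data[[ctr]], mconfig, tconfig, pwf,
                      prepped$binning, prepped$region_sets[[ctr]],
                      lr_bank$regressors[[ctr]], eps = lr_bank$eps)
  slice_models <- vector("list", T_)
  logs <- vector("list", T_)
  for (n in seq_len(T_)) {
    r <- train_slice_model(n, slice_data[[n]], init, pwf,
                           lr_bank$regressors[[n]], prepped$region_sets[[n]],
                           prepped$binning, tconfig, eps = lr_bank$eps)
    slice_models[[n]] <- r$models
    logs[[n]] <- r$log
  }
  structure(list(slice_models = slice_models, model_config = mconfig,
                 train_config = tconfig, pwf = pwf,
                 binning = prepped$binning,
                 region_sets = prepped$region_sets, lr_bank = lr_bank,
                 loss_log = do.call(rbind, logs), n_slices = T_,
                 image_dim = prepped$image_dim,
                 slice_index = prepped$slice_index),
            class = "progression_model")
}

#' Validation scorer for the PWF grid search
#'
#' Returns a closure mapping `pwf_params` to the final-epoch total loss of
#' a central-slice model trained under that schedule on the training part
#' of the cohort and scored on a held-out validation fraction. This is the
#' `eval_fn` expected by [pwf_grid_search()].
#'
#' @param prepped a `prepped_cohort`.
#' @param lr_bank an `lr_bank`.
#' @param mconfig a `model_config`.
#' @param tconfig a `train_config` (use few epochs: one short training run
#'   is performed per grid draw).
#' @param val_frac held-out fraction of scans used for scoring.
#' @return function(pwf_params) -> validation total loss.
#' @export
pwf_validation_eval <- function(prepped, lr_bank, mconfig, tconfig,
                                val_frac = 0.25) {
  ctr <- (prepped$n_slices + 1L) %/% 2L
  np <- prod(prepped$image_dim)
  X <- vapply(prepped$stacks, function(st) as.numeric(st$slices[, , ctr]),
              numeric(np))
  set.seed(derive_seed(tconfig$seed, "pwf-validation-split"))
  N <- ncol(X)
  val <- sample.int(N, max(1L, round(val_frac * N)))
  tr_idx <- setdiff(seq_len(N), val)
  data_tr <- list(X = X[, tr_idx, drop = FALSE],
                  theta = prepped$meta$age[tr_idx],
                  dx = prepped$meta$dx[tr_idx])
  binning <- prepped$binning
  rs <- prepped$region_sets[[ctr]]
  regs <- lr_bank$regressors[[ctr]]
  mu_val <- membership_matrix(binning, prepped$meta$age[val])
  bins_val <- assign_bin(binning, prepped$meta$age[val])
  function(params) {
    init <- build_models(mconfig)
    r <- train_slice_model(ctr, data_tr, init, params, regs, rs, binning,
                           tconfig, eps = lr_bank$eps)
    weights <- pwf_weights_at(params, tconfig$epochs - 1L)
    tot <- 0
    for (k in seq_along(val)) {
      s <- val[k]
      g <- generate_sequence(r$models, X[, s], prepped$meta$dx[s])
      z <- net_forward(r$models$E, X[, s, drop = FALSE])$out
      bundle <- list(
        rec = loss_rec(X[, s], g, mu_val[, k]),
        vox = loss_vox(g, bins_val[k]),
        reg = loss_reg(g, bins_val[k], prepped$meta$dx[s], rs, regs,
                       binning$centers, lr_bank$eps),
        Db = loss_adv_brain(db_prob(r$models, X[, s, drop = FALSE]),
                            db_prob(r$models, g[, bins_val[k], drop = FALSE])
                            )$L_Db,
        Dz = loss_adv_latent(dz_prob(r$models, sample_prior(mconfig, 1L)),
                             dz_prob(r$models, z))$L_Dz)
      tot <- tot + loss_total(bundle, weights)
    }
    tot / length(val)
  }
}

#' Gaussian cross-slice smoothing
#'
#' Each output slice is the Gaussian-weighted average of its +-half_width
#' nearest neighbours (weights prop. to exp(-k^2 / (2 sigma^2)),
#' renormalized over the in-range neighbours at the stack boundary).
#' Linear, and preserves the per-pixel range of the contributing slices.
#'
#' @param stack n_pixels x T matrix or H x W x T array of slices.
#' @param sigma Gaussian width in slice units.
#' @param half_width neighbour radius.
#' @return smoothed stack of the same shape.
#' @export
smooth_slices <- function(stack, sigma = 1.5, half_width = 2L) {
  arr <- is.array(stack) && length(dim(stack)) == 3L
  m <- if (arr) matrix(stack, ncol = dim(stack)[3]) else stack
  T_ <- ncol(m)
  if (T_ < 1L) stop("empty slice stack")
  w <- exp(-(seq(-half_width, half_width))^2 / (2 * sigma^2))
  out <- m * 0
  for (n in seq_len(T_)) {
    ks <- seq(max(1L, n - half_width), min(T_, n + half_width))
    wk <- w[ks - n + half_width + 1L]
    out[, n] <- m[, ks, drop = FALSE] %*% (wk / sum(wk))
  }
  if (arr) array(out, dim(stack)) else out
}
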