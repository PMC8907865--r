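# Same-grid 3D restoration ("super-resolution") stage. Cross-slice Gaussian
# smoothing buys 3D coherence at the price of anatomical detail; this block
# learns to undo that loss. It is trained separately from the progression
# model on self-generated pairs: the high-resolution target is the
# preprocessed input volume itself, the low-resolution counterpart is the
# model's own reconstruction of that volume at its own age (smoothing
# included, restoration disabled). No resampling is involved: input and
# output live on the same voxel grid.
#
# Architecture: a small densely connected 3D conv net with a residual
# output head initialized to zero, so the untrained network is the
# identity map.

#' Build LR/HR training pairs for the restoration network
#'
#' For every training scan, the high-resolution volume is the stack of its
#' normalized slices and the low-resolution counterpart is the progression
#' model's reconstruction of the same scan at the scan's own age bin,
#' smoothed across slices.
#'
#' @param model a trained `progression_model`.
#' @param prepped the `prepped_cohort` the model was trained on (or any
#'   compatible one).
#' @return list of `sr_pair` objects: `lr` and `hr` arrays of equal shape,
#'   both in [0, 1].
#' @export
make_sr_pairs <- function(model, prepped) {
  stopifnot(inherits(model, "progression_model"),
            inherits(prepped, "prepped_cohort"))
  if (model$n_slices != prepped$n_slices) stop("slice count mismatch")
  np <- prod(model$image_dim)
  lapply(seq_along(prepped$stacks), function(si) {
    st <- prepped$stacks[[si]]
    d <- prepped$meta$dx[si]
    a <- assign_bin(model$binning, st$age)
    lr <- matrix(0, np, model$n_slices)
    for (n in seq_len(model$n_slices)) {
      g <- generate_sequence(model$slice_models[[n]],
                             st$slices[, , n], d)
      lr[, n] <- g[, a]
    }
    lr <- smooth_slices(lr, model$train_config$smooth_sigma,
                        model$train_config$smooth_half_width)
    structure(list(lr = array(lr, dim(st$slices)), hr = st$slices,
                   subject_id = st$subject_id, age = st$age),
              class = "sr_pair")
  })
}

sr_plans <- function(sp) list(p1 = conv_plan(sp, 3L, 1L, 1L))

sr_forward <- function(sr, vol, with_cache = FALSE) {
  sp <- dim(vol)
  key <- paste(sp, collapse = "x")
  plan <- conv_plan(sp, 3L, 1L, 1L)
  x <- matrix(as.numeric(vol), ncol = 1L)
  l1 <- sr$layers$c1; l1$plan <- plan
  l2 <- sr$layers$c2; l2$plan <- plan
  l3 <- sr$layers$c3; l3$plan <- plan
  r1 <- layer_fwd(l1, x)
  r2 <- layer_fwd(l2, r1$Y)
  cat12 <- rbind(r1$Y, r2$Y)          # dense connectivity: concat features
  r3 <- layer_fwd(l3, cat12)
  out <- x + r3$Y                     # residual head
  if (!with_cache) return(out)
  list(out = out, x = x, plan = plan, l = list(l1, l2, l3),
       caches = list(r1$cache, r2$cache, r3$cache),
       y1 = r1$Y, y2 = r2$Y)
}

sr_backward <- function(sr, fw, dOut) {
  g3 <- layer_bwd(fw$l[[3]], fw$caches[[3]], dOut)
  nf <- nrow(fw$y1) # rows of first feature block
  d1 <- g3$dX[seq_len(nf), , drop = FALSE]
  d2 <- g3$dX[nf + seq_len(nrow(fw$y2)), , drop = FALSE]
  g2 <- layer_bwd(fw$l[[2]], fw$caches[[2]], d2)
  g1 <- layer_bwd(fw$l[[1]], fw$caches[[1]], d1 + g2$dX)
  list(grads = list(list(dW = g1$dW, db = g1$db),
                    list(dW = g2$dW, db = g2$db),
                    list(dW = g3$dW, db = g3$db)))
}

#' Train the 3D restoration network
#'
#' Patch-based voxel-wise MSE training with Adam on LR/HR pairs. The
#' residual output layer starts at zero, so training starts from the
#' identity map and learns the correction.
#'
#' @param pairs list of `sr_pair` from [make_sr_pairs()].
#' @param n_filters feature channels per dense-block layer.
#' @param patch cubic patch edge length (voxels) used for training draws.
#' @param epochs training epochs; each epoch draws one patch per pair.
#' @param alpha,beta1 Adam parameters.
#' @param clip gradient-norm clip.
#' @param seed RNG seed.
#' @return object of class `sr_model` with the layer weights and a per-epoch
#'   loss log.
#' @export
train_sr <- function(pairs, n_filters = 8L, patch = 8L, epochs = 40L,
                     alpha = 1e-3, beta1 = 0.5, clip = 10, seed = 1L) {
  if (length(pairs) == 0L) stop("empty pair list")
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  pplan <- conv_plan(rep(patch, 3L), 3L, 1L, 1L)
  layers <- list(c1 = layer_conv(pplan, 1L, n_filters, "lrelu"),
                 c2 = layer_conv(pplan, n_filters, n_filters, "lrelu"),
                 c3 = layer_conv(pplan, 2L * n_filters, 1L, "linear"))
  layers$c3$W[] <- 0                 # residual head: identity at init
  sr <- structure(list(layers = layers, n_filters = n_filters,
                       patch = patch), class = "sr_model")
  net <- net_new(list(layers$c1, layers$c2, layers$c3))
  opt <- adam_new(net, alpha = alpha, beta1 = beta1)
  log <- numeric(epochs)
  dims <- dim(pairs[[1]]$lr)
  psz <- pmin(patch, dims)
  for (e in seq_len(epochs)) {
    tot <- 0
    for (pr in pairs) {
      o <- vapply(seq_len(3L), function(k)
        sample.int(dims[k] - psz[k] + 1L, 1L), 0L)
      idx <- lapply(seq_len(3L), function(k) o[k] + seq_len(psz[k]) - 1L)
      lr <- pr$lr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      hr <- pr$hr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      fw <- sr_forward(sr, lr, with_cache = TRUE)
      resid <- fw$out - as.numeric(hr)
      tot <- tot + mean(resid^2)
      bw <- sr_backward(sr, fw, 2 * resid / length(resid))
      net <- net_new(list(sr$layers$c1, sr$layers$c2, sr$layers$c3))
      st <- adam_step(net, bw$grads, opt, clip)
      opt <- st$opt
      sr$layers$c1 <- st$net$layers[[1]]
      sr$layers$c2 <- st$net$layers[[2]]
      sr$layers$c3 <- st$net$layers[[3]]
    }
    log[e] <- tot / length(pairs)
  }
  sr$loss_log <- data.frame(epoch = seq_len(epochs), mse = log)
  sr
}

#' Apply the restoration network to a volume
#'
#' Same-shape restoration: the network's residual correction is added to
#' the input and the result clipped to [0, 1]. Deterministic given weights.
#'
#' @param sr an `sr_model` (possibly untrained: then near-identity).
#' @param volume 3D array in [0, 1].
#' @return restored volume, same shape, in [0, 1].
#' @export
apply_sr <- function(sr, volume) {
  stopifnot(inherits(sr, "sr_model"))
  if (length(dim(volume)) != 3L) stop("volume must be a 3D array")
  if (any(dim(volume) < 2L)) stop("volume too small for restoration")
  out <- sr_forward(sr, volume)
  array(pmin(pmax(out, 0), 1), dim(volume))
}

# weight fingerprint used by the personalization freeze contract
sr_hash <- function(sr) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(sr$layers$c1$W, sr$layers$c1$b, sr$layers$c2$W,
               sr$layers$c2$b, sr$layers$c3$W, sr$layers$c3$b), f)
  unname(tools::md5sum(f))
}
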