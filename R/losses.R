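# The five training losses and their weighted total. All image losses use
# mean squared error over pixels (keeping weights comparable across image
# sizes) and operate on single samples: a slice X as a numeric vector/matrix
# and a generated sequence G as an (n_pixels x A) matrix. Each loss has a
# companion gradient used by the training loop; adversarial terms are the
# standard non-saturating binary cross-entropy formulation, and the stored
# adversarial values are the discriminator cross-entropies entering the
# total loss.

#' Membership-weighted reconstruction loss
#'
#' sum_i mu_i * MSE(X, G_i): the difference between the input slice and
#' every generated age-bin output, weighted by the fuzzy membership of the
#' input's age in that bin so that nearer ages weigh more heavily.
#'
#' @param x input slice (vector or matrix of pixels).
#' @param g_seq n_pixels x A matrix of generated outputs.
#' @param mu length-A membership weights mu_i(theta).
#' @return non-negative scalar.
#' @export
loss_rec <- function(x, g_seq, mu) {
  x <- as.numeric(x)
  if (ncol(g_seq) != length(mu)) stop("length mismatch: A != length(mu)")
  if (nrow(g_seq) != length(x)) stop("pixel count mismatch")
  sum(mu * colMeans((g_seq - x)^2))
}

grad_loss_rec <- function(x, g_seq, mu) {
  x <- as.numeric(x)
  sweep(2 * (g_seq - x) / nrow(g_seq), 2L, mu, `*`)
}

#' Voxel-level monotonicity loss
#'
#' Penalizes, for the output at the input's own age bin `a`, voxels that
#' exceed the element-wise minimum of all earlier outputs or fall below the
#' element-wise maximum of all later outputs. At the sequence boundaries the
#' missing term is omitted (and the 1/2 factor with it).
#'
#' @param g_seq n_pixels x A matrix of generated outputs.
#' @param a input age-bin index in 1..A.
#' @return non-negative scalar; 0 for a constant sequence.
#' @export
loss_vox <- function(g_seq, a) {
  A <- ncol(g_seq)
  if (a < 1 || a > A) stop("age-bin index out of range")
  terms <- numeric(0)
  if (a > 1) {
    lo <- apply(g_seq[, seq_len(a - 1L), drop = FALSE], 1L, min)
    terms <- c(terms, mean((g_seq[, a] - lo)^2))
  }
  if (a < A) {
    hi <- apply(g_seq[, seq(a + 1L, A), drop = FALSE], 1L, max)
    terms <- c(terms, mean((g_seq[, a] - hi)^2))
  }
  if (length(terms) == 0L) return(0)
  if (length(terms) == 2L) mean(terms) else terms
}

# subgradient: residuals route to G_a and to the element-wise argmin/argmax
# slice (first index on ties)
grad_loss_vox <- function(g_seq, a) {
  A <- ncol(g_seq); np <- nrow(g_seq)
  dG <- g_seq * 0
  both <- (a > 1) && (a < A)
  fac <- if (both) 0.5 else 1
  if (a > 1) {
    pre <- g_seq[, seq_len(a - 1L), drop = FALSE]
    lo <- apply(pre, 1L, min)
    wmin <- max.col(-pre, ties.method = "first")
    r <- 2 * (g_seq[, a] - lo) / np * fac
    dG[, a] <- dG[, a] + r
    dG[cbind(seq_len(np), wmin)] <- dG[cbind(seq_len(np), wmin)] - r
  }
  if (a < A) {
    post <- g_seq[, seq(a + 1L, A), drop = FALSE]
    hi <- apply(post, 1L, max)
    wmax <- a + max.col(post, ties.method = "first")
    r <- 2 * (g_seq[, a] - hi) / np * fac
    dG[, a] <- dG[, a] + r
    dG[cbind(seq_len(np), wmax)] <- dG[cbind(seq_len(np), wmax)] - r
  }
  dG
}

#' Region-level progression loss
#'
#' Size-weighted squared deviation between the regional intensity ratios of
#' the generated sequence and the ratios predicted by the per-region
#' regressors, averaged over regions and time pairs: for each region q and
#' each bin o on the opposite side of the input bin a, the generated ratio
#' is (sum of later output over the mask + eps)/(sum of earlier output +
#' eps), compared against predict_ratio at the corresponding bin-centre
#' ages; the total is normalized by R * (A - 1).
#'
#' @param g_seq n_pixels x A matrix of generated outputs.
#' @param a input age-bin index.
#' @param d diagnosis code 0-3.
#' @param region_set `region_set` for this slice (masks must match the
#'   image pixel count).
#' @param regressors list of `regional_lr`, one per mask.
#' @param centers length-A ages (years) of the bin centres.
#' @param eps numerical guard (default 0.1), matching the value used when
#'   fitting the regressors.
#' @return non-negative scalar.
#' @export
loss_reg <- function(g_seq, a, d, region_set, regressors, centers, eps = 0.1) {
  A <- ncol(g_seq)
  R <- region_set$R
  if (length(regressors) < R) stop("missing regressor for some region")
  tot <- 0
  for (q in seq_len(R)) {
    m <- as.logical(region_set$masks[[q]])
    sums <- colSums(g_seq[m, , drop = FALSE]) + eps
    lr <- regressors[[q]]
    s <- region_set$sizes[q]      # a weight: may be rescaled by the caller
    for (o in seq_len(A)) {
      if (o == a) next
      if (o < a) {
        pred <- predict_ratio(lr, centers[o], centers[a], d)
        gen <- sums[a] / sums[o]
      } else {
        pred <- predict_ratio(lr, centers[a], centers[o], d)
        gen <- sums[o] / sums[a]
      }
      tot <- tot + s * (pred - gen)^2
    }
  }
  tot / (R * (A - 1))
}

grad_loss_reg <- function(g_seq, a, d, region_set, regressors, centers,
                          eps = 0.1) {
  A <- ncol(g_seq)
  R <- region_set$R
  dG <- g_seq * 0
  norm <- R * (A - 1)
  for (q in seq_len(R)) {
    m <- as.logical(region_set$masks[[q]])
    sums <- colSums(g_seq[m, , drop = FALSE]) + eps
    lr <- regressors[[q]]
    s <- region_set$sizes[q]
    for (o in seq_len(A)) {
      if (o == a) next
      if (o < a) { num <- a; den <- o
        pred <- predict_ratio(lr, centers[o], centers[a], d)
      } else { num <- o; den <- a
        pred <- predict_ratio(lr, centers[a], centers[o], d)
      }
      gen <- sums[num] / sums[den]
      coefb <- -2 * s * (pred - gen) / norm   # d/d gen
      dG[m, num] <- dG[m, num] + coefb / sums[den]
      dG[m, den] <- dG[m, den] - coefb * sums[num] / sums[den]^2
    }
  }
  dG
}

# clamped binary cross-entropy on probabilities
bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Adversarial image loss (brain realism)
#'
#' Standard non-saturating GAN pair on the image discriminator's patch
#' probabilities: the discriminator cross-entropy BCE(real -> 1) +
#' BCE(fake -> 0), and the generator term BCE(fake -> 1).
#'
#' @param p_real,p_fake discriminator probabilities on real and generated
#'   slices (any shape; treated element-wise as patch/sample probabilities).
#' @return list(L_Db, gen_term), both non-negative.
#' @export
loss_adv_brain <- function(p_real, p_fake) {
  if (length(p_real) == 0L || length(p_fake) == 0L) stop("empty batch")
  list(L_Db = bce(p_real, 1) + bce(p_fake, 0), gen_term = bce(p_fake, 1))
}

#' Adversarial latent loss (temporal smoothness prior)
#'
#' As [loss_adv_brain()] with the latent discriminator: vectors drawn from
#' the uniform prior play the real role and encoded vectors the fake role;
#' the encoder term is BCE(encoded -> 1).
#'
#' @param p_prior,p_encoded discriminator probabilities on prior samples and
#'   encoded latents.
#' @return list(L_Dz, enc_term).
#' @export
loss_adv_latent <- function(p_prior, p_encoded) {
  if (length(p_prior) == 0L || length(p_encoded) == 0L) stop("empty batch")
  list(L_Dz = bce(p_prior, 1) + bce(p_encoded, 0), enc_term = bce(p_encoded, 1))
}

#' Weighted total loss
#'
#' w_reg*L_reg + w_vox*L_vox + w_b*L_Db + w_z*L_Dz + w_rec*L_rec.
#'
#' @param bundle list with elements `rec`, `vox`, `reg`, `Db`, `Dz`.
#' @param weights named numeric with `w_reg`, `w_vox`, `w_b`, `w_z`,
#'   `w_rec`, all >= 0.
#' @return scalar.
#' @export
loss_total <- function(bundle, weights) {
  w <- weights[c("w_reg", "w_vox", "w_b", "w_z", "w_rec")]
  if (any(is.na(w))) stop("weights must be named w_reg, w_vox, w_b, w_z, w_rec")
  if (any(w < 0)) stop("negative loss weight")
  unname(w["w_reg"] * bundle$reg + w["w_vox"] * bundle$vox +
           w["w_b"] * bundle$Db + w["w_z"] * bundle$Dz +
           w["w_rec"] * bundle$rec)
}
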