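test_that("model configuration validates its invariants", {
  expect_equal(model_config()$latent_dim, 200L)
  expect_equal(model_config()$image_size, 128L)
  expect_error(model_config(image_size = 20), "power of two")
  expect_error(model_config(image_size = 8), "power of two")
  expect_error(model_config(latent_dim = 1), "latent_dim")
})

test_that("network construction is shape-correct and seed-deterministic", {
  cfg <- model_config(image_size = 32, latent_dim = 16, n_age_bins = 3,
                      base_filters = 4, seed = 21)
  m1 <- build_models(cfg)
  m2 <- build_models(cfg)
  expect_identical(atrophynet:::net_params(m1$E),
                   atrophynet:::net_params(m2$E))
  expect_identical(atrophynet:::net_params(m1$G),
                   atrophynet:::net_params(m2$G))
  x <- matrix(runif(32 * 32), ncol = 1)
  z <- atrophynet:::net_forward(m1$E, x)$out
  expect_equal(nrow(z), 16)
  expect_true(all(is.finite(z)))
  expect_true(all(abs(z) <= 1))          # tanh latent, prior support [-1,1]
  g <- atrophynet:::net_forward(m1$G,
                                atrophynet:::gen_input(z, 2, 1, cfg))$out
  expect_equal(nrow(g), 32 * 32)
  expect_true(all(g >= 0 & g <= 1))
  pb <- atrophynet:::db_prob(m1, x)
  pz <- atrophynet:::dz_prob(m1, z)
  expect_true(all(pb > 0 & pb < 1))
  expect_true(all(pz > 0 & pz < 1))
})

test_that("generated sequences are age-indexed, bounded and repeatable", {
  cfg <- tiny_mconfig()
  m <- build_models(cfg)
  x <- matrix(runif(16 * 16), 16, 16)
  s1 <- generate_sequence(m, x, 2)
  expect_equal(dim(s1), c(256, 3))
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_identical(s1, generate_sequence(m, x, 2))
  expect_error(generate_sequence(m, matrix(0.5, 8, 8), 0), "image_size")
  expect_error(generate_sequence(m, x, 7), "diagnosis")
})

test_that("every loss drives gradients into the networks it trains", {
  set.seed(31)
  cfg <- tiny_mconfig()
  m <- build_models(cfg)
  A <- cfg$n_age_bins
  x <- matrix(runif(256, 0.2, 0.8), ncol = 1)
  fe <- atrophynet:::net_forward(m$E, x)
  z <- fe$out
  fws <- lapply(seq_len(A), function(i)
    atrophynet:::net_forward(m$G, atrophynet:::gen_input(z, i, 1, cfg)))
  g_seq <- vapply(fws, function(f) f$out[, 1], numeric(256))

  backprop_norms <- function(dG) {
    gg <- 0; dz <- matrix(0, cfg$latent_dim, 1)
    for (i in seq_len(A)) {
      bw <- atrophynet:::net_backward(m$G, fws[[i]]$caches,
                                      dG[, i, drop = FALSE])
      gg <- gg + sum(abs(atrophynet:::grads_flat(bw$grads)))
      dz <- dz + bw$dX[seq_len(cfg$latent_dim), , drop = FALSE]
    }
    be <- atrophynet:::net_backward(m$E, fe$caches, dz)
    c(G = gg, E = sum(abs(atrophynet:::grads_flat(be$grads))))
  }
  mu <- membership_oracle <- runif(A, 0.3, 1)
  n_rec <- backprop_norms(atrophynet:::grad_loss_rec(x[, 1], g_seq, mu))
  expect_true(all(n_rec > 0))
  n_vox <- backprop_norms(atrophynet:::grad_loss_vox(g_seq, 2))
  expect_true(all(n_vox > 0))
  rs <- structure(list(n = 1L,
                       masks = list(matrix(c(TRUE, FALSE), 16, 16)),
                       sizes = 128L, R = 1L, labels = "1"),
                  class = "region_set")
  lrs <- list(structure(list(beta = c(2, 0, -0.1, 0), fallback = FALSE),
                        class = "regional_lr"))
  n_reg <- backprop_norms(
    atrophynet:::grad_loss_reg(g_seq, 2, 1, rs, lrs, c(66, 72, 78)))
  expect_true(all(n_reg > 0))
  # adversarial: G receives gradient through Db, E through Dz
  fo <- atrophynet:::net_forward(m$Db, g_seq[, 2, drop = FALSE])
  po <- 1 / (1 + exp(-fo$out))
  dfake <- atrophynet:::net_backward(m$Db, fo$caches,
                                     (po - 1) / length(po))$dX
  dG <- g_seq * 0; dG[, 2] <- dfake
  expect_gt(backprop_norms(dG)[["G"]], 0)
  fz <- atrophynet:::net_forward(m$Dz, z)
  pz <- 1 / (1 + exp(-fz$out))
  dz_adv <- atrophynet:::net_backward(m$Dz, fz$caches,
                                      (pz - 1) / length(pz))$dX
  be <- atrophynet:::net_backward(m$E, fe$caches, dz_adv)
  expect_gt(sum(abs(atrophynet:::grads_flat(be$grads))), 0)
  # and the discriminators themselves
  bdb <- atrophynet:::net_backward(m$Db, fo$caches, (po - 0) / length(po))
  expect_gt(sum(abs(atrophynet:::grads_flat(bdb$grads))), 0)
  bdz <- atrophynet:::net_backward(m$Dz, fz$caches, (pz - 0) / length(pz))
  expect_gt(sum(abs(atrophynet:::grads_flat(bdz$grads))), 0)
})
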