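test_that("reconstruction loss matches its definition and hand cases", {
  # A = 1, mu = 1, X = 0.5, G = 0 -> MSE 0.25
  expect_equal(loss_rec(rep(0.5, 9), matrix(0, 9, 1), 1), 0.25)
  g <- matrix(runif(16 * 3), 16, 3)
  expect_equal(loss_rec(g[, 2], g, c(1, 1, 1))
               , ref_loss_rec(g[, 2], g, c(1, 1, 1)))
  # zero iff G_i = X wherever mu_i > 0
  expect_equal(loss_rec(g[, 1], g[, c(1, 1), drop = FALSE], c(0.5, 1)), 0)
  # linear in the membership weights
  x <- runif(16)
  mu <- c(0.2, 0.9, 0.4)
  expect_equal(loss_rec(x, g, 2 * mu), 2 * loss_rec(x, g, mu))
  expect_error(loss_rec(x, g, c(1, 1)), "mismatch")
})

test_that("voxel monotonicity loss handles interior and boundary bins", {
  # constant sequences cost nothing
  expect_equal(loss_vox(matrix(0.7, 5, 4), 2), 0)
  # hand case: scalar voxels, A=3, a=2, G = (1.0, 0.5, 0.2)
  g <- matrix(c(1.0, 0.5, 0.2), 1, 3)
  expect_equal(loss_vox(g, 2), 0.5 * ((0.5 - 1)^2 + (0.5 - 0.2)^2))
  # a = 1 with later outputs below G_1 except a max equal to G_1
  g2 <- cbind(rep(0.8, 4), rep(0.8, 4), rep(0.3, 4))
  expect_equal(loss_vox(g2, 1), 0)
  expect_error(loss_vox(g, 5), "out of range")
})

test_that("all losses match loop-based references on small random cases", {
  for (seed in 1:5) {
    set.seed(seed)
    A <- sample(2:3, 1)
    np <- sample(c(4, 9, 16), 1)
    side <- as.integer(sqrt(np))
    g <- matrix(runif(np * A), np, A)
    x <- runif(np)
    mu <- runif(A)
    a <- sample(A, 1)
    expect_equal(loss_rec(x, g, mu), ref_loss_rec(x, g, mu),
                 tolerance = 1e-10)
    expect_equal(loss_vox(g, a), ref_loss_vox(g, a), tolerance = 1e-10)
    rs <- rand_region_set(side, 3, seed + 100)
    lrs <- lapply(1:3, function(q) rand_lr(seed * 7 + q))
    centers <- c(66, 72, 78)[seq_len(A)]
    expect_equal(loss_reg(g, a, 2, rs, lrs, centers),
                 ref_loss_reg(g, a, 2, rs, lrs, centers),
                 tolerance = 1e-10)
    pr <- runif(6); pf <- runif(6)
    got <- loss_adv_brain(pr, pf)
    want <- ref_bce_pair(pr, pf)
    expect_equal(got$L_Db, want$disc, tolerance = 1e-10)
    expect_equal(got$gen_term, want$gen, tolerance = 1e-10)
  }
})

test_that("regional loss: hand case, zero-residual and size linearity", {
  # one region of size 50, A = 2, a = 1, LR = 0.9, sums 50 then 40
  rs <- structure(list(n = 1L, masks = list(matrix(TRUE, 50, 1)),
                       sizes = 50L, R = 1L, labels = "1"),
                  class = "region_set")
  lr9 <- structure(list(beta = c(stats::qlogis(0.9), 0, 0, 0),
                        fallback = FALSE), class = "regional_lr")
  g <- cbind(rep(1, 50), rep(0.8, 50))   # sums 50, 40
  want <- 50 * (0.9 - 40.1 / 50.1)^2
  expect_equal(loss_reg(g, 1, 0, rs, list(lr9), c(70, 75)), want,
               tolerance = 1e-9)
  # zero when generated ratios equal the predictions exactly
  ratio <- (40.1) / (50.1)
  lrx <- structure(list(beta = c(stats::qlogis(ratio), 0, 0, 0),
                        fallback = FALSE), class = "regional_lr")
  expect_equal(loss_reg(g, 1, 0, rs, list(lrx), c(70, 75)), 0,
               tolerance = 1e-12)
  # scaling the region size scales the loss
  rs2 <- rs; rs2$sizes <- 100L
  expect_equal(loss_reg(g, 1, 0, rs2, list(lr9), c(70, 75)), 2 * want,
               tolerance = 1e-9)
})

test_that("adversarial losses have their closed-form reference points", {
  # indifferent discriminator: 2 ln 2
  expect_equal(loss_adv_brain(rep(0.5, 4), rep(0.5, 4))$L_Db, 2 * log(2))
  expect_equal(loss_adv_latent(rep(0.5, 3), rep(0.5, 3))$L_Dz, 2 * log(2))
  # near-perfect discriminator: loss near 0
  expect_lt(loss_adv_brain(rep(1 - 1e-7, 4), rep(1e-7, 4))$L_Db, 1e-5)
  # generator term decreases as Db(fake) -> 1
  gts <- vapply(c(0.1, 0.5, 0.9, 0.99),
                function(p) loss_adv_brain(0.5, p)$gen_term, 0)
  expect_true(all(diff(gts) < 0))
  # equilibrium: optimal Dz on matched distributions gives ln 2 per term
  expect_equal(loss_adv_latent(0.5, 0.5)$enc_term, log(2))
  expect_error(loss_adv_brain(numeric(0), 0.5), "empty")
})

test_that("total loss is the exact weighted sum", {
  b <- list(rec = 5, vox = 2, reg = 3, Db = 4, Dz = 1)
  w0 <- c(w_reg = 0, w_vox = 0, w_b = 0, w_z = 0, w_rec = 0)
  expect_equal(loss_total(b, w0), 0)
  w1 <- c(w_reg = 1, w_vox = 1, w_b = 1, w_z = 1, w_rec = 1)
  expect_equal(loss_total(list(rec = 1, vox = 2, reg = 3, Db = 4, Dz = 5),
                          w1), 15)
  wt <- c(w_reg = 1.25, w_vox = 1.25, w_b = 0.002, w_z = 0.05, w_rec = 100)
  avg <- list(reg = 0.26, vox = 0.24, Db = 72.27, Dz = 12.34, rec = 0.003)
  # grid ranges were chosen so each weighted component is at most ~1
  expect_true(all(c(wt["w_reg"] * avg$reg, wt["w_vox"] * avg$vox,
                    wt["w_b"] * avg$Db, wt["w_z"] * avg$Dz,
                    wt["w_rec"] * avg$rec) <= 1))
  expect_error(loss_total(b, c(w_reg = -1, w_vox = 0, w_b = 0, w_z = 0,
                               w_rec = 0)), "negative")
})

test_that("analytic loss gradients match finite differences", {
  set.seed(77)
  np <- 16; A <- 3
  g <- matrix(runif(np * A, 0.2, 0.8), np, A)
  x <- runif(np)
  mu <- runif(A)
  fd <- function(f, g) num_grad(function(v) f(matrix(v, np, A)),
                                as.numeric(g))
  expect_equal(as.numeric(atrophynet:::grad_loss_rec(x, g, mu)),
               fd(function(gm) loss_rec(x, gm, mu), g), tolerance = 1e-6)
  expect_equal(as.numeric(atrophynet:::grad_loss_vox(g, 2)),
               fd(function(gm) loss_vox(gm, 2), g), tolerance = 1e-6)
  rs <- rand_region_set(4, 2, 5)
  lrs <- list(rand_lr(1), rand_lr(2))
  centers <- c(66, 72, 78)
  expect_equal(
    as.numeric(atrophynet:::grad_loss_reg(g, 2, 1, rs, lrs, centers)),
    fd(function(gm) loss_reg(gm, 2, 1, rs, lrs, centers), g),
    tolerance = 1e-6)
})
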