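test_that("cross-slice smoothing has Gaussian weights and boundary rules", {
  # constant stacks pass through unchanged (weights sum to 1)
  cst <- matrix(0.4, 10, 6)
  expect_equal(smooth_slices(cst), cst)
  # impulse response at interior slices recovers the weight profile
  imp <- matrix(0, 4, 9); imp[, 5] <- 1
  sm <- smooth_slices(imp, sigma = 1.5, half_width = 2)
  w <- sm[1, 3:7]
  expect_equal(w[3] / w[2], 1 / exp(-1 / 4.5), tolerance = 1e-10)
  expect_equal(w[3] / w[1], 1 / exp(-4 / 4.5), tolerance = 1e-10)
  expect_equal(w[2], w[4]); expect_equal(w[1], w[5])
  # boundary: first slice mixes only in-range neighbours, renormalized
  imp0 <- matrix(0, 4, 5); imp0[, 1] <- 1
  sm0 <- smooth_slices(imp0)
  wts <- exp(-(0:2)^2 / 4.5)
  expect_equal(sm0[1, 1], wts[1] / sum(wts), tolerance = 1e-10)
  # linearity and range preservation
  set.seed(61)
  a <- matrix(runif(40), 8, 5); b <- matrix(runif(40), 8, 5)
  expect_equal(smooth_slices(a + 2 * b), smooth_slices(a) + 2 * smooth_slices(b))
  sm <- smooth_slices(a)
  expect_true(all(sm >= min(a) - 1e-12 & sm <= max(a) + 1e-12))
  # 3D arrays keep their shape
  arr <- array(runif(64), c(4, 4, 4))
  expect_equal(dim(smooth_slices(arr)), c(4, 4, 4))
  expect_error(smooth_slices(matrix(0, 3, 0)), "empty")
})

test_that("common initialization is deterministic and honours iters = 0", {
  pp <- tiny_prepped()
  bank <- tiny_bank()
  mcfg <- tiny_mconfig()
  tcfg <- tiny_tconfig()
  data2 <- list(X = vapply(pp$stacks, function(s) as.numeric(s$slices[, , 2]),
                           numeric(256)),
                theta = pp$meta$age, dx = pp$meta$dx)
  # iters = 0: exactly the seeded random initialization
  m0 <- common_init(data2, mcfg, tcfg, pwf_params(), pp$binning,
                    pp$region_sets[[2]], bank$regressors[[2]], iters = 0)
  expect_identical(atrophynet:::net_params(m0$E),
                   atrophynet:::net_params(build_models(mcfg)$E))
  i1 <- common_init(data2, mcfg, tcfg, pwf_params(), pp$binning,
                    pp$region_sets[[2]], bank$regressors[[2]], iters = 3)
  i2 <- common_init(data2, mcfg, tcfg, pwf_params(), pp$binning,
                    pp$region_sets[[2]], bank$regressors[[2]], iters = 3)
  for (net in c("E", "G", "Db", "Dz"))
    expect_identical(atrophynet:::net_params(i1[[net]]),
                     atrophynet:::net_params(i2[[net]]))
  # training moved the weights
  expect_false(identical(atrophynet:::net_params(i1$E),
                         atrophynet:::net_params(m0$E)))
  expect_error(common_init(list(X = matrix(0, 4, 0), theta = numeric(0),
                                dx = integer(0)),
                           mcfg, tcfg, pwf_params(), pp$binning,
                           pp$region_sets[[2]], bank$regressors[[2]]),
               "empty")
})

test_that("slice training logs every epoch with its schedule weights", {
  pm <- tiny_model()
  tcfg <- tiny_tconfig()
  log <- pm$loss_log
  expect_equal(nrow(log), 3 * tcfg$epochs)      # T = 3 slices
  expect_equal(sort(unique(log$slice)), 1:3)
  expect_equal(sort(unique(log$epoch)), 0:(tcfg$epochs - 1))
  sched <- pwf_schedule(pm$pwf, tcfg$epochs)
  for (cn in c("w_rec", "w_reg", "w_vox", "w_b", "w_z"))
    expect_equal(log[[cn]][log$slice == 1], sched[[cn]])
  expect_true(all(is.finite(log$tot)))
  expect_equal(length(pm$slice_models), 3)
})

test_that("re-training one slice reproduces its weights bit for bit", {
  pp <- tiny_prepped()
  bank <- tiny_bank()
  pm <- tiny_model()
  mcfg <- tiny_mconfig()
  tcfg <- tiny_tconfig()
  init <- common_init(
    list(X = vapply(pp$stacks, function(s) as.numeric(s$slices[, , 2]),
                    numeric(256)),
         theta = pp$meta$age, dx = pp$meta$dx),
    mcfg, tcfg, pwf_params(), pp$binning, pp$region_sets[[2]],
    bank$regressors[[2]])
  data1 <- list(X = vapply(pp$stacks, function(s) as.numeric(s$slices[, , 1]),
                           numeric(256)),
                theta = pp$meta$age, dx = pp$meta$dx)
  redo <- train_slice_model(1, data1, init, pwf_params(),
                            bank$regressors[[1]], pp$region_sets[[1]],
                            pp$binning, tcfg)
  for (net in c("E", "G", "Db", "Dz"))
    expect_identical(atrophynet:::net_params(redo$models[[net]]),
                     atrophynet:::net_params(pm$slice_models[[1]][[net]]))
})
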