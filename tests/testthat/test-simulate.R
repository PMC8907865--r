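test_that("personalization fine-tunes the slice models and nothing else", {
  pm <- tiny_model()
  srm <- tiny_sr()
  coh <- tiny_cohort()
  sub <- coh$subjects[[1]]
  vol <- sub$scans[[1]]$volume
  # iters = 0 is a no-op
  expect_identical(personalize(pm, vol, sub$scans[[1]]$age, sub$dx,
                               iters = 0), pm)
  h0 <- atrophynet:::sr_hash(srm)
  pmp <- personalize(pm, vol, sub$scans[[1]]$age, sub$dx, iters = 5)
  # restoration weights untouched (freeze contract)
  expect_identical(atrophynet:::sr_hash(srm), h0)
  # slice-model weights moved
  expect_false(identical(atrophynet:::net_params(pmp$slice_models[[1]]$E),
                         atrophynet:::net_params(pm$slice_models[[1]]$E)))
  # reconstruction of the baseline at its own bin improves
  st <- normalize_slices(vol, pm$n_slices)
  bin <- assign_bin(pm$binning, sub$scans[[1]]$age)
  rec_mse <- function(model) {
    tot <- 0
    for (n in seq_len(model$n_slices)) {
      g <- generate_sequence(model$slice_models[[n]], st$slices[, , n],
                             sub$dx)
      tot <- tot + mean((g[, bin] - as.numeric(st$slices[, , n]))^2)
    }
    tot / model$n_slices
  }
  expect_lt(rec_mse(pmp), rec_mse(pm))
})

test_that("simulated sequences are deterministic, bounded and complete", {
  pm <- tiny_model()
  srm <- tiny_sr()
  coh <- tiny_cohort()
  sub <- coh$subjects[[2]]
  vol <- sub$scans[[1]]$volume
  res <- simulate_sequence(pm, vol, sub$scans[[1]]$age, sub$dx, sr = srm)
  expect_s3_class(res, "simulation_result")
  expect_equal(length(res$volumes), pm$model_config$n_age_bins)
  expect_equal(res$ages, pm$binning$centers)
  expect_true(all(diff(res$ages) > 0))
  for (v in res$volumes) expect_equal(dim(v), c(16, 16, 3))
  res2 <- simulate_sequence(pm, vol, sub$scans[[1]]$age, sub$dx, sr = srm)
  expect_identical(res$volumes, res2$volumes)
  # de-normalized outputs live in each input slice's intensity range
  st <- normalize_slices(vol, pm$n_slices)
  for (v in res$volumes) {
    for (j in seq_len(3)) {
      rng <- range(vol[, , st$slice_index[j]])
      expect_gte(min(v[, , j]), rng[1] - 1e-9)
      expect_lte(max(v[, , j]), rng[2] + 1e-9)
    }
  }
})

test_that("age interpolation is exactly linear between bin centres", {
  m <- c(66, 70, 74)
  vols <- lapply(c(1, 2, 4), function(k) array(k * 0.1, c(4, 4, 2)))
  res <- structure(list(volumes = vols, ages = m, theta = 67, d = 1),
                   class = "simulation_result")
  # endpoints are returned exactly
  expect_identical(interpolate_age(res, 66), vols[[1]])
  expect_identical(interpolate_age(res, 74), vols[[3]])
  # midpoint equals the voxel-wise average, checked against a loop
  mid <- interpolate_age(res, 68)
  want <- vols[[1]]
  for (i in seq_along(want)) want[i] <- (vols[[1]][i] + vols[[2]][i]) / 2
  expect_equal(mid, want)
  # general lambda for constant volumes
  v <- interpolate_age(res, 73)
  lam <- (73 - 70) / 4
  expect_equal(v[1, 1, 1], (1 - lam) * 0.2 + lam * 0.4, tolerance = 1e-12)
  expect_error(interpolate_age(res, 60), "extrapolation")
  expect_error(interpolate_age(res, 75), "extrapolation")
})

test_that("the fitted simulator object exposes the modelling interface", {
  pm <- tiny_model()
  coh <- tiny_cohort()
  fit <- structure(list(model = pm, sr = tiny_sr(), lr_bank = tiny_bank(),
                        binning = pm$binning, n_scans = 19, n_subjects = 8,
                        call = quote(atrophynet())),
                   class = "atrophynet")
  expect_output(print(fit), "progression simulator")
  expect_output(print(summary(fit)), "final-epoch loss weights")
  cf <- coef(fit)
  expect_true(all(c("slice", "region", "age_gap", "fallback") %in%
                    names(cf)))
  expect_equal(nrow(cf), sum(lengths(fit$lr_bank$regressors)))
  sub <- coh$subjects[[1]]
  res <- simulate(fit, newdata = sub$scans[[1]]$volume,
                  age = sub$scans[[1]]$age, d = sub$dx,
                  personalize_iters = 2)
  expect_s3_class(res, "simulation_result")
  pv <- predict(fit, newdata = sub$scans[[1]]$volume,
                age = sub$scans[[1]]$age, d = sub$dx,
                ages = fit$binning$centers[2], personalize_iters = 2)
  expect_equal(length(pv), 1)
  expect_equal(dim(pv[[1]]), c(16, 16, 3))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
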