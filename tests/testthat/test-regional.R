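# hand-built two-scan "cohort" wrapper with known slice values, enough for
# the ratio-extraction contract
fake_prepped <- function(vals1, vals2, mask) {
  mk <- function(v, age) {
    structure(list(slices = array(v, c(nrow(mask), ncol(mask), 1)),
                   subject_id = "s1", age = age), class = "slice_stack")
  }
  structure(list(stacks = list(mk(vals1, 70), mk(vals2, 72)),
                 meta = data.frame(subject_id = c("s1", "s1"),
                                   age = c(70, 72), dx = c(2, 2)),
                 region_sets = list(structure(list(n = 1, masks = list(mask),
                                                   sizes = sum(mask), R = 1L,
                                                   labels = "1"),
                                              class = "region_set")),
                 n_slices = 1L, image_dim = dim(mask)),
            class = "prepped_cohort")
}

test_that("ratio extraction matches hand arithmetic and pair counting", {
  mask <- matrix(FALSE, 4, 4); mask[1:2, 1:2] <- TRUE
  v1 <- matrix(0, 4, 4); v1[mask] <- 12.5      # region sum 50
  v2 <- matrix(0, 4, 4); v2[mask] <- 10        # region sum 40
  smp <- extract_ratio_samples(fake_prepped(v1, v2, mask), 1, 1)
  expect_equal(nrow(smp), 1)
  expect_equal(smp$ratio, 40.1 / 50.1, tolerance = 1e-12)
  expect_equal(smp$o, 70); expect_equal(smp$a, 72); expect_equal(smp$d, 2)
  # identical scans give ratio exactly 1
  smp1 <- extract_ratio_samples(fake_prepped(v1, v1, mask), 1, 1)
  expect_equal(smp1$ratio, 1)
  # a 3-scan subject yields C(3,2) = 3 ordered pairs
  pp <- tiny_prepped()
  sid <- names(which(table(pp$meta$subject_id) == 3))[1]
  if (!is.na(sid)) {
    smp3 <- extract_ratio_samples(pp, 1, 1)
    expect_equal(sum(smp3$subject == sid), 3)
    expect_true(all(smp3$a > smp3$o))
  }
})

test_that("monotone filtering drops only increasing ratios, in order", {
  smp <- data.frame(o = 1:4, a = 2:5, d = 0, ratio = c(0.9, 1.1, 1.0, 0.8))
  expect_equal(monotone_filter(smp)$ratio, c(0.9, 1.0, 0.8))
  ok <- data.frame(ratio = c(0.5, 1.0))
  expect_identical(monotone_filter(ok), ok)
  expect_equal(nrow(monotone_filter(data.frame(ratio = c(1.2, 1.01)))), 0)
  expect_lte(nrow(monotone_filter(smp)), nrow(smp))
})

test_that("regressor fitting recovers the generative decline", {
  spec <- tiny_spec(n_subjects = 30, volume_shape = c(4, 16, 16),
                    visits_per_subject = c(3, 3), noise_sd = 0, seed = 202L)
  pp <- prep_cohort(generate_cohort(spec), n_slices = 3, n_bins = 3,
                    radii = integer(0))
  bank <- fit_regressor_bank(pp)
  errs <- c()
  for (n in 1:3) for (q in seq_along(bank$regressors[[n]])) {
    smp <- extract_ratio_samples(pp, n, q)
    pred <- predict_ratio(bank$regressors[[n]][[q]], smp$o, smp$a, smp$d)
    errs <- c(errs, abs(pred - regional_decline(smp$o, smp$a, smp$d,
                                                spec$atrophy_params)))
  }
  expect_lt(mean(errs), 0.02)
  # severity ordering: kappa increases with d, so predictions must too
  lr <- bank$regressors[[2]][[1]]
  expect_lte(predict_ratio(lr, 70, 80, 3), predict_ratio(lr, 70, 80, 0))
})

test_that("regressor edge cases: fallback, constant fit, contract", {
  few <- data.frame(o = c(70, 71), a = c(72, 73), d = 0, ratio = c(0.9, 0.9))
  lr <- fit_regressor(few)
  expect_true(lr$fallback)
  expect_equal(predict_ratio(lr, 65, 85, 3), 1)
  ones <- data.frame(o = 70 + 1:6, a = 72 + 1:6, d = rep(0:1, 3), ratio = 1)
  lr1 <- fit_regressor(ones)
  expect_equal(predict_ratio(lr1, 70, 75, 0), 1, tolerance = 1e-3)
  # zero-gap constraint and interval validation
  smp <- data.frame(o = runif(20, 63, 80), d = sample(0:3, 20, TRUE))
  smp$a <- smp$o + runif(20, 0.5, 5)
  smp$ratio <- regional_decline(smp$o, smp$a, smp$d)
  lr2 <- fit_regressor(monotone_filter(smp))
  expect_identical(predict_ratio(lr2, 70, 70, 2), 1)
  expect_error(predict_ratio(lr2, 70, 69, 2), "invalid interval")
  p <- predict_ratio(lr2, 70, seq(70, 85, 0.5), 2)
  expect_true(all(p > 0 & p <= 1))
  if (lr2$beta[3] <= 0) expect_true(all(diff(p) <= 1e-12))
})
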