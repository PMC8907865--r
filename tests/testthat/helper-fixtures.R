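# Shared fixtures, built once per test run and memoized; all sizes are
# deliberately tiny so the full suite stays fast.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 8, volume_shape = c(4, 16, 16),
         n_regions_per_slice = 4, visits_per_subject = c(2, 3),
         noise_sd = 0.01, seed = 101L),
    list(...))
  do.call(cohort_spec, args)
}

tiny_cohort <- function() memo("cohort", function() generate_cohort(tiny_spec()))

tiny_prepped <- function() memo("prepped", function()
  prep_cohort(tiny_cohort(), n_slices = 3, n_bins = 3, radii = 1L))

tiny_bank <- function() memo("bank", function()
  fit_regressor_bank(tiny_prepped()))

tiny_mconfig <- function() model_config(image_size = 16, latent_dim = 8,
                                        n_age_bins = 3, base_filters = 4,
                                        seed = 7L)

tiny_tconfig <- function(...) {
  args <- utils::modifyList(
    list(epochs = 6, batch_size = 10, common_init_iters = 5, seed = 9L,
         personalize_iters = 3),
    list(...))
  do.call(train_config, args)
}

# one small trained progression model shared by the train / sr / simulate
# tests (~20 s to build)
tiny_model <- function() memo("model", function()
  train_all(tiny_prepped(), tiny_bank(), tiny_mconfig(), tiny_tconfig()))

tiny_sr <- function() memo("sr", function()
  train_sr(make_sr_pairs(tiny_model(), tiny_prepped()), n_filters = 4,
           patch = 8, epochs = 5, seed = 13L))

# a small region set on an 8x8 slice with 4 quadrant labels
quadrant_atlas <- function(n = 8) {
  a <- matrix(0L, n, n)
  h <- n / 2
  a[1:h, 1:h] <- 1L; a[1:h, (h + 1):n] <- 2L
  a[(h + 1):n, 1:h] <- 3L; a[(h + 1):n, (h + 1):n] <- 4L
  a
}
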