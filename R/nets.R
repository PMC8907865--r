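# The four networks of one slice model: encoder E (image -> latent),
# generator G (latent + age-bin + diagnosis one-hots -> image), image
# discriminator Db (patch-style convolutional) and latent discriminator Dz
# (MLP). Built on the conv/backprop core in nn.R; capacity scales with the
# image size so that small desk configurations train in seconds.

#' Model configuration
#'
#' @param image_size square slice size in pixels; a power of two >= 16
#'   (default 128).
#' @param latent_dim latent space size (default 200).
#' @param n_age_bins number of age bins A conditioning the generator.
#' @param n_diagnoses number of diagnosis codes (4).
#' @param base_filters filters in the first conv layer; doubled at each
#'   stride-2 stage (capped at 8x).
#' @param seed RNG seed for parameter initialization.
#' @return object of class `model_config`.
#' @export
model_config <- function(image_size = 128L, latent_dim = 200L,
                         n_age_bins = 10L, n_diagnoses = 4L,
                         base_filters = 32L, seed = 1L) {
  if (image_size < 16L || bitwAnd(image_size, image_size - 1L) != 0L)
    stop("image_size must be a power of two >= 16")
  if (latent_dim < 2L) stop("latent_dim must be >= 2")
  structure(list(image_size = as.integer(image_size),
                 latent_dim = as.integer(latent_dim),
                 n_age_bins = as.integer(n_age_bins),
                 n_diagnoses = as.integer(n_diagnoses),
                 base_filters = as.integer(base_filters),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build the four networks of a slice model
#'
#' Deterministic for a fixed seed. The encoder is a stride-2 conv stack
#' ending in a tanh dense layer (latents in [-1,1], matching the uniform
#' prior's support); the generator mirrors it with transpose convolutions
#' and a sigmoid output in [0,1]; Db is a conv stack producing patch
#' logits; Dz a 3-layer MLP on latents. Conditioning is by concatenating
#' one-hot age-bin and diagnosis codes to the latent vector.
#'
#' @param config a `model_config`.
#' @return object of class `model_set` with elements E, G, Db, Dz, config.
#' @export
build_models <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  sz <- config$image_size
  n_down <- as.integer(log2(sz / 4))
  nf <- config$base_filters
  chans <- pmin(nf * 2^(seq_len(n_down) - 1L), nf * 8L)
  plans <- lapply(seq_len(n_down), function(i)
    conv_plan(rep(sz / 2^(i - 1L), 2L), k = 3L, stride = 2L, pad = 1L))
  c_in <- c(1L, chans[-n_down])

  enc_layers <- lapply(seq_len(n_down), function(i)
    layer_conv(plans[[i]], c_in[i], chans[i], "lrelu"))
  enc_layers[[n_down + 1L]] <-
    layer_dense(16L * chans[n_down], config$latent_dim, "tanh",
                w_scale = sqrt(1 / (16 * chans[n_down])))
  E <- net_new(enc_layers)

  cond_dim <- config$latent_dim + config$n_age_bins + config$n_diagnoses
  gen_layers <- list(layer_dense(cond_dim, 16L * chans[n_down], "lrelu"))
  for (i in rev(seq_len(n_down))) {
    cout <- if (i == 1L) 1L else chans[i - 1L]
    act <- if (i == 1L) "sigmoid" else "lrelu"
    gen_layers[[length(gen_layers) + 1L]] <-
      layer_convT(plans[[i]], chans[i], cout, act)
  }
  G <- net_new(gen_layers)

  n_disc <- min(n_down, 3L)
  db_layers <- lapply(seq_len(n_disc), function(i)
    layer_conv(plans[[i]], c_in[i], chans[i], "lrelu"))
  last_sz <- sz / 2^n_disc
  db_layers[[n_disc + 1L]] <-
    layer_conv(conv_plan(rep(last_sz, 2L), 3L, 1L, 1L), chans[n_disc], 1L,
               "linear", w_scale = sqrt(1 / (9 * chans[n_disc])))
  Db <- net_new(db_layers)

  Dz <- net_new(list(layer_dense(config$latent_dim, 64L, "lrelu"),
                     layer_dense(64L, 64L, "lrelu"),
                     layer_dense(64L, 1L, "linear", w_scale = 0.05)))

  structure(list(E = E, G = G, Db = Db, Dz = Dz, config = config),
            class = "model_set")
}

one_hot <- function(i, n) { v <- numeric(n); v[i] <- 1; v }

# conditioned generator input: latent columns + one-hot age bin + diagnosis
gen_input <- function(z, i, d, config) {
  B <- ncol(z)
  rbind(z, matrix(one_hot(i, config$n_age_bins), config$n_age_bins, B),
        matrix(one_hot(d + 1L, config$n_diagnoses), config$n_diagnoses, B))
}

# discriminator probabilities (patch-wise for Db, scalar for Dz)
db_prob <- function(models, x) {
  logits <- net_forward(models$Db, as.matrix(x))$out
  1 / (1 + exp(-logits))
}

dz_prob <- function(models, z) {
  logits <- net_forward(models$Dz, as.matrix(z))$out
  1 / (1 + exp(-logits))
}

# uniform latent prior on [-1, 1]^latent_dim
sample_prior <- function(config, B) {
  matrix(stats::runif(config$latent_dim * B, -1, 1), config$latent_dim, B)
}

#' Generate the age-conditioned output sequence of one slice
#'
#' Encodes the input slice once and decodes it at every age bin with the
#' diagnosis held fixed: G(E(x), i, d) for i in 1..A.
#'
#' @param models a `model_set`.
#' @param x input slice: matrix image_size x image_size (or a pixel vector),
#'   values in [0,1].
#' @param d diagnosis code 0-3.
#' @return n_pixels x A matrix of generated outputs, each column in [0,1].
#' @export
generate_sequence <- function(models, x, d) {
  config <- models$config
  np <- config$image_size^2
  x <- matrix(as.numeric(x), ncol = 1)
  if (nrow(x) != np) stop("input slice does not match image_size")
  if (!d %in% 0:(config$n_diagnoses - 1L)) stop("invalid diagnosis code")
  z <- net_forward(models$E, x)$out
  out <- matrix(0, np, config$n_age_bins)
  for (i in seq_len(config$n_age_bins))
    out[, i] <- net_forward(models$G, gen_input(z, i, d, config))$out
  out
}
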