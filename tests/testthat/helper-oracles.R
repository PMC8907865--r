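# Independent loop-based reference implementations of the loss terms,
# written directly from their definitions with explicit loops and no shared
# code with the package internals. Used to pin the vectorized versions.

ref_mse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s / length(a)
}

ref_loss_rec <- function(x, g_seq, mu) {
  tot <- 0
  for (i in seq_len(ncol(g_seq))) tot <- tot + mu[i] * ref_mse(x, g_seq[, i])
  tot
}

ref_loss_vox <- function(g_seq, a) {
  A <- ncol(g_seq)
  np <- nrow(g_seq)
  terms <- c()
  if (a > 1) {
    lo <- rep(Inf, np)
    for (i in 1:(a - 1)) for (p in 1:np) lo[p] <- min(lo[p], g_seq[p, i])
    terms <- c(terms, ref_mse(g_seq[, a], lo))
  }
  if (a < A) {
    hi <- rep(-Inf, np)
    for (i in (a + 1):A) for (p in 1:np) hi[p] <- max(hi[p], g_seq[p, i])
    terms <- c(terms, ref_mse(g_seq[, a], hi))
  }
  if (length(terms) == 0) 0 else sum(terms) / length(terms)
}

ref_loss_reg <- function(g_seq, a, d, region_set, regressors, centers,
                         eps = 0.1) {
  A <- ncol(g_seq)
  tot <- 0
  for (q in seq_len(region_set$R)) {
    mask <- region_set$masks[[q]]
    sums <- numeric(A)
    for (i in seq_len(A)) {
      s <- 0
      for (p in which(as.logical(mask))) s <- s + g_seq[p, i]
      sums[i] <- s
    }
    for (o in seq_len(A)) {
      if (o == a) next
      if (o < a) {
        pred <- predict_ratio(regressors[[q]], centers[o], centers[a], d)
        gen <- (sums[a] + eps) / (sums[o] + eps)
      } else {
        pred <- predict_ratio(regressors[[q]], centers[a], centers[o], d)
        gen <- (sums[o] + eps) / (sums[a] + eps)
      }
      tot <- tot + region_set$sizes[q] * (pred - gen)^2
    }
  }
  tot / (region_set$R * (A - 1))
}

ref_bce_pair <- function(p_real, p_fake) {
  cl <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)
  d <- 0
  for (p in cl(p_real)) d <- d - log(p) / length(p_real)
  for (p in cl(p_fake)) d <- d - log(1 - p) / length(p_fake)
  g <- 0
  for (p in cl(p_fake)) g <- g - log(p) / length(p_fake)
  list(disc = d, gen = g)
}

# random region sets / regressors for loss tests
rand_region_set <- function(np_side, R, seed) {
  set.seed(seed)
  masks <- lapply(seq_len(R), function(q) {
    m <- matrix(runif(np_side^2) < 0.5, np_side, np_side)
    if (!any(m)) m[1, 1] <- TRUE
    m
  })
  structure(list(n = 1L, masks = masks, sizes = vapply(masks, sum, 0L),
                 R = R, labels = as.character(seq_len(R))),
            class = "region_set")
}

rand_lr <- function(seed) {
  set.seed(seed)
  structure(list(beta = c(rnorm(1, 2, 0.5), rnorm(1, 0, 0.01),
                          -abs(rnorm(1, 0.1, 0.05)), rnorm(1, 0, 0.05)),
                 fallback = FALSE, n_samples = 10L, rms = 0),
            class = "regional_lr")
}

# finite-difference gradient of a scalar function at x
num_grad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
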