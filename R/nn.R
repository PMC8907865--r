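# Minimal neural-network core: dense, strided convolution and transpose
# convolution (2D/3D) with exact adjoint backpropagation, leaky-ReLU /
# sigmoid / tanh activations, and an Adam optimiser. Image batches are
# stored as matrices of shape (n_spatial * n_channels, batch) with the
# spatial index fastest, then channel; all convolutions are expressed
# through a precomputed sparse gather operator S so that the transpose
# convolution is literally the adjoint t(S) of the matching convolution.

#' Build a convolution index plan
#'
#' Precomputes the sparse patch-gather operator for a (possibly strided,
#' zero-padded) convolution over a 2D or 3D grid. The same plan serves the
#' forward convolution, its gradient, and the matching transpose
#' convolution (which uses the adjoint operator).
#'
#' @param sp_in integer vector of input spatial dimensions (length 2 or 3).
#' @param k kernel width (same in every dimension).
#' @param stride stride (same in every dimension).
#' @param pad zero padding (same in every dimension).
#' @return a list with the operator `S`, spatial sizes and kernel volume.
#' @keywords internal
conv_plan <- function(sp_in, k = 3L, stride = 1L, pad = 1L) {
  nd <- length(sp_in)
  stopifnot(nd %in% c(2L, 3L), all(sp_in >= 1L))
  sp_out <- (sp_in + 2L * pad - k) %/% stride + 1L
  if (any(sp_out < 1L)) stop("conv_plan: kernel larger than padded input")
  K <- k^nd
  P <- prod(sp_out)
  # multi-indices (0-based) for output positions and kernel offsets
  grid0 <- function(dims) {
    idx <- lapply(dims, function(d) 0:(d - 1L))
    as.matrix(expand.grid(idx))  # first dim fastest
  }
  pos <- grid0(sp_out)                     # P x nd
  off <- grid0(rep(k, nd))                 # K x nd
  # input coordinate for (p, kk): pos*stride + off - pad, per dimension
  ii <- integer(0); jj <- integer(0)
  in_mult <- cumprod(c(1L, sp_in[-nd]))    # linearisation multipliers
  for (kk in seq_len(K)) {
    coord <- sweep(pos * stride, 2L, off[kk, ] - pad, `+`)  # P x nd, 0-based
    ok <- rowSums(coord < 0L) == 0L & rowSums(sweep(coord, 2L, sp_in, `>=`)) == 0L
    if (!any(ok)) next
    lin <- as.integer(coord[ok, , drop = FALSE] %*% in_mult) + 1L
    rows <- (which(ok) - 1L) * K + kk      # row order: kernel fastest, position slow
    ii <- c(ii, rows); jj <- c(jj, lin)
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(P * K, prod(sp_in)))
  list(S = S, sp_in = sp_in, sp_out = sp_out, n_in = prod(sp_in),
       P = P, K = K, k = k, stride = stride, pad = pad)
}

act_fwd <- function(x, act) {
  switch(act,
         linear  = x,
         lrelu   = { x[x < 0] <- x[x < 0] * 0.2; x },
         sigmoid = 1 / (1 + exp(-x)),
         tanh    = tanh(x),
         stop("unknown activation: ", act))
}

act_bwd <- function(dy, y, act) {
  switch(act,
         linear  = dy,
         lrelu   = dy * ifelse(y > 0, 1, 0.2),
         sigmoid = dy * y * (1 - y),
         tanh    = dy * (1 - y^2),
         stop("unknown activation: ", act))
}

layer_dense <- function(n_in, n_out, act = "lrelu", w_scale = NULL) {
  if (is.null(w_scale)) w_scale <- sqrt(2 / n_in)
  list(type = "dense", act = act,
       W = matrix(stats::rnorm(n_out * n_in, sd = w_scale), n_out, n_in),
       b = numeric(n_out))
}

layer_conv <- function(plan, c_in, c_out, act = "lrelu", w_scale = NULL) {
  if (is.null(w_scale)) w_scale <- sqrt(2 / (plan$K * c_in))
  list(type = "conv", act = act, plan = plan, cin = c_in, cout = c_out,
       W = matrix(stats::rnorm(c_out * plan$K * c_in, sd = w_scale),
                  c_out, plan$K * c_in),
       b = numeric(c_out))
}

# Transpose convolution mapping the plan's *output* grid back to its *input*
# grid (upsampling when the plan is strided). Weights: (c_in x K*c_out).
layer_convT <- function(plan, c_in, c_out, act = "lrelu", w_scale = NULL) {
  if (is.null(w_scale)) w_scale <- sqrt(2 / (plan$K * c_in))
  list(type = "convT", act = act, plan = plan, cin = c_in, cout = c_out,
       W = matrix(stats::rnorm(c_in * plan$K * c_out, sd = w_scale),
                  c_in, plan$K * c_out),
       b = numeric(c_out))
}

layer_fwd <- function(layer, X) {
  B <- ncol(X)
  if (layer$type == "dense") {
    Z <- layer$W %*% X + layer$b
    Y <- act_fwd(Z, layer$act)
    return(list(Y = Y, cache = list(X = X, Y = Y)))
  }
  p <- layer$plan
  if (layer$type == "conv") {
    Xr <- matrix(X, p$n_in, layer$cin * B)
    Cm <- as.matrix(p$S %*% Xr)                          # (P*K, Cin*B)
    A <- aperm(array(Cm, c(p$K, p$P, layer$cin, B)), c(1, 3, 2, 4))
    cols <- matrix(A, p$K * layer$cin, p$P * B)
    Z <- layer$W %*% cols + layer$b                      # (Cout, P*B)
    Y <- matrix(aperm(array(Z, c(layer$cout, p$P, B)), c(2, 1, 3)),
                p$P * layer$cout, B)
    Y <- act_fwd(Y, layer$act)
    return(list(Y = Y, cache = list(cols = cols, Y = Y, B = B)))
  }
  if (layer$type == "convT") {
    # input lives on the plan's output grid (P), result on its input grid
    A <- matrix(aperm(array(X, c(p$P, layer$cin, B)), c(2, 1, 3)),
                layer$cin, p$P * B)
    M <- crossprod(layer$W, A)                           # (K*Cout, P*B)
    Mr <- matrix(aperm(array(M, c(p$K, layer$cout, p$P, B)), c(1, 3, 2, 4)),
                 p$P * p$K, layer$cout * B)
    Yr <- as.matrix(Matrix::crossprod(p$S, Mr))          # (n_in, Cout*B)
    Y <- matrix(Yr, p$n_in * layer$cout, B) + rep(layer$b, each = p$n_in)
    Y <- act_fwd(Y, layer$act)
    return(list(Y = Y, cache = list(A = A, Y = Y, B = B)))
  }
  stop("unknown layer type")
}

layer_bwd <- function(layer, cache, dY) {
  B <- ncol(dY)
  dY <- act_bwd(dY, cache$Y, layer$act)
  if (layer$type == "dense") {
    return(list(dX = crossprod(layer$W, dY),
                dW = tcrossprod(dY, cache$X), db = rowSums(dY)))
  }
  p <- layer$plan
  if (layer$type == "conv") {
    dZ <- matrix(aperm(array(dY, c(p$P, layer$cout, B)), c(2, 1, 3)),
                 layer$cout, p$P * B)
    dW <- tcrossprod(dZ, cache$cols)
    db <- rowSums(dZ)
    dcols <- crossprod(layer$W, dZ)                      # (K*Cin, P*B)
    dA <- matrix(aperm(array(dcols, c(p$K, layer$cin, p$P, B)), c(1, 3, 2, 4)),
                 p$P * p$K, layer$cin * B)
    dXr <- as.matrix(Matrix::crossprod(p$S, dA))         # (n_in, Cin*B)
    return(list(dX = matrix(dXr, p$n_in * layer$cin, B), dW = dW, db = db))
  }
  if (layer$type == "convT") {
    dYr <- matrix(dY, p$n_in, layer$cout * B)
    db <- rowSums(matrix(colSums(dYr), layer$cout, B))
    dMr <- as.matrix(p$S %*% dYr)                        # (P*K, Cout*B)
    dM <- matrix(aperm(array(dMr, c(p$K, p$P, layer$cout, B)), c(1, 3, 2, 4)),
                 p$K * layer$cout, p$P * B)
    dA <- layer$W %*% dM                                 # (Cin, P*B)
    dW <- tcrossprod(cache$A, dM)                        # (Cin, K*Cout)
    dX <- matrix(aperm(array(dA, c(layer$cin, p$P, B)), c(2, 1, 3)),
                 p$P * layer$cin, B)
    return(list(dX = dX, dW = dW, db = db))
  }
  stop("unknown layer type")
}

net_new <- function(layers) structure(list(layers = layers), class = "nn_net")

net_forward <- function(net, X) {
  caches <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    r <- layer_fwd(net$layers[[l]], X)
    caches[[l]] <- r$cache
    X <- r$Y
  }
  list(out = X, caches = caches)
}

net_backward <- function(net, caches, dOut) {
  L <- length(net$layers)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    g <- layer_bwd(net$layers[[l]], caches[[l]], dOut)
    grads[[l]] <- list(dW = g$dW, db = g$db)
    dOut <- g$dX
  }
  list(dX = dOut, grads = grads)
}

net_params <- function(net) {
  unlist(lapply(net$layers, function(l) c(l$W, l$b)))
}

net_set_params <- function(net, theta) {
  pos <- 0L
  for (l in seq_along(net$layers)) {
    nw <- length(net$layers[[l]]$W); nb <- length(net$layers[[l]]$b)
    net$layers[[l]]$W[] <- theta[pos + seq_len(nw)]; pos <- pos + nw
    net$layers[[l]]$b[] <- theta[pos + seq_len(nb)]; pos <- pos + nb
  }
  net
}

grads_flat <- function(grads) {
  unlist(lapply(grads, function(g) c(g$dW, g$db)))
}

#' @keywords internal
adam_new <- function(net, alpha = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  st <- lapply(net$layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  list(state = st, alpha = alpha, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L)
}

# Adam update with optional global-norm gradient clipping; returns both the
# updated network and optimiser state.
adam_step <- function(net, grads, opt, clip = 10) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g$dW^2) + sum(g$db^2), 0)))
  sc <- if (is.finite(gnorm) && gnorm > clip) clip / gnorm else 1
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr <- opt$alpha * sqrt(1 - b2^opt$t) / (1 - b1^opt$t)
  for (l in seq_along(net$layers)) {
    s <- opt$state[[l]]
    gW <- grads[[l]]$dW * sc; gb <- grads[[l]]$db * sc
    s$mW <- b1 * s$mW + (1 - b1) * gW; s$vW <- b2 * s$vW + (1 - b2) * gW^2
    s$mb <- b1 * s$mb + (1 - b1) * gb; s$vb <- b2 * s$vb + (1 - b2) * gb^2
    net$layers[[l]]$W <- net$layers[[l]]$W - corr * s$mW / (sqrt(s$vW) + opt$eps)
    net$layers[[l]]$b <- net$layers[[l]]$b - corr * s$mb / (sqrt(s$vb) + opt$eps)
    opt$state[[l]] <- s
  }
  list(net = net, opt = opt)
}
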