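# Profile weight functions: mean-reverting exponential schedules that assign
# each of the five losses an epoch-dependent weight,
# f_l(t) = rho^t * b_l + (1 - rho^t) * b_l * v^(d_l),
# so each weight starts at its shape parameter b_l and converges to the
# asymptote b_l * v^(d_l); the direction d_l = +-1 makes the profile ascend
# or descend by a factor v. Shape and direction parameters are chosen by a
# seeded random search on a grid, scored by the total validation loss.

pwf_losses <- c("reg", "vox", "b", "z", "rec")

#' Profile-weight-function parameters
#'
#' Defaults are the best grid-search values for the full-scale training
#' configuration: b_reg = b_vox = 1.25, b_b = 0.002, b_z = 0.05, b_rec = 100,
#' ascending direction (+1) for all losses except the reconstruction loss
#' (-1), rho = 0.99 and v = 10.
#'
#' @param b named numeric shape parameters (> 0) for reg, vox, b, z, rec.
#' @param d named directions, each -1 or +1.
#' @param rho per-epoch decay in (0, 1).
#' @param v condition factor (> 0): the asymptote/initial ratio is v^(d_l).
#' @return object of class `pwf_params`.
#' @export
pwf_params <- function(b = c(reg = 1.25, vox = 1.25, b = 0.002,
                             z = 0.05, rec = 100),
                       d = c(reg = 1, vox = 1, b = 1, z = 1, rec = -1),
                       rho = 0.99, v = 10) {
  b <- b[pwf_losses]; d <- d[pwf_losses]
  if (any(is.na(b)) || any(b <= 0)) stop("shape parameters must be > 0")
  if (!all(d %in% c(-1, 1))) stop("directions must be -1 or +1")
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  if (v <= 0) stop("v must be > 0")
  structure(list(b = b, d = d, rho = rho, v = v), class = "pwf_params")
}

#' Evaluate a profile weight function
#'
#' @param params a `pwf_params`.
#' @param loss one of "reg", "vox", "b", "z", "rec".
#' @param t epoch (integer >= 0); vectorized.
#' @return weight f_loss(t).
#' @export
pwf_value <- function(params, loss, t) {
  if (!loss %in% pwf_losses) stop("unknown loss key: ", loss)
  if (any(t < 0)) stop("epoch must be >= 0")
  b <- params$b[[loss]]
  asym <- b * params$v^params$d[[loss]]
  r <- params$rho^t
  r * b + (1 - r) * asym
}

#' Full per-epoch weight schedule
#'
#' @param params a `pwf_params`.
#' @param n_epochs number of rows (epochs t = 0 .. n_epochs - 1).
#' @return data.frame with columns epoch, w_reg, w_vox, w_b, w_z, w_rec.
#' @export
pwf_schedule <- function(params, n_epochs) {
  if (n_epochs < 1) stop("n_epochs must be >= 1")
  t <- seq_len(n_epochs) - 1L
  out <- data.frame(epoch = t)
  for (l in pwf_losses)
    out[[paste0("w_", l)]] <- pwf_value(params, l, t)
  out
}

# weight vector for one epoch, named as loss_total() expects
pwf_weights_at <- function(params, t) {
  w <- vapply(pwf_losses, function(l) pwf_value(params, l, t), 0)
  stats::setNames(w, paste0("w_", pwf_losses))
}

#' Default search grid for PWF parameters
#'
#' Shape ranges: b_reg, b_vox in [1, 2] step 0.25; b_b in [0.001, 0.004]
#' step 0.001; b_z in [0.05, 0.1] step 0.01; b_rec in [75, 175] step 25;
#' all directions in \{-1, +1\}.
#'
#' @return named list of candidate value vectors.
#' @export
pwf_default_grid <- function() {
  list(b_reg = seq(1, 2, by = 0.25), b_vox = seq(1, 2, by = 0.25),
       b_b = seq(0.001, 0.004, by = 0.001), b_z = seq(0.05, 0.1, by = 0.01),
       b_rec = seq(75, 175, by = 25),
       d_reg = c(-1, 1), d_vox = c(-1, 1), d_b = c(-1, 1), d_z = c(-1, 1),
       d_rec = c(-1, 1))
}

#' Random grid search over PWF parameters
#'
#' Draws parameter combinations uniformly without replacement from the
#' Cartesian grid (exhaustively when `n_draws` covers the grid) and keeps
#' the combination minimizing `eval_fn`.
#'
#' @param grid named list of candidate vectors; names `b_<loss>` and
#'   `d_<loss>` (missing entries fall back to the defaults of
#'   [pwf_params()]); optional `rho`, `v`.
#' @param n_draws number of evaluations (>= 1).
#' @param eval_fn function(pwf_params) -> validation total loss.
#' @param seed RNG seed for the draw.
#' @return list(best = `pwf_params`, best_value, trace = data.frame of all
#'   evaluated combinations and their scores).
#' @export
pwf_grid_search <- function(grid, n_draws, eval_fn, seed = 1L) {
  if (length(grid) == 0L || any(vapply(grid, length, 0L) == 0L))
    stop("empty grid")
  if (n_draws < 1) stop("n_draws must be >= 1")
  sizes <- vapply(grid, length, 0L)
  total <- prod(sizes)
  set.seed(seed)
  take <- min(n_draws, total)
  cells <- if (take == total) seq_len(total) else sample.int(total, take)
  decode <- function(cell) {
    cell <- cell - 1L
    out <- list()
    for (k in seq_along(grid)) {
      out[[names(grid)[k]]] <- grid[[k]][cell %% sizes[k] + 1L]
      cell <- cell %/% sizes[k]
    }
    out
  }
  as_params <- function(vals) {
    def <- pwf_params()
    b <- def$b; d <- def$d
    for (l in pwf_losses) {
      if (!is.null(vals[[paste0("b_", l)]])) b[[l]] <- vals[[paste0("b_", l)]]
      if (!is.null(vals[[paste0("d_", l)]])) d[[l]] <- vals[[paste0("d_", l)]]
    }
    pwf_params(b = b, d = d,
               rho = if (is.null(vals$rho)) def$rho else vals$rho,
               v = if (is.null(vals$v)) def$v else vals$v)
  }
  trace <- vector("list", length(cells))
  best <- NULL; best_value <- Inf
  for (i in seq_along(cells)) {
    vals <- decode(cells[i])
    p <- as_params(vals)
    score <- eval_fn(p)
    trace[[i]] <- data.frame(c(vals, list(value = score)))
    if (score < best_value) { best <- p; best_value <- score }
  }
  list(best = best, best_value = best_value, trace = do.call(rbind, trace))
}
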