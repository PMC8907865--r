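# Per-region sigmoid-link regressors predicting the ratio of regional
# intensity between two ages, conditioned on diagnosis. Fitted on
# longitudinal scan pairs after removing pairs where regional intensity
# increases (outliers under the monotone-atrophy assumption), they supply
# the regional targets for the region-level progression loss.

#' Extract regional intensity-ratio samples
#'
#' For every ordered scan pair (earlier age o, later age a) of every subject,
#' the ratio of summed region intensity on the normalized slice:
#' (sum at a + eps) / (sum at o + eps).
#'
#' @param prepped a `prepped_cohort`.
#' @param n slice index in 1..T.
#' @param q region index within the slice's `region_set`.
#' @param eps numerical guard added to both sums (default 0.1).
#' @return data.frame (subject, o, a, d, ratio), ordered by subject then pair.
#' @export
extract_ratio_samples <- function(prepped, n, q, eps = 0.1) {
  stopifnot(inherits(prepped, "prepped_cohort"))
  mask <- prepped$region_sets[[n]]$masks[[q]]
  sums <- vapply(prepped$stacks,
                 function(st) sum(st$slices[, , n][mask]), 0)
  meta <- prepped$meta
  out <- list()
  for (sid in unique(meta$subject_id)) {
    sel <- which(meta$subject_id == sid)
    if (length(sel) < 2L) next
    sel <- sel[order(meta$age[sel])]
    for (i in seq_len(length(sel) - 1L)) {
      for (j in seq(i + 1L, length(sel))) {
        out[[length(out) + 1L]] <- data.frame(
          subject = sid, o = meta$age[sel[i]], a = meta$age[sel[j]],
          d = meta$dx[sel[i]],
          ratio = (sums[sel[j]] + eps) / (sums[sel[i]] + eps))
      }
    }
  }
  if (length(out) == 0L)
    stop("insufficient data: no subject has two or more scans")
  do.call(rbind, out)
}

#' Drop pairs where regional intensity increased
#'
#' Rows with ratio > 1 are removed (outliers under monotone atrophy);
#' row order is preserved. May return an empty table.
#'
#' @param samples data.frame with a `ratio` column.
#' @return filtered data.frame.
#' @export
monotone_filter <- function(samples) samples[samples$ratio <= 1, , drop = FALSE]

#' Fit a regional intensity-ratio regressor
#'
#' Sigmoid-link regression of a bounded ratio: ratios are clipped to
#' [1e-4, 1 - 1e-4], logit-transformed and regressed by least squares on
#' (1, baseline age o, age gap a - o, diagnosis d). The zero-gap constraint
#' predict(o, o, d) = 1 is enforced in prediction rather than in the linear
#' predictor. With fewer than 4 samples the regressor falls back to the
#' identity predictor (always 1) and carries a warning flag.
#'
#' @param samples data.frame (o, a, d, ratio), normally already passed
#'   through [monotone_filter()].
#' @param n,q slice/region bookkeeping indices.
#' @return object of class `regional_lr` with `beta` (intercept,
#'   baseline-age, age-gap, diagnosis), `fallback`, `n_samples`, `rms`.
#' @export
fit_regressor <- function(samples, n = NA_integer_, q = NA_integer_) {
  if (nrow(samples) < 4L) {
    return(structure(list(n = n, q = q, beta = c(Inf, 0, 0, 0),
                          fallback = TRUE, n_samples = nrow(samples),
                          rms = NA_real_),
                     class = "regional_lr"))
  }
  r <- pmin(pmax(samples$ratio, 1e-4), 1 - 1e-4)
  y <- stats::qlogis(r)
  X <- cbind(1, samples$o, samples$a - samples$o, samples$d)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  structure(list(n = n, q = q, beta = unname(beta), fallback = FALSE,
                 n_samples = nrow(samples),
                 rms = sqrt(mean(fit$residuals^2))),
            class = "regional_lr")
}

#' Predict a regional intensity ratio
#'
#' Sigmoid of the linear predictor, clamped to (0, 1]; exactly 1 when
#' a == o. Vectorized over (o, a, d).
#'
#' @param lr a `regional_lr`.
#' @param o baseline age, years.
#' @param a follow-up age, years (>= o).
#' @param d diagnosis code 0-3.
#' @return predicted ratio in (0, 1].
#' @export
predict_ratio <- function(lr, o, a, d) {
  if (any(a < o)) stop("invalid interval: a < o")
  eta <- lr$beta[1] + lr$beta[2] * o + lr$beta[3] * (a - o) + lr$beta[4] * d
  p <- stats::plogis(eta)
  p <- pmax(pmin(p, 1), 1e-8)
  p[a == o] <- 1
  p
}

#' Fit the full bank of regional regressors
#'
#' One regressor per (slice n, region q), fitted on monotone-filtered ratio
#' samples extracted from the normalized slices.
#'
#' @param prepped a `prepped_cohort`.
#' @param eps numerical guard used in ratio extraction (default 0.1); the
#'   same value should be used when evaluating the regional loss.
#' @return object of class `lr_bank`: `regressors[[n]][[q]]`, `eps`.
#' @export
fit_regressor_bank <- function(prepped, eps = 0.1) {
  stopifnot(inherits(prepped, "prepped_cohort"))
  regs <- lapply(seq_len(prepped$n_slices), function(n) {
    rs <- prepped$region_sets[[n]]
    lapply(seq_len(rs$R), function(q) {
      smp <- monotone_filter(extract_ratio_samples(prepped, n, q, eps))
      fit_regressor(smp, n = n, q = q)
    })
  })
  structure(list(regressors = regs, eps = eps), class = "lr_bank")
}
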