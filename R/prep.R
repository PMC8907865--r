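# Pre-processing: extraction of the T central axial slices, invertible
# per-slice intensity normalization, age binning with fuzzy Gaussian
# membership, and atlas-region augmentation by morphological erosion and
# dilation. Volumes are arrays (height, width, depth) with the axial slice
# index on the third axis.

#' Extract and normalize axial slices
#'
#' Takes the `T` central axial slices of a volume and normalizes each
#' independently: standardisation to zero mean / unit standard deviation
#' (removing scanner gain and offset), then an affine map to [0, 1] via the
#' slice's own minimum and maximum. The composed affine map is recorded per
#' slice so the original intensities can be recovered exactly.
#'
#' @param volume 3D array (height, width, depth).
#' @param n_slices number of central axial slices T to keep (<= depth).
#' @param subject_id,age optional metadata carried on the result.
#' @return an object of class `slice_stack`: `slices` (H x W x T array in
#'   [0,1]), `records` (data.frame slice, shift, scale with
#'   original = normalized * scale + shift), `slice_index` (depth indices
#'   used), plus the metadata.
#' @export
normalize_slices <- function(volume, n_slices, subject_id = NA_character_,
                             age = NA_real_) {
  dims <- dim(volume)
  if (length(dims) != 3L) stop("volume must be a 3D array")
  depth <- dims[3]
  if (depth < n_slices) stop("volume depth ", depth, " < T = ", n_slices)
  start <- (depth - n_slices) %/% 2L
  idx <- start + seq_len(n_slices)
  out <- array(0, c(dims[1], dims[2], n_slices))
  shift <- numeric(n_slices); scale <- numeric(n_slices)
  for (j in seq_len(n_slices)) {
    sl <- volume[, , idx[j]]
    sdv <- stats::sd(sl)
    if (!is.finite(sdv) || sdv == 0)
      stop("degenerate scale: slice ", idx[j], " has constant intensity")
    z <- (sl - mean(sl)) / sdv
    zr <- range(z)
    out[, , j] <- (z - zr[1]) / (zr[2] - zr[1])
    # composition of the two affine maps: original = normalized*scale + shift
    rr <- range(sl)
    scale[j] <- rr[2] - rr[1]
    shift[j] <- rr[1]
  }
  structure(list(slices = out,
                 records = data.frame(slice = seq_len(n_slices),
                                      shift = shift, scale = scale),
                 slice_index = idx, subject_id = subject_id, age = age),
            class = "slice_stack")
}

#' Invert slice normalization
#'
#' @param stack a `slice_stack`.
#' @param slices optional replacement slice array of the same shape (e.g.
#'   model output) to map back to the original intensity scale.
#' @return 3D array on the original intensity scale.
#' @export
denormalize_slices <- function(stack, slices = stack$slices) {
  stopifnot(inherits(stack, "slice_stack"))
  out <- slices
  for (j in seq_len(dim(out)[3]))
    out[, , j] <- out[, , j] * stack$records$scale[j] + stack$records$shift[j]
  out
}

#' Build equal-width age bins
#'
#' Bins span the observed age range. Each bin's centre m_i is the mean age of
#' the samples falling in it (the bin midpoint when empty), delta_i is the
#' maximum age difference within the bin (the bin width when fewer than two
#' samples fall in it), and the fuzzy membership width is
#' sigma_i = width_factor * delta_i.
#'
#' @param ages numeric vector of ages (years).
#' @param n_bins bin count A (>= 2).
#' @param width_factor proportionality constant c in sigma_i = c * delta_i.
#' @return object of class `age_binning` with fields `A`, `edges`, `centers`,
#'   `delta`, `sigma`.
#' @export
build_age_bins <- function(ages, n_bins, width_factor = 1) {
  if (n_bins < 2L) stop("need at least 2 age bins")
  if (length(ages) < n_bins) stop("fewer ages than bins")
  rng <- range(ages)
  if (diff(rng) == 0) stop("degenerate age range: all ages equal")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(ages, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  width <- diff(rng) / n_bins
  centers <- delta <- numeric(n_bins)
  for (i in seq_len(n_bins)) {
    a <- ages[bin == i]
    centers[i] <- if (length(a)) mean(a) else (edges[i] + edges[i + 1]) / 2
    delta[i] <- if (length(a) >= 2L) diff(range(a)) else width
  }
  structure(list(A = as.integer(n_bins), edges = edges, centers = centers,
                 delta = delta, sigma = width_factor * delta,
                 width_factor = width_factor),
            class = "age_binning")
}

#' Age-bin index containing an age (ties to the lower bin)
#' @param binning an `age_binning`.
#' @param theta age in years.
#' @return bin index in 1..A.
#' @export
assign_bin <- function(binning, theta) {
  i <- findInterval(theta, binning$edges, left.open = TRUE)
  pmin(pmax(i, 1L), binning$A)
}

#' Fuzzy Gaussian age-bin membership
#'
#' mu_i(theta) = exp(-(theta - m_i)^2 / (2 sigma_i^2)). Memberships are fuzzy,
#' not probabilistic: no normalization across bins is applied.
#'
#' @param binning an `age_binning`.
#' @param theta age in years.
#' @param i bin index in 1..A.
#' @return membership value in (0, 1].
#' @export
membership <- function(binning, theta, i) {
  if (any(i < 1L | i > binning$A)) stop("bin index out of range")
  s <- binning$sigma[i]
  if (any(s == 0)) stop("degenerate membership width: sigma = 0")
  exp(-(theta - binning$centers[i])^2 / (2 * s^2))
}

# memberships for all bins at once: A x length(theta)
membership_matrix <- function(binning, theta) {
  outer(seq_len(binning$A), theta, function(i, th) membership(binning, th, i))
}

#' Build an augmented region set from an atlas slice
#'
#' For every nonzero atlas label the base mask is emitted together with one
#' eroded and one dilated variant per morphological radius (a disc brush of
#' size 2*radius+1); variants that come out empty are discarded. The
#' resulting masks overlap by construction, which is intended: they act as
#' jittered versions of each region.
#'
#' @param atlas_slice integer-labelled 2D matrix.
#' @param n slice index the set belongs to (bookkeeping only).
#' @param radii integer vector of morphological radii; use `integer(0)` for
#'   base masks only.
#' @return object of class `region_set`: `masks` (list of logical matrices),
#'   `sizes` (voxel counts), `R` (mask count), `labels`, `n`.
#' @export
build_region_set <- function(atlas_slice, n = 1L, radii = 1L) {
  labs <- sort(unique(atlas_slice[atlas_slice > 0]))
  if (length(labs) == 0L) stop("no regions: atlas slice is empty")
  masks <- list(); tags <- character(0)
  for (lab in labs) {
    base <- atlas_slice == lab
    masks[[length(masks) + 1L]] <- base
    tags <- c(tags, sprintf("%d", lab))
    for (r in radii[radii > 0]) {
      brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
      er <- EBImage::erode(base * 1, brush) > 0
      if (any(er)) {
        masks[[length(masks) + 1L]] <- er
        tags <- c(tags, sprintf("%d-er%d", lab, r))
      }
      di <- EBImage::dilate(base * 1, brush) > 0
      if (any(di)) {
        masks[[length(masks) + 1L]] <- di
        tags <- c(tags, sprintf("%d-di%d", lab, r))
      }
    }
  }
  structure(list(n = n, masks = masks,
                 sizes = vapply(masks, sum, 0L), R = length(masks),
                 labels = tags),
            class = "region_set")
}

#' Pre-process a phantom cohort for slice-wise model training
#'
#' Extracts and normalizes the T central slices of every scan, builds the
#' age binning over all scan ages, and builds the augmented region set of
#' every slice from the cohort atlas.
#'
#' @param cohort a `phantom_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param n_slices number of axial slices T.
#' @param n_bins number of age bins A.
#' @param width_factor membership width factor c (sigma = c * delta).
#' @param radii morphological radii for region augmentation.
#' @return object of class `prepped_cohort`: `stacks` (list of
#'   `slice_stack`), `meta` (data.frame subject_id, age, dx), `binning`,
#'   `region_sets` (per slice), `n_slices`, `image_dim`.
#' @export
prep_cohort <- function(cohort, n_slices, n_bins = 10L, width_factor = 1,
                        radii = 1L) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  stacks <- list(); meta <- list()
  for (sub in cohort$subjects) {
    for (sc in sub$scans) {
      stacks[[length(stacks) + 1L]] <-
        normalize_slices(sc$volume, n_slices, sub$subject_id, sc$age)
      meta[[length(meta) + 1L]] <-
        data.frame(subject_id = sub$subject_id, age = sc$age, dx = sub$dx)
    }
  }
  meta <- do.call(rbind, meta)
  binning <- build_age_bins(meta$age, n_bins, width_factor)
  slice_index <- stacks[[1]]$slice_index
  region_sets <- lapply(seq_len(n_slices), function(j)
    build_region_set(cohort$atlas[, , slice_index[j]], n = j, radii = radii))
  structure(list(stacks = stacks, meta = meta, binning = binning,
                 region_sets = region_sets, n_slices = as.integer(n_slices),
                 image_dim = dim(stacks[[1]]$slices)[1:2],
                 slice_index = slice_index),
            class = "prepped_cohort")
}
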