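# Synthetic longitudinal brain-phantom cohorts with known, diagnosis-dependent
# monotone regional atrophy. These stand in for a real ageing/dementia MRI
# cohort: every region's noiseless mean intensity follows a logistic decline
# in age whose depth increases with diagnosis severity, so downstream
# regression and simulation steps can be validated against exact ground truth.

#' Specify a synthetic phantom cohort
#'
#' Defaults emulate a large ageing/dementia T1 cohort: ages 63-87 years,
#' diagnosis mix 28% cognitively normal, 4% subjective memory concern,
#' 54% mild cognitive impairment, 14% Alzheimer's disease, and 4-5 visits
#' spaced about nine months apart (roughly 4.7 scans spanning three years).
#'
#' @param n_subjects number of subjects.
#' @param volume_shape integer c(depth, height, width) in voxels; the depth is
#'   the number of axial slices. All dimensions must be at least 4.
#' @param n_regions_per_slice number of atlas regions tiling each axial slice.
#' @param age_range numeric c(min, max) age in years.
#' @param visits_per_subject integer c(min, max) scans per subject.
#' @param visit_spacing nominal years between consecutive visits.
#' @param diagnosis_probs probability of diagnosis codes 0-3; must sum to 1.
#' @param atrophy_params list with `kappa` (length-4 non-decreasing maximal
#'   fractional decline per diagnosis, each in [0,1)), `tau` (inflection age,
#'   years) and `s` (logistic slope, years).
#' @param noise_sd additive Gaussian intensity noise (image units, >= 0).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 3, volume_shape = c(6, 16, 16), seed = 1)
cohort_spec <- function(n_subjects = 20,
                        volume_shape = c(95, 128, 128),
                        n_regions_per_slice = 9,
                        age_range = c(63, 87),
                        visits_per_subject = c(4, 5),
                        visit_spacing = 0.75,
                        diagnosis_probs = c(0.28, 0.04, 0.54, 0.14),
                        atrophy_params = list(kappa = c(0.05, 0.08, 0.15, 0.30),
                                              tau = 75, s = 5),
                        noise_sd = 0.02,
                        seed = 1L) {
  if (abs(sum(diagnosis_probs) - 1) > 1e-9)
    stop("diagnosis_probs must sum to 1")
  if (length(diagnosis_probs) != 4L)
    stop("diagnosis_probs must have length 4")
  if (is.unsorted(atrophy_params$kappa))
    stop("atrophy kappa must be non-decreasing with diagnosis severity")
  if (any(atrophy_params$kappa < 0) || any(atrophy_params$kappa >= 1))
    stop("atrophy kappa must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(volume_shape) != 3L || any(volume_shape < 4L))
    stop("degenerate volume_shape: every dimension must be >= 4")
  if (diff(age_range) <= 0) stop("age_range must be increasing")
  structure(list(n_subjects = as.integer(n_subjects),
                 volume_shape = as.integer(volume_shape),
                 n_regions_per_slice = as.integer(n_regions_per_slice),
                 age_range = age_range,
                 visits_per_subject = as.integer(rep(visits_per_subject,
                                                     length.out = 2L)),
                 visit_spacing = visit_spacing,
                 diagnosis_probs = diagnosis_probs,
                 atrophy_params = atrophy_params,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Ground-truth regional intensity decline ratio
#'
#' The phantom's generative decline is logistic in age:
#' g(theta) = 1 - kappa_d / (1 + exp(-(theta - tau)/s)). The function returns
#' the ratio g(theta)/g(theta0), i.e. the fraction of regional mean intensity
#' retained between a baseline age and a later age under diagnosis `d`. It is
#' 1 at theta == theta0 and non-increasing in theta.
#'
#' @param theta0 baseline age, years.
#' @param theta follow-up age, years (>= theta0).
#' @param d diagnosis code 0-3.
#' @param params atrophy parameter list as in [cohort_spec()].
#' @return decline ratio in (0, 1].
#' @export
regional_decline <- function(theta0, theta, d,
                             params = cohort_spec()$atrophy_params) {
  if (any(theta < theta0)) stop("invalid interval: theta < theta0")
  if (!all(d %in% 0:3)) stop("diagnosis code must be in 0..3")
  g <- function(th, kap) 1 - kap / (1 + exp(-(th - params$tau) / params$s))
  kap <- params$kappa[d + 1L]
  g(theta, kap) / g(theta0, kap)
}

# ellipsoid geometry shared by volumes and atlas; the bright outer rim is a
# non-declining intensity anchor (see the methods vignette): slice-wise
# standardisation + min-max rescaling would otherwise divide out a globally
# uniform decline.
phantom_geometry <- function(volume_shape) {
  tdim <- volume_shape[1]; h <- volume_shape[2]; w <- volume_shape[3]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2; cz <- (tdim + 1) / 2
  ry <- 0.30 * h; rx <- 0.30 * w; rz <- 0.70 * tdim
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  tissue <- array(FALSE, c(h, w, tdim)); rim <- array(FALSE, c(h, w, tdim))
  for (z in seq_len(tdim)) {
    zq <- ((z - cz) / rz)^2
    e_in <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 + zq
    e_out <- ((yy - cy) / (1.4 * ry))^2 + ((xx - cx) / (1.4 * rx))^2 + zq
    tissue[, , z] <- e_in <= 1
    rim[, , z] <- e_out <= 1 & e_in > 1
  }
  list(tissue = tissue, rim = rim)
}

# tile each axial slice's tissue cross-section into n contiguous grid sectors
# (per-slice bounding box, so all n regions are non-empty on every slice).
phantom_atlas <- function(tissue, n_regions) {
  dims <- dim(tissue)
  atlas <- array(0L, dims)
  n_bands <- max(1L, floor(sqrt(n_regions)))
  per_band <- diff(round(seq(0, n_regions, length.out = n_bands + 1)))
  for (z in seq_len(dims[3])) {
    m <- tissue[, , z]
    if (!any(m)) next
    rows <- range(which(rowSums(m) > 0)); cols <- range(which(colSums(m) > 0))
    ri <- row(m); ci <- col(m)
    band <- pmin(n_bands, pmax(1L, ceiling((ri - rows[1] + 1) /
                                             (diff(rows) + 1) * n_bands)))
    lab <- matrix(0L, dims[1], dims[2])
    for (b in seq_len(n_bands)) {
      kb <- per_band[b]
      sect <- pmin(kb, pmax(1L, ceiling((ci - cols[1] + 1) /
                                          (diff(cols) + 1) * kb)))
      sel <- band == b & m
      lab[sel] <- sum(per_band[seq_len(b - 1L)]) + sect[sel]
    }
    atlas[, , z] <- lab
  }
  storage.mode(atlas) <- "integer"
  atlas
}

#' Generate a phantom cohort
#'
#' Deterministic for a fixed seed. Each subject receives a diagnosis code, a
#' visit schedule, and per-region base intensities; every scan's voxel values
#' are `base * g_d(age)` inside the tissue ellipsoid (region-wise), 1 on the
#' bright rim, 0 in the background, plus optional Gaussian noise. The true
#' noiseless per-region mean trajectories are returned alongside.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `phantom_cohort` with elements `subjects`
#'   (list of subject records), `atlas` (labelled integer volume),
#'   `tissue`/`rim` masks, `trajectories` (data.frame subject_id, region_id,
#'   age, mean_intensity) and the originating `cohort_spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  geo <- phantom_geometry(spec$volume_shape)
  atlas <- phantom_atlas(geo$tissue, spec$n_regions_per_slice)
  dims <- dim(atlas)
  tdim <- dims[3]
  n_reg <- spec$n_regions_per_slice
  subjects <- vector("list", spec$n_subjects)
  traj <- list()
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("sub%03d", s)
    d <- sample(0:3, 1L, prob = spec$diagnosis_probs)
    nv <- sample(seq(spec$visits_per_subject[1], spec$visits_per_subject[2]),
                 1L)
    span <- (nv - 1) * spec$visit_spacing
    theta0 <- stats::runif(1, spec$age_range[1],
                           max(spec$age_range[1], spec$age_range[2] - span))
    gaps <- spec$visit_spacing * stats::runif(max(nv - 1, 0), 0.8, 1.2)
    ages <- theta0 + cumsum(c(0, gaps))
    base <- stats::runif(n_reg, 0.35, 0.75)
    kap <- spec$atrophy_params$kappa[d + 1L]
    g_age <- function(th)
      1 - kap / (1 + exp(-(th - spec$atrophy_params$tau) /
                           spec$atrophy_params$s))
    scans <- vector("list", nv)
    for (v in seq_len(nv)) {
      decl <- g_age(ages[v])
      vol <- array(0, dims)
      vol[geo$rim] <- 1
      for (r in seq_len(n_reg)) {
        vol[atlas == r] <- base[r] * decl
        traj[[length(traj) + 1L]] <-
          data.frame(subject_id = sid, region_id = r, age = ages[v],
                     mean_intensity = base[r] * decl)
      }
      if (spec$noise_sd > 0)
        vol <- vol + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims)
      scans[[v]] <- list(age = ages[v], volume = vol)
    }
    subjects[[s]] <- list(subject_id = sid, dx = d, scans = scans)
  }
  structure(list(subjects = subjects, atlas = atlas,
                 tissue = geo$tissue, rim = geo$rim,
                 trajectories = do.call(rbind, traj), spec = spec),
            class = "phantom_cohort")
}

#' Write a phantom cohort to disk
#'
#' One NIfTI per scan plus the atlas, a scan manifest CSV
#' (subject_id, age, dx, path) and the ground-truth trajectories CSV.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir existing writable directory.
#' @return path to the manifest CSV, invisibly usable by [read_cohort()].
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  rows <- list()
  for (sub in cohort$subjects) {
    for (v in seq_along(sub$scans)) {
      f <- file.path(dir, sprintf("%s_v%02d.nii.gz", sub$subject_id, v))
      RNifti::writeNifti(cohort_img(sub$scans[[v]]$volume), f,
                         datatype = "double")
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = sub$subject_id, age = sub$scans[[v]]$age,
                   dx = sub$dx, path = basename(f))
    }
  }
  RNifti::writeNifti(cohort_img(cohort$atlas), file.path(dir, "atlas.nii.gz"),
                     datatype = "int16")
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  utils::write.csv(cohort$trajectories, file.path(dir, "trajectories.csv"),
                   row.names = FALSE)
  invisible(mpath)
}

cohort_img <- function(arr) RNifti::asNifti(arr)

#' Read a phantom cohort written by [write_cohort()]
#'
#' @param manifest_path path to the manifest CSV; the atlas and trajectory
#'   files are looked up in the same directory.
#' @return a `phantom_cohort` (tissue mask reconstructed as atlas > 0).
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  dir <- dirname(manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  read_arr <- function(path) {
    a <- RNifti::readNifti(path)
    array(as.numeric(a), dim(a))
  }
  a0 <- read_arr(file.path(dir, "atlas.nii.gz"))
  atlas_arr <- array(as.integer(round(a0)), dim(a0))
  subjects <- lapply(split(manifest, manifest$subject_id), function(mm) {
    mm <- mm[order(mm$age), ]
    scans <- lapply(seq_len(nrow(mm)), function(i)
      list(age = mm$age[i],
           volume = read_arr(file.path(dir, mm$path[i]))))
    list(subject_id = mm$subject_id[1], dx = mm$dx[1], scans = scans)
  })
  names(subjects) <- NULL
  subjects <- subjects[order(vapply(subjects, `[[`, "", "subject_id"))]
  tpath <- file.path(dir, "trajectories.csv")
  traj <- if (file.exists(tpath)) utils::read.csv(tpath) else NULL
  structure(list(subjects = subjects, atlas = atlas_arr,
                 tissue = atlas_arr > 0, rim = NULL,
                 trajectories = traj, spec = NULL),
            class = "phantom_cohort")
}
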