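# Volumetric accuracy protocol: regional volumes as fractions of total
# brain volume, compared between simulated and reference scans. On
# phantoms, segmentation is mask-plus-threshold; externally produced
# segmentation masks (e.g. from a dedicated neuroimaging pipeline) can be
# passed through the same interface for real data.

#' Measure regional and total brain volumes
#'
#' A region's volume is the number of voxels inside its mask whose
#' intensity exceeds the threshold; total brain volume is counted over the
#' brain mask the same way.
#'
#' @param volume 3D array.
#' @param masks named list of logical arrays (region masks), each matching
#'   the volume shape.
#' @param brain_mask logical array for total brain volume.
#' @param threshold intensity threshold.
#' @return list(regions = named voxel counts, total = total brain count).
#' @export
measure_volumes <- function(volume, masks, brain_mask, threshold = 0) {
  if (!identical(unname(dim(brain_mask)), unname(dim(volume))))
    stop("brain mask shape mismatch")
  total <- sum(volume[brain_mask] > threshold)
  if (total == 0) stop("empty foreground: no voxel above threshold")
  regions <- vapply(masks, function(m) {
    if (!identical(unname(dim(m)), unname(dim(volume))))
      stop("region mask shape mismatch")
    sum(volume[m] > threshold)
  }, 0)
  list(regions = regions, total = total)
}

#' Volumetric error between a simulated and a reference scan
#'
#' Err = | v_sim / tb_sim - v_ref / tb_ref | * 100: the absolute difference
#' between the region-to-total-brain volume fractions, in percent of total
#' brain volume. Symmetric in its two scans and invariant to rescaling all
#' intensities (with the threshold rescaled likewise).
#'
#' @param sim_volume,real_volume 3D arrays of equal shape.
#' @param region_mask,brain_mask logical arrays.
#' @param threshold intensity threshold applied to both scans.
#' @return non-negative error in percent.
#' @export
volumetric_error <- function(sim_volume, real_volume, region_mask,
                             brain_mask, threshold = 0) {
  ms <- measure_volumes(sim_volume, list(r = region_mask), brain_mask,
                        threshold)
  mr <- measure_volumes(real_volume, list(r = region_mask), brain_mask,
                        threshold)
  abs(ms$regions[["r"]] / ms$total - mr$regions[["r"]] / mr$total) * 100
}

#' Cohort-level volumetric report
#'
#' Per-region mean and sample standard deviation of the volumetric errors
#' across subjects, in the wide layout regions-as-columns.
#'
#' @param errors data.frame with columns `subject`, `region`, `err`.
#' @param regions optional character vector fixing the column order.
#' @param file optional path; when given the wide table is written as CSV.
#' @return object of class `volumetric_report`: `errors` (input), `summary`
#'   (region, mean, sd), `wide` (two-row mean/sd table).
#' @export
cohort_report <- function(errors, regions = NULL, file = NULL) {
  if (nrow(errors) == 0L) stop("empty error table")
  if (any(errors$err < 0)) stop("negative volumetric error")
  if (is.null(regions)) regions <- unique(errors$region)
  sm <- do.call(rbind, lapply(regions, function(r) {
    e <- errors$err[errors$region == r]
    data.frame(region = r, mean = mean(e),
               sd = if (length(e) > 1L) stats::sd(e) else 0,
               n = length(e))
  }))
  wide <- rbind(mean = stats::setNames(sm$mean, sm$region),
                sd = stats::setNames(sm$sd, sm$region))
  if (!is.null(file))
    utils::write.csv(data.frame(stat = rownames(wide), wide,
                                check.names = FALSE),
                     file, row.names = FALSE)
  structure(list(errors = errors, summary = sm, wide = wide),
            class = "volumetric_report")
}

#' @export
print.volumetric_report <- function(x, ...) {
  cat("Volumetric error report (% of total brain volume)\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-12s %.3f +/- %.3f  (n = %d)\n", x$summary$region[i],
                x$summary$mean[i], x$summary$sd[i], x$summary$n[i]))
  invisible(x)
}
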