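#' IIR normalization of LA wall intensities
#'
#' Divides every wall-voxel intensity by the mean blood-pool intensity of
#' the same scan, yielding the dimensionless image intensity ratio
#' `NI(x) = I(x) / mu_BP`.  The mean and standard deviation of NI over the
#' wall feed the fibrosis threshold.
#'
#' @param image an [image_volume()].
#' @param blood_pool blood-pool [label_map()], congruent with `image` and
#'   non-empty with positive mean intensity.
#' @param wall LA-wall [label_map()], congruent with `image`.
#' @return A list with `stats` (class `blood_pool_stats`: `mu_bp`,
#'   `voxel_count`) and `nw` (a [normalized_wall()]).
#' @export
iir_normalize <- function(image, blood_pool, wall) {
  stopifnot(inherits(image, "image_volume"))
  check_congruent(image, blood_pool, "image and blood pool")
  check_congruent(image, wall, "image and wall")
  bp <- as_mask_array(blood_pool)
  wl <- as_mask_array(wall)
  if (!any(bp)) stop("blood pool mask is empty", call. = FALSE)
  mu_bp <- mean(image$data[bp])
  if (!is.finite(mu_bp) || mu_bp <= 0)
    stop("mean blood-pool intensity must be positive for IIR normalization",
         call. = FALSE)
  idx <- which(wl)
  ni <- image$data[idx] / mu_bp
  nw <- normalized_wall(ni, idx = idx, dim = dim(image$data),
                        spacing = image$spacing)
  stats <- structure(list(mu_bp = mu_bp, voxel_count = sum(bp)),
                     class = "blood_pool_stats")
  list(stats = stats, nw = nw)
}

#' Normalized-wall container
#'
#' Holds the IIR-normalized intensities of the LA wall voxels together with
#' their grid locations, so that volumetric and slice-wise fibrosis
#' fractions can be computed.  Usually produced by [iir_normalize()]; the
#' constructor is exported so NI values obtained elsewhere can be fed into
#' the thresholding stage directly.
#'
#' @param ni numeric vector of normalized intensities (one per wall voxel).
#' @param idx linear indices of the wall voxels within the grid.
#' @param dim grid dimensions (length 3).
#' @param spacing voxel spacing in mm.
#' @return An object of class `normalized_wall` with `ni`, `idx`, `dim`,
#'   `spacing`, `mu_ni` and `sigma_ni` (sample SD, n - 1 denominator).
#' @export
normalized_wall <- function(ni, idx = seq_along(ni), dim = c(length(ni), 1L, 1L),
                            spacing = c(1, 1, 1)) {
  ni <- as.double(ni)
  if (any(!is.finite(ni))) stop("NI values must be finite", call. = FALSE)
  if (length(idx) != length(ni))
    stop("`idx` must match `ni` in length", call. = FALSE)
  structure(list(ni = ni, idx = as.integer(idx), dim = as.integer(dim),
                 spacing = as.double(spacing),
                 mu_ni = mean(ni),
                 sigma_ni = if (length(ni) >= 2L) stats::sd(ni) else NA_real_),
            class = "normalized_wall")
}

#' Fibrosis threshold: mean IIR + k standard deviations
#'
#' `T_fib = mu_NI + k * sigma_NI` with `k = 2` by default (`k` of 3 or 4
#' leaves too few supra-threshold voxels at typical enhancement levels and
#' is offered only as an option).
#'
#' @param nw a [normalized_wall()] with at least two voxels.
#' @param k_sd SD multiplier (default 2).
#' @return Threshold value (dimensionless).
#' @export
fibrosis_threshold <- function(nw, k_sd = 2) {
  stopifnot(inherits(nw, "normalized_wall"))
  if (length(nw$ni) < 2L || is.na(nw$sigma_ni))
    stop("fewer than 2 wall voxels: SD undefined", call. = FALSE)
  nw$mu_ni + k_sd * nw$sigma_ni
}

#' Volumetric percent myocardial fibrosis
#'
#' A wall voxel is fibrotic iff `NI > t_fib` (strictly).  The fibrosis
#' volume is the fibrotic voxel count times the voxel volume, and
#' volumetric %MF is 100 times fibrosis volume over total wall volume.
#'
#' @param nw a non-empty [normalized_wall()].
#' @param t_fib threshold from [fibrosis_threshold()].
#' @return A list: `mf_voxels`, `mf_volume_mm3`, `wall_volume_mm3`,
#'   `percent_mf`.
#' @export
percent_mf_volumetric <- function(nw, t_fib) {
  stopifnot(inherits(nw, "normalized_wall"))
  n_wall <- length(nw$ni)
  if (n_wall == 0L) stop("empty wall: %MF undefined", call. = FALSE)
  vv <- prod(nw$spacing)
  n_mf <- sum(nw$ni > t_fib)
  list(mf_voxels = as.integer(n_mf),
       mf_volume_mm3 = n_mf * vv,
       wall_volume_mm3 = n_wall * vv,
       percent_mf = 100 * n_mf / n_wall)
}

#' Slice-wise percent myocardial fibrosis
#'
#' Selects the axial slice containing the highest number of fibrotic
#' voxels (ties broken to the lowest slice index) and reports the fibrotic
#' share of that slice's wall area.  Requires at least one fibrotic voxel
#' somewhere; absence of enhancement is an error distinct from a 0%
#' volumetric measurement.
#'
#' @inheritParams percent_mf_volumetric
#' @return A list: `slice` (1-based axial index), `percent_mf`,
#'   `mf_voxels_slice`, `wall_voxels_slice`, `tie` (logical).
#' @export
percent_mf_slicewise <- function(nw, t_fib) {
  stopifnot(inherits(nw, "normalized_wall"))
  fib <- nw$ni > t_fib
  if (!any(fib))
    stop("no enhanced voxel anywhere in the wall: slice-wise %MF undefined",
         call. = FALSE)
  k <- arrayInd(nw$idx, nw$dim)[, 3]
  mf_by_k <- tapply(fib, k, sum)
  wall_by_k <- tapply(fib, k, length)
  best <- which.max(mf_by_k)              # first maximum -> lowest k
  tie <- sum(mf_by_k == mf_by_k[best]) > 1L
  list(slice = as.integer(names(mf_by_k)[best]),
       percent_mf = 100 * mf_by_k[[best]] / wall_by_k[[best]],
       mf_voxels_slice = as.integer(mf_by_k[[best]]),
       wall_voxels_slice = as.integer(wall_by_k[[best]]),
       tie = tie)
}

#' Signed longitudinal change in percent fibrosis
#'
#' `D_abs = V_p - V_b` in percentage points; the sign is kept (a decrease
#' is negative).
#'
#' @param v_b,v_p %MF at baseline and post-pacing.
#' @return Signed difference in percentage points.
#' @export
d_abs <- function(v_b, v_p) {
  stopifnot(is.finite(v_b), is.finite(v_p))
  v_p - v_b
}

#' Group summary: mean +/- SD and median +/- IQR
#'
#' SD uses the n - 1 denominator; the IQR is Q3 - Q1 with
#' linear-interpolation quantiles (R type 7).  With a single value the SD
#' and IQR are `NA`.
#'
#' @param values numeric vector, length >= 1.
#' @return Named list `mean`, `sd`, `median`, `iqr`, `n`.
#' @export
group_summary <- function(values) {
  values <- as.double(values)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarize", call. = FALSE)
  list(mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
       median = stats::median(values),
       iqr = if (length(values) >= 2L)
         stats::IQR(values, type = 7) else NA_real_,
       n = length(values))
}

#' One-call fibrosis measurement for a single scan
#'
#' Runs [iir_normalize()], [fibrosis_threshold()],
#' [percent_mf_volumetric()] and [percent_mf_slicewise()] and assembles a
#' measurement record.  In-situ (post-mortem) scans are refused: stagnant
#' gadolinium pooling in the blood pool invalidates blood-pool-based
#' normalization, so IIR %MF is reported for in-vivo timepoints only.
#'
#' @inheritParams iir_normalize
#' @param k_sd SD multiplier for the threshold (default 2).
#' @param timepoint `"baseline"`, `"post_pacing"` or `"in_situ"`.
#' @return A list of class `fibrosis_measurement`.
#' @export
quantify_fibrosis <- function(image, blood_pool, wall, k_sd = 2,
                              timepoint = c("baseline", "post_pacing",
                                            "in_situ")) {
  timepoint <- match.arg(timepoint)
  if (timepoint == "in_situ")
    stop("in-situ scans are excluded from IIR %MF computation ",
         "(blood-pool normalization is invalid post-mortem)", call. = FALSE)
  nz <- iir_normalize(image, blood_pool, wall)
  t_fib <- fibrosis_threshold(nz$nw, k_sd = k_sd)
  vol <- percent_mf_volumetric(nz$nw, t_fib)
  sl <- tryCatch(percent_mf_slicewise(nz$nw, t_fib),
                 error = function(e) NULL)
  structure(list(
    timepoint = timepoint,
    mu_bp = nz$stats$mu_bp,
    mu_ni = nz$nw$mu_ni,
    sigma_ni = nz$nw$sigma_ni,
    k_sd = k_sd,
    t_fib = t_fib,
    mf_voxels = vol$mf_voxels,
    mf_volume_mm3 = vol$mf_volume_mm3,
    wall_volume_mm3 = vol$wall_volume_mm3,
    percent_mf_volumetric = vol$percent_mf,
    percent_mf_slicewise = if (is.null(sl)) NA_real_ else sl$percent_mf,
    max_slice_index = if (is.null(sl)) NA_integer_ else sl$slice,
    slice_tie = if (is.null(sl)) NA else sl$tie
  ), class = "fibrosis_measurement")
}

#' @export
print.fibrosis_measurement <- function(x, ...) {
  cat(sprintf(
    "<fibrosis_measurement> %s: T_fib=%.3f, %%MF vol=%.2f%%, slice %d=%.2f%%\n",
    x$timepoint, x$t_fib, x$percent_mf_volumetric,
    if (is.na(x$max_slice_index)) -1L else x$max_slice_index,
    if (is.na(x$percent_mf_slicewise)) NaN else x$percent_mf_slicewise))
  invisible(x)
}
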