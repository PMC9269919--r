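# Image-quality and observer-variability metrics: NEMA-4 SNR, Dice,
# boundary F1 / precision / recall, relative volume error, intraclass
# correlation and inter-rater reliability.

#' NEMA-4 signal-to-noise ratio
#'
#' SNR = factor * mean(signal ROI) / mean(SD of the four background ROIs).
#' The Rayleigh correction factor (default 0.66) converts the SD of a
#' magnitude-image background, which is Rayleigh rather than Gaussian
#' distributed, into an equivalent Gaussian noise estimate.
#'
#' @param image an [image_volume()].
#' @param signal_roi non-empty [label_map()] over the blood pool.
#' @param noise_rois list of exactly 4 disjoint non-empty background
#'   [label_map()]s.
#' @param factor Rayleigh correction factor, default 0.66.
#' @return A list of class `snr_result`: `signal_mean`, `noise_sd_avg`,
#'   `rayleigh_factor`, `snr`.
#' @export
nema4_snr <- function(image, signal_roi, noise_rois, factor = 0.66) {
  stopifnot(inherits(image, "image_volume"))
  if (!is.list(noise_rois) || length(noise_rois) != 4L)
    stop("exactly 4 noise ROIs are required", call. = FALSE)
  sig <- as_mask_array(signal_roi)
  check_congruent(image, signal_roi, "image and signal ROI")
  if (!any(sig)) stop("signal ROI is empty", call. = FALSE)
  masks <- lapply(noise_rois, as_mask_array)
  counts <- vapply(masks, sum, integer(1))
  if (any(counts < 2L))
    stop("each noise ROI needs at least 2 voxels", call. = FALSE)
  overlap <- Reduce(`+`, lapply(masks, function(m) m + 0))
  if (any(overlap > 1)) stop("noise ROIs must be disjoint", call. = FALSE)
  sds <- vapply(masks, function(m) stats::sd(image$data[m]), numeric(1))
  noise <- mean(sds)
  if (noise <= 0) stop("degenerate noise ROI: zero SD", call. = FALSE)
  structure(list(signal_mean = mean(image$data[sig]), noise_sd_avg = noise,
                 rayleigh_factor = factor,
                 snr = factor * mean(image$data[sig]) / noise),
            class = "snr_result")
}

#' Dice similarity coefficient (percent)
#'
#' `100 * 2|A n B| / (|A| + |B|)`; 100 when both masks are empty, 0 when
#' exactly one is.
#'
#' @param a,b congruent [label_map()]s or logical arrays.
#' @return DSC in percent.
#' @export
dice <- function(a, b) {
  ma <- as_mask_array(a); mb <- as_mask_array(b)
  if (!identical(dim(ma), dim(mb)))
    stop("masks are not congruent", call. = FALSE)
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0L) return(100)
  100 * 2 * sum(ma & mb) / (na + nb)
}

#' Mean pairwise Dice over repeated segmentations
#'
#' For `m` segmentation attempts, the DSC is computed for each of the
#' `choose(m, 2)` unordered pairs (attempt 1 vs 2, 2 vs 3, 3 vs 1 for
#' three attempts) and summarized as mean and SD.
#'
#' @param masks list of >= 2 congruent masks.
#' @return List `mean`, `sd`, `pairwise` (named vector of pair DSCs).
#' @export
pairwise_mean_dice <- function(masks) {
  if (!is.list(masks) || length(masks) < 2L)
    stop("at least 2 masks are required", call. = FALSE)
  pairs <- utils::combn(length(masks), 2)
  vals <- apply(pairs, 2, function(p) dice(masks[[p[1]]], masks[[p[2]]]))
  names(vals) <- apply(pairs, 2, paste, collapse = "v")
  list(mean = mean(vals),
       sd = if (length(vals) >= 2L) stats::sd(vals) else NA_real_,
       pairwise = vals)
}

# boundary voxels: mask voxels with at least one non-mask 6-neighbour
# (voxels on the array edge count as boundary)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift3 <- function(m, dx, dy, dz) {
    out <- array(FALSE, d)
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs, ys, zs] <- m[xs - dx, ys - dy, zs - dz, drop = FALSE]
    out
  }
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    interior <- interior & shift3(mask, o[1], o[2], o[3])
  mask & !interior
}

# minimum Euclidean distance (voxel units) from each row of `from` to the
# point set `to`; chunked brute force
min_dists <- function(from, to, chunk = 512L) {
  n <- nrow(from)
  out <- numeric(n)
  tt <- t(to)
  to_sq <- colSums(tt^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    blk <- from[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), to_sq, `+`) - 2 * blk %*% tt
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Boundary F1 score, precision and recall
#'
#' Boundary voxels (6-connectivity) are extracted from both masks;
#' precision is the fraction of candidate-boundary voxels within
#' `tolerance` (Euclidean, voxel units) of the reference boundary, recall
#' the symmetric quantity, and F1 their harmonic mean.  Both boundaries
#' empty gives 100; exactly one empty gives 0.
#'
#' @param candidate,reference congruent masks.
#' @param tolerance distance tolerance in voxels (default 2).
#' @return List `f1`, `precision`, `recall` (all percent).
#' @export
boundary_scores <- function(candidate, reference, tolerance = 2) {
  mc <- as_mask_array(candidate); mr <- as_mask_array(reference)
  if (!identical(dim(mc), dim(mr)))
    stop("masks are not congruent", call. = FALSE)
  if (tolerance < 0) stop("`tolerance` must be >= 0", call. = FALSE)
  bc <- which(boundary_voxels(mc)); br <- which(boundary_voxels(mr))
  if (length(bc) == 0L && length(br) == 0L)
    return(list(f1 = 100, precision = 100, recall = 100))
  if (length(bc) == 0L || length(br) == 0L)
    return(list(f1 = 0, precision = 0, recall = 0))
  pc <- arrayInd(bc, dim(mc)); pr <- arrayInd(br, dim(mr))
  if (is.infinite(tolerance)) {
    precision <- recall <- 100
  } else {
    precision <- 100 * mean(min_dists(pc, pr) <= tolerance)
    recall <- 100 * mean(min_dists(pr, pc) <= tolerance)
  }
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(f1 = f1, precision = precision, recall = recall)
}

#' Signed relative volume error
#'
#' `(|candidate| - |reference|) / |reference|` as a signed fraction.
#'
#' @param candidate,reference congruent masks; reference non-empty.
#' @return Signed fraction.
#' @export
relative_volume_error <- function(candidate, reference) {
  mc <- as_mask_array(candidate); mr <- as_mask_array(reference)
  if (!identical(dim(mc), dim(mr)))
    stop("masks are not congruent", call. = FALSE)
  nr <- sum(mr)
  if (nr == 0L) stop("reference mask is empty", call. = FALSE)
  (sum(mc) - nr) / nr
}

#' Reliability from variance components
#'
#' `(1 + s2w / (k * s2b))^-1`: with `k = 1` this is the intraclass
#' correlation (within-operator repeatability); with `k` operators it is
#' the inter-rater reliability.
#'
#' @param s2w within-condition variance component.
#' @param s2b between-condition variance component (> 0).
#' @param k number of operators (default 1).
#' @return Reliability in (0, 1].
#' @export
reliability_from_components <- function(s2w, s2b, k = 1) {
  if (!is.finite(s2b) || s2b <= 0)
    stop("degenerate between-condition variance (sigma2_b <= 0)",
         call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  1 / (1 + s2w / (k * s2b))
}

#' Intraclass correlation for one operator's repeated measurements
#'
#' `sigma2_w` is the mean within-condition sample variance over repeats;
#' `sigma2_b` the sample variance of condition means; the ICC is
#' `(1 + sigma2_w / sigma2_b)^-1`.
#'
#' @param measurements matrix with one row per condition (e.g. animal x
#'   timepoint) and one column per repeated attempt; >= 2 rows and >= 2
#'   columns.
#' @return List `icc`, `sigma2_w`, `sigma2_b`.
#' @export
icc_intra <- function(measurements) {
  m <- as.matrix(measurements)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop(">= 2 conditions with >= 2 repeats each are required",
         call. = FALSE)
  s2w <- mean(apply(m, 1, stats::var))
  s2b <- stats::var(rowMeans(m))
  list(icc = reliability_from_components(s2w, s2b, k = 1),
       sigma2_w = s2w, sigma2_b = s2b)
}

#' Inter-rater reliability over k operators
#'
#' Pools the within-cell variance over all condition-by-operator cells and
#' computes `R = (1 + sigma2_w / (k * sigma2_b))^-1`.  The grouping axis
#' for `sigma2_b` is configurable: `"condition"` (default; variance of
#' per-condition means pooled over operators) or `"cell"` (variance of all
#' condition-by-operator cell means).
#'
#' @param measurements 3D array `[condition, repeat, operator]` or list of
#'   per-operator matrices as in [icc_intra()].
#' @param grouping `"condition"` or `"cell"`.
#' @return List `r`, `k`, `sigma2_w`, `sigma2_b`.
#' @export
inter_rater_r <- function(measurements, grouping = c("condition", "cell")) {
  grouping <- match.arg(grouping)
  if (is.list(measurements))
    measurements <- simplify2array(lapply(measurements, as.matrix))
  if (length(dim(measurements)) != 3L)
    stop("`measurements` must be [condition, repeat, operator]",
         call. = FALSE)
  k <- dim(measurements)[3]
  if (k < 2L) stop("at least 2 operators are required", call. = FALSE)
  cellvar <- apply(measurements, c(1, 3), stats::var)
  s2w <- mean(cellvar)
  s2b <- if (grouping == "condition")
    stats::var(apply(measurements, 1, mean))
  else stats::var(as.vector(apply(measurements, c(1, 3), mean)))
  list(r = reliability_from_components(s2w, s2b, k = k), k = k,
       sigma2_w = s2w, sigma2_b = s2b)
}
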