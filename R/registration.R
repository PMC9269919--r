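#' Least-squares rigid registration of labelled landmarks
#'
#' Finds the rotation + translation minimizing the sum of squared
#' differences between fixed landmarks and transformed moving landmarks,
#' by the closed-form solution: centroid alignment followed by the
#' orthogonal-Procrustes rotation (SVD of the cross-covariance with
#' determinant correction, so reflections are excluded).  Correspondence
#' is strictly by landmark label, never by row order.
#'
#' @param moving,fixed [landmark_set()]s carrying the same labels;
#'   at least 3 non-collinear points.
#' @return A list of class `rigid_transform`: `rotation` (3x3, det +1),
#'   `translation` (mm), `rmse_mm` (residual landmark RMSE), `n`.
#'   The transform maps moving-space points to fixed space:
#'   `y = R x + t`.
#' @export
fit_rigid_landmarks <- function(moving, fixed) {
  stopifnot(inherits(moving, "landmark_set"), inherits(fixed, "landmark_set"))
  if (!setequal(moving$labels, fixed$labels))
    stop("landmark labels do not correspond between the two sets",
         call. = FALSE)
  X <- moving$coords[fixed$labels, , drop = FALSE]   # align by label
  Y <- fixed$coords
  n <- nrow(Y)
  if (n < 3L)
    stop("at least 3 landmarks are required for rigid registration",
         call. = FALSE)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  # collinearity check: centered points must span at least 2 dimensions
  if (sum(svd(Xc)$d > 1e-9 * max(1, max(abs(Xc)))) < 2L)
    stop("degenerate landmark geometry: points are collinear", call. = FALSE)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cy - as.vector(R %*% cx)
  res <- Y - (X %*% t(R) + matrix(t, n, 3, byrow = TRUE))
  structure(list(rotation = R, translation = t,
                 rmse_mm = sqrt(mean(rowSums(res^2))), n = n),
            class = "rigid_transform")
}

#' Build a rigid transform from parameters
#'
#' @param angle_deg rotation angle in degrees about `axis`.
#' @param axis rotation axis, default z (the axial direction).
#' @param translation mm triple.
#' @param center optional rotation centre (mm); the result is still stored
#'   as `y = R x + t` with the centre folded into `t`.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(angle_deg = 0, axis = c(0, 0, 1),
                            translation = c(0, 0, 0), center = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t <- as.vector(center - R %*% center) + translation
  structure(list(rotation = R, translation = t, rmse_mm = 0, n = 0L),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform`.
#' @param pts n x 3 matrix of mm coordinates, or a [landmark_set()].
#' @return Transformed points (same type as input).
#' @export
transform_points <- function(t, pts) {
  stopifnot(inherits(t, "rigid_transform"))
  if (inherits(pts, "landmark_set")) {
    out <- pts
    out$coords <- transform_points(t, pts$coords)
    dimnames(out$coords) <- list(out$labels, c("x", "y", "z"))
    return(out)
  }
  pts <- as.matrix(pts)
  pts %*% t(t$rotation) + matrix(t$translation, nrow(pts), 3, byrow = TRUE)
}

#' Invert a rigid transform
#'
#' @param t a `rigid_transform`.
#' @return The inverse transform.
#' @export
invert_rigid <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rinv <- t(t$rotation)
  structure(list(rotation = Rinv,
                 translation = as.vector(-Rinv %*% t$translation),
                 rmse_mm = t$rmse_mm, n = t$n),
            class = "rigid_transform")
}

#' Resample a volume or label map through a rigid transform
#'
#' Resamples onto the input grid: the output voxel at physical position `p`
#' takes the input value at `T^-1(p)`, with trilinear interpolation for
#' intensity volumes and nearest-neighbour for label maps.  Positions
#' mapping outside the field of view become 0.
#'
#' @param vol an [image_volume()] or [label_map()].
#' @param t a `rigid_transform` mapping input (moving) space to output
#'   (fixed) space.
#' @return Resampled object of the same class as `vol`.
#' @export
apply_rigid_to_volume <- function(vol, t) {
  stopifnot(inherits(t, "rigid_transform"))
  is_label <- inherits(vol, "label_map")
  arr <- if (is_label) vol$mask + 0 else vol$data
  d <- dim(arr)
  sp <- vol$spacing; og <- vol$origin
  idx <- arrayInd(seq_len(prod(d)), d)
  phys <- sweep(sweep(idx - 1, 2, sp, `*`), 2, og, `+`)
  src <- transform_points(invert_rigid(t), phys)
  cont <- sweep(sweep(src, 2, og, `-`), 2, sp, `/`) + 1  # continuous index
  if (is_label) {
    ni <- round(cont)
    ok <- ni[, 1] >= 1 & ni[, 1] <= d[1] & ni[, 2] >= 1 & ni[, 2] <= d[2] &
      ni[, 3] >= 1 & ni[, 3] <= d[3]
    out <- numeric(prod(d))
    lin <- ni[ok, 1] + (ni[ok, 2] - 1) * d[1] + (ni[ok, 3] - 1) * d[1] * d[2]
    out[ok] <- arr[lin]
    label_map(array(out != 0, d), region = vol$region, spacing = sp,
              origin = og)
  } else {
    f <- floor(cont)
    w <- cont - f
    for (ax in 1:3) {               # positions exactly on the upper face
      at_top <- cont[, ax] == d[ax]
      f[at_top, ax] <- d[ax] - 1
      w[at_top, ax] <- 1
    }
    out <- numeric(prod(d))
    ok <- f[, 1] >= 1 & f[, 1] <= d[1] - 1 & f[, 2] >= 1 & f[, 2] <= d[2] - 1 &
      f[, 3] >= 1 & f[, 3] <= d[3] - 1
    if (any(ok)) {
      fo <- f[ok, , drop = FALSE]; wo <- w[ok, , drop = FALSE]
      lin <- function(di, dj, dk)
        arr[fo[, 1] + di + (fo[, 2] + dj - 1) * d[1] +
              (fo[, 3] + dk - 1) * d[1] * d[2]]
      out[ok] <-
        lin(0, 0, 0) * (1 - wo[, 1]) * (1 - wo[, 2]) * (1 - wo[, 3]) +
        lin(1, 0, 0) * wo[, 1] * (1 - wo[, 2]) * (1 - wo[, 3]) +
        lin(0, 1, 0) * (1 - wo[, 1]) * wo[, 2] * (1 - wo[, 3]) +
        lin(0, 0, 1) * (1 - wo[, 1]) * (1 - wo[, 2]) * wo[, 3] +
        lin(1, 1, 0) * wo[, 1] * wo[, 2] * (1 - wo[, 3]) +
        lin(1, 0, 1) * wo[, 1] * (1 - wo[, 2]) * wo[, 3] +
        lin(0, 1, 1) * (1 - wo[, 1]) * wo[, 2] * wo[, 3] +
        lin(1, 1, 1) * wo[, 1] * wo[, 2] * wo[, 3]
    }
    image_volume(array(out, d), spacing = sp, origin = og)
  }
}

#' Serialize a rigid transform to JSON
#'
#' Stores the rotation row-major plus the translation, so external tools
#' can re-apply the mapping.
#'
#' @param t a `rigid_transform`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_rigid_transform <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::write_json(
    list(rotation_row_major = as.vector(t(t$rotation)),
         translation_mm = t$translation, rmse_mm = t$rmse_mm, n = t$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rmse = %.4g mm over %d landmarks\n",
              x$rmse_mm, x$n))
  invisible(x)
}
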