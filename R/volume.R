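#' In-memory 3D image volume
#'
#' A minimal format-neutral container for a scalar 3D image: a numeric array
#' plus voxel geometry.  Axis 3 (index `k`) enumerates axial slices; axes 1-2
#' are in-plane.  The physical position of voxel `(i, j, k)` (1-based) is
#' `origin + spacing * (c(i, j, k) - 1)`; only axis-aligned grids are
#' represented.
#'
#' @param data 3D numeric array of finite, non-negative intensities.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, position of voxel (1,1,1) in mm.
#' @return An object of class `image_volume`.
#' @examples
#' vol <- image_volume(array(0, c(4, 4, 4)), spacing = c(0.625, 0.625, 0.975))
#' voxel_volume(vol)
#' @export
image_volume <- function(data, spacing = c(0.625, 0.625, 0.975),
                         origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "double"
  if (any(!is.finite(data)))
    stop("intensities must be finite", call. = FALSE)
  spacing <- as.double(spacing)
  origin <- as.double(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Binary label map on an image grid
#'
#' @param mask 3D logical (or 0/1) array congruent with its companion volume.
#' @param region semantic tag for the mask:
#'   one of `"blood_pool"`, `"dilated"`, `"wall"`, `"fibrosis"`, `"exclusion"`
#'   or `"generic"`.
#' @param spacing,origin voxel geometry, as for [image_volume()].
#' @return An object of class `label_map`.
#' @export
label_map <- function(mask, region = "generic",
                      spacing = c(0.625, 0.625, 0.975), origin = c(0, 0, 0)) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array", call. = FALSE)
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1)))
      stop("`mask` values must be logical or 0/1", call. = FALSE)
    mask <- array(mask != 0, dim(mask))
  }
  if (anyNA(mask)) stop("`mask` must not contain NA", call. = FALSE)
  region <- match.arg(region, c("blood_pool", "dilated", "wall", "fibrosis",
                                "exclusion", "generic"))
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive values (mm)", call. = FALSE)
  structure(list(mask = mask, region = region, spacing = spacing,
                 origin = as.double(origin)),
            class = "label_map")
}

#' Named 3D landmark set
#'
#' Ordered anatomical fiducials in physical (mm) coordinates, used for rigid
#' registration between imaging timepoints.  Labels must be unique;
#' registration requires at least three non-collinear points.
#'
#' @param labels character vector of unique landmark names.
#' @param coords numeric matrix, one row per landmark, columns x, y, z (mm).
#' @param role `"fixed"` or `"moving"`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(labels, coords, role = c("fixed", "moving")) {
  role <- match.arg(role)
  labels <- as.character(labels)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != length(labels) || ncol(coords) != 3L)
    stop("`coords` must be an n x 3 matrix matching `labels`", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate landmark label: ",
         labels[anyDuplicated(labels)], call. = FALSE)
  if (any(!is.finite(coords)))
    stop("landmark coordinates must be finite", call. = FALSE)
  dimnames(coords) <- list(labels, c("x", "y", "z"))
  structure(list(labels = labels, coords = coords, role = role),
            class = "landmark_set")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map:", x$region, "> ", paste(dim(x$mask), collapse = " x "),
      ", ", sum(x$mask), " voxels set\n", sep = "")
  invisible(x)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set:", x$role, "> ", length(x$labels), " points\n", sep = "")
  invisible(x)
}

#' Voxel volume in cubic millimetres
#'
#' @param x an [image_volume()] or [label_map()].
#' @return `prod(spacing)` in mm^3.
#' @export
voxel_volume <- function(x) prod(x$spacing)

# shared congruence check used by every mask-pairing operation
check_congruent <- function(a, b, what = "masks") {
  da <- if (inherits(a, "image_volume")) dim(a$data) else dim(a$mask)
  db <- if (inherits(b, "image_volume")) dim(b$data) else dim(b$mask)
  if (!identical(da, db))
    stop(what, " are not congruent: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

as_mask_array <- function(x) {
  if (inherits(x, "label_map")) x$mask
  else if (is.array(x) && is.logical(x)) x
  else stop("expected a label_map or logical array", call. = FALSE)
}
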