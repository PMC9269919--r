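# LA myocardial wall extraction: in-plane dilation of the blood-pool
# chamber followed by Boolean subtraction, with an optional exclusion mask
# standing in for interactive corrections (valves, septal regions).

disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[g$di^2 + g$dj^2 <= radius^2, , drop = FALSE]
}

# shift a 3D logical array in-plane by (di, dj), zero-filling
shift2d <- function(mask, di, dj) {
  d <- dim(mask)
  out <- array(FALSE, d)
  si <- max(1, 1 + di):min(d[1], d[1] + di)
  sj <- max(1, 1 + dj):min(d[2], d[2] + dj)
  out[si, sj, ] <- mask[si - di, sj - dj, , drop = FALSE]
  out
}

#' In-plane (axial) morphological dilation
#'
#' Dilates each axial slice independently by a 2D Euclidean disk of the
#' given radius (lattice points with `di^2 + dj^2 <= radius^2`); no growth
#' occurs across slices.  A radius-4 disk covers 49 pixels.  Alternatively
#' `element = "iterated3x3"` applies `radius` iterations of a 3x3 box,
#' since the structuring element of the interactive tool this emulates is
#' not published.
#'
#' @param chamber a [label_map()] (or logical array) of the blood-pool
#'   chamber.
#' @param radius dilation radius in pixels (integer >= 1; default 4).
#' @param element `"disk"` (default) or `"iterated3x3"`.
#' @return A [label_map()] with region `"dilated"`.
#' @export
axial_dilate <- function(chamber, radius = 4, element = c("disk", "iterated3x3")) {
  element <- match.arg(element)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1)
    stop("`radius` must be a single value >= 1", call. = FALSE)
  mask <- as_mask_array(chamber)
  if (element == "disk") {
    off <- disk_offsets(radius)
    out <- mask
    for (r in seq_len(nrow(off))) {
      if (off$di[r] == 0 && off$dj[r] == 0) next
      out <- out | shift2d(mask, off$di[r], off$dj[r])
    }
  } else {
    out <- mask
    off <- expand.grid(di = -1:1, dj = -1:1)
    for (it in seq_len(as.integer(radius))) {
      cur <- out
      for (r in seq_len(nrow(off))) {
        if (off$di[r] == 0 && off$dj[r] == 0) next
        out <- out | shift2d(cur, off$di[r], off$dj[r])
      }
    }
  }
  sp <- if (inherits(chamber, "label_map")) chamber$spacing else c(0.625, 0.625, 0.975)
  og <- if (inherits(chamber, "label_map")) chamber$origin else c(0, 0, 0)
  label_map(out, region = "dilated", spacing = sp, origin = og)
}

#' Boolean removal (set difference) of one mask from another
#'
#' @param dilated,chamber congruent [label_map()]s (or logical arrays);
#'   voxels of `chamber` are removed from `dilated`.
#' @return A [label_map()] holding `dilated AND NOT chamber`.
#' @export
boolean_remove <- function(dilated, chamber) {
  a <- as_mask_array(dilated)
  b <- as_mask_array(chamber)
  if (!identical(dim(a), dim(b)))
    stop("masks are not congruent", call. = FALSE)
  sp <- if (inherits(dilated, "label_map")) dilated$spacing else c(0.625, 0.625, 0.975)
  og <- if (inherits(dilated, "label_map")) dilated$origin else c(0, 0, 0)
  label_map(a & !b, region = "wall", spacing = sp, origin = og)
}

#' Extract the LA myocardial wall from a blood-pool mask
#'
#' Composes [axial_dilate()] and [boolean_remove()], then removes any
#' voxels of the optional exclusion mask (the file-based stand-in for
#' interactive removal of valves and septal regions).
#'
#' @param chamber blood-pool [label_map()]; must be non-empty.
#' @param exclusion optional congruent [label_map()] of voxels to drop from
#'   the wall.
#' @param radius in-plane dilation radius in pixels (default 4).
#' @param element structuring element, see [axial_dilate()].
#' @return A list of class `wall_segmentation` with elements `dilated`,
#'   `wall` (both [label_map()]s) and `excluded_voxel_count`.
#' @export
extract_wall <- function(chamber, exclusion = NULL, radius = 4,
                         element = c("disk", "iterated3x3")) {
  mask <- as_mask_array(chamber)
  if (!any(mask))
    stop("empty chamber mask: no wall derivable", call. = FALSE)
  dil <- axial_dilate(chamber, radius = radius, element = element)
  wall <- boolean_remove(dil, chamber)
  excluded <- 0L
  if (!is.null(exclusion)) {
    ex <- as_mask_array(exclusion)
    if (!identical(dim(ex), dim(wall$mask)))
      stop("exclusion mask not congruent with chamber", call. = FALSE)
    excluded <- sum(wall$mask & ex)
    wall$mask <- wall$mask & !ex
  }
  structure(list(dilated = dil, wall = wall,
                 excluded_voxel_count = as.integer(excluded)),
            class = "wall_segmentation")
}

#' @export
print.wall_segmentation <- function(x, ...) {
  cat("<wall_segmentation> wall: ", sum(x$wall$mask), " voxels (",
      x$excluded_voxel_count, " excluded)\n", sep = "")
  invisible(x)
}
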