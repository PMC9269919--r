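#' Read a 3D scalar volume (NRRD or NIfTI)
#'
#' NRRD (`.nrrd`, attached or detached data, raw or gzip encoded) is the
#' canonical dialect; NIfTI-1 (`.nii`, `.nii.gz`) is accepted for
#' interoperability.  Geometry is taken from the header; a header with no
#' voxel spacing falls back to the study's acquisition geometry
#' (0.625 x 0.625 x 0.975 mm) with a warning.  Only axis-aligned grids are
#' supported; oblique direction matrices are rejected.
#'
#' @param path path to a `.nrrd`, `.nhdr`, `.nii` or `.nii.gz` file.
#' @param format_hint optional `"nrrd"` or `"nifti"`, overriding the
#'   extension-based dispatch.
#' @return An [image_volume()].
#' @seealso [write_volume()], [read_landmarks()]
#' @export
read_volume <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- format_hint %||% guess_format(path)
  if (fmt == "nrrd") {
    v <- read_nrrd(path)
    image_volume(v$data, spacing = v$spacing, origin = v$origin)
  } else {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) > 3L) {
      d <- dim(img)
      if (all(d[-(1:3)] == 1L)) img <- array(img, d[1:3])
      else stop("unsupported content: volume has ", length(d),
                " dimensions", call. = FALSE)
    }
    xf <- RNifti::xform(img)
    rot <- abs(xf[1:3, 1:3]); diag(rot) <- 0
    if (any(rot > 1e-6))
      stop("non-axis-aligned NIfTI orientation is not supported",
           call. = FALSE)
    spacing <- abs(diag(xf[1:3, 1:3]))
    origin <- xf[1:3, 4]
    if (any(spacing <= 0) || all(spacing == 1) && attr(xf, "code") == 0) {
      pd <- RNifti::pixdim(img)[1:3]
      if (all(pd > 0)) spacing <- pd
    }
    if (any(!is.finite(spacing)) || any(spacing <= 0)) {
      warning("NIfTI header carries no voxel spacing; ",
              "defaulting to 0.625 x 0.625 x 0.975 mm", call. = FALSE)
      spacing <- c(0.625, 0.625, 0.975)
    }
    image_volume(array(as.double(img), dim(img)), spacing = spacing,
                 origin = origin)
  }
}

#' Write a volume or label map to NRRD or NIfTI
#'
#' Format follows the file extension (`.nrrd` default dialect; `.nii` /
#' `.nii.gz` for NIfTI).  Label maps are written as 8-bit 0/1; intensity
#' volumes as double precision, so geometry and voxel values round-trip
#' exactly.
#'
#' @param vol an [image_volume()] or [label_map()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  is_label <- inherits(vol, "label_map")
  if (!is_label && !inherits(vol, "image_volume"))
    stop("`vol` must be an image_volume or label_map", call. = FALSE)
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  data <- if (is_label) array(as.integer(vol$mask), dim(vol$mask)) else vol$data
  fmt <- guess_format(path)
  if (fmt == "nrrd") {
    write_nrrd(data, path, spacing = vol$spacing, origin = vol$origin,
               type = if (is_label) "uint8" else "double")
  } else {
    img <- RNifti::asNifti(data)
    RNifti::pixdim(img) <- vol$spacing
    m <- diag(4)
    m[1:3, 1:3] <- diag(vol$spacing)
    m[1:3, 4] <- vol$origin
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

guess_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.(nrrd|nhdr)$", lp)) "nrrd"
  else if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else stop("cannot infer volume format from extension: ", basename(path),
            call. = FALSE)
}

#' Read a landmark table (CSV / FCSV dialect)
#'
#' Expects columns `label,x,y,z` (header required); lines starting with `#`
#' (as written by Slicer-style FCSV files) are skipped.  Labels must be
#' unique and coordinates numeric; row order is preserved.
#'
#' @param path path to the landmark table.
#' @param role `"fixed"` or `"moving"` role tag for the resulting set.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, role = c("fixed", "moving")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("landmark table has no data rows: ", path, call. = FALSE)
  tab <- utils::read.csv(text = paste(lines, collapse = "\n"),
                         stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("landmark table must have columns label,x,y,z", call. = FALSE)
  coords <- as.matrix(tab[, c("x", "y", "z")])
  if (!is.numeric(coords) || any(!is.finite(coords)))
    stop("non-numeric landmark coordinate in ", path, call. = FALSE)
  landmark_set(tab$label, coords, role = role)
}

#' Write a landmark table as CSV
#'
#' @param lm a [landmark_set()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  df <- data.frame(label = lm$labels, x = lm$coords[, 1], y = lm$coords[, 2],
                   z = lm$coords[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
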