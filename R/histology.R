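#' Percent fibrosis from a Masson's-trichrome RGB slide
#'
#' Pixels are converted to hue/saturation/value; background is excluded by
#' low saturation or high value, and the remaining tissue pixels are
#' classified blue (collagen, i.e. fibrosis) versus red (myocytes) by hue
#' interval.  Percent fibrosis is the blue share of tissue pixels.
#'
#' The default hue window for collagen is `[90, 270)` degrees with
#' everything else counted as red/magenta tissue; background is
#' `saturation < 0.15` or `value > 0.95`.  All cutoffs are configurable
#' because staining intensity varies between labs.
#'
#' @param image `height x width x 3` RGB array in `[0, 1]`, a
#'   `trichrome_slide` from [generate_trichrome_image()], or a path to a
#'   PNG (or TIFF, if the `tiff` package is installed) file.
#' @param hue_blue collagen hue interval in degrees, `[low, high)`.
#' @param background_saturation pixels below this saturation are
#'   background.
#' @param background_value pixels above this value (brightness) are
#'   background.
#' @return A list of class `trichrome_classification`: `n_fibrotic`,
#'   `n_nonfibrotic`, `n_background`, `percent_fibrosis`.
#' @export
percent_fibrosis_trichrome <- function(image, hue_blue = c(90, 270),
                                       background_saturation = 0.15,
                                       background_value = 0.95) {
  if (inherits(image, "trichrome_slide")) image <- image$rgb
  if (is.character(image)) image <- read_rgb_image(image)
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("`image` must be an RGB array (height x width x 3)", call. = FALSE)
  n_px <- prod(dim(image)[1:2])
  rgbm <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)
  hue <- hsv[1, ] * 360
  bg <- hsv[2, ] < background_saturation | hsv[3, ] > background_value
  tissue <- !bg
  if (!any(tissue))
    stop("no tissue pixels after background exclusion", call. = FALSE)
  blue <- tissue & hue >= hue_blue[1] & hue < hue_blue[2]
  n_fib <- sum(blue)
  n_non <- sum(tissue) - n_fib
  structure(list(n_fibrotic = as.integer(n_fib),
                 n_nonfibrotic = as.integer(n_non),
                 n_background = as.integer(n_px - n_fib - n_non),
                 percent_fibrosis = 100 * n_fib / (n_fib + n_non)),
            class = "trichrome_classification")
}

read_rgb_image <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.png$", lp)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", lp)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF slides requires the 'tiff' package", call. = FALSE)
    img <- tiff::readTIFF(path)
  } else stop("unsupported slide format: ", basename(path), call. = FALSE)
  if (length(dim(img)) == 3L && dim(img)[3] > 3L)
    img <- img[, , 1:3, drop = FALSE]   # drop alpha
  img
}

#' Write a trichrome slide to PNG
#'
#' @param slide a `trichrome_slide`.
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_trichrome_png <- function(slide, path) {
  stopifnot(inherits(slide, "trichrome_slide"))
  png::writePNG(slide$rgb, path)
  invisible(path)
}

#' Per-animal and group summaries of slice-wise histology fibrosis
#'
#' Averages the slice-wise percent-fibrosis values within each animal
#' (missing slices simply absent), then summarizes the per-animal averages
#' per group with [group_summary()].
#'
#' @param per_slice data frame with columns `animal`, `percent_fibrosis`
#'   and optionally `group` (defaults to a single group) and `slice`.
#' @return A list: `per_animal` (data frame animal, group, n_slices,
#'   mean_percent), `group` (named list of [group_summary()] results, plus
#'   `all` across every animal).
#' @export
histology_summaries <- function(per_slice) {
  if (!is.data.frame(per_slice) || nrow(per_slice) == 0L)
    stop("`per_slice` must be a non-empty data frame", call. = FALSE)
  if (!all(c("animal", "percent_fibrosis") %in% names(per_slice)))
    stop("`per_slice` needs columns animal, percent_fibrosis", call. = FALSE)
  if (is.null(per_slice$group)) per_slice$group <- "all"
  ok <- !is.na(per_slice$percent_fibrosis)
  per_slice <- per_slice[ok, , drop = FALSE]
  sp <- split(per_slice, per_slice$animal)
  per_animal <- do.call(rbind, lapply(sp, function(d)
    data.frame(animal = d$animal[1], group = d$group[1],
               n_slices = nrow(d),
               mean_percent = mean(d$percent_fibrosis))))
  per_animal <- per_animal[order(match(per_animal$animal,
                                       unique(per_slice$animal))), ]
  rownames(per_animal) <- NULL
  groups <- split(per_animal$mean_percent, per_animal$group)
  out <- lapply(groups, group_summary)
  out$all <- group_summary(per_animal$mean_percent)
  list(per_animal = per_animal, group = out)
}
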