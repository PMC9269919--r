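# Synthetic LGE-CMR phantom generator with known ground truth.
#
# The phantom is a bright ellipsoidal blood-pool chamber surrounded by a
# thin myocardial wall (the in-plane annulus obtained by dilating each
# chamber cross-section by the wall thickness), with contiguous patches of
# enhancing (fibrotic) wall voxels at a controllable fraction, Rician
# magnitude noise, and 13 labelled anatomical-surrogate landmarks.

# run `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

shift_mask <- function(mask, dx, dy, dz = 0) {
  d <- dim(mask)
  out <- array(FALSE, d)
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[xs, ys, zs] <- mask[xs - dx, ys - dy, zs - dz, drop = FALSE]
  out
}

dilate_cross <- function(mask, offsets) {
  out <- mask
  for (o in offsets) out <- out | shift_mask(mask, o[1], o[2], o[3])
  out
}

# grow contiguous patches inside `allowed` until exactly `target` voxels
# are set; seeds and any re-seeding are drawn from the current RNG stream,
# ring-by-ring growth and trimming are deterministic (linear-index order)
grow_patches <- function(allowed, target, n_seeds, offsets) {
  if (target <= 0L) return(array(FALSE, dim(allowed)))
  avail <- which(allowed)
  if (target > length(avail))
    stop("patch target exceeds available voxels", call. = FALSE)
  cur <- array(FALSE, dim(allowed))
  seeds <- sample(avail, min(n_seeds, target))
  cur[seeds] <- TRUE
  while (sum(cur) < target) {
    frontier <- dilate_cross(cur, offsets) & allowed & !cur
    need <- target - sum(cur)
    idx <- which(frontier)
    if (length(idx) == 0L) {                      # component exhausted
      rest <- setdiff(which(allowed), which(cur))
      cur[rest[sample.int(length(rest), 1L)]] <- TRUE
      next
    }
    cur[idx[seq_len(min(need, length(idx)))]] <- TRUE
  }
  cur
}

offsets6 <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
offsets4 <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))

#' Phantom specification
#'
#' Collects all parameters of the synthetic LGE-CMR phantom.  The default
#' intensity means (blood 600, healthy wall 360, fibrotic wall 840) put
#' the noise-free normalized intensities at 0.6 and 1.4, bracketing the
#' 0.9-1.3 range of fibrosis thresholds seen in practice.
#'
#' @param grid_shape voxel grid dimensions (nx, ny, nz).
#' @param spacing voxel spacing in mm.
#' @param chamber_semi_axes_mm ellipsoid semi-axes of the blood pool (mm).
#' @param wall_thickness wall thickness in voxels (in-plane; >= 1).
#' @param fibrosis_fraction target fibrotic fraction f of wall voxels,
#'   in `[0, 1)`.
#' @param intensity_means named or positional triple (blood, healthy wall,
#'   fibrotic wall) in arbitrary units.
#' @param noise_sigma Rician noise sigma (>= 0) in the same units.
#' @param n_patches number of fibrotic patch seeds.
#' @param seed integer seed; identical specs with identical seeds generate
#'   bit-identical phantoms.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(36L, 36L, 30L),
                         spacing = c(0.625, 0.625, 0.975),
                         chamber_semi_axes_mm = c(6.25, 5.625, 11.7),
                         wall_thickness = 4L,
                         fibrosis_fraction = 0.05,
                         intensity_means = c(blood = 600, healthy = 360,
                                             fibrotic = 840),
                         noise_sigma = 20,
                         n_patches = 3L,
                         seed = 1L) {
  if (fibrosis_fraction < 0 || fibrosis_fraction >= 1)
    stop("`fibrosis_fraction` must be in [0, 1)", call. = FALSE)
  if (wall_thickness < 1) stop("`wall_thickness` must be >= 1", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (intensity_means[1] <= 0) stop("blood intensity must be > 0", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.double(spacing),
                 chamber_semi_axes_mm = as.double(chamber_semi_axes_mm),
                 wall_thickness = as.integer(wall_thickness),
                 fibrosis_fraction = fibrosis_fraction,
                 intensity_means = as.double(intensity_means),
                 noise_sigma = noise_sigma,
                 n_patches = as.integer(n_patches),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

landmark_names <- c(
  "ascending aorta", "descending aorta", "aortic arch",
  "left pulmonary artery", "right pulmonary artery",
  "left superior pulmonary vein", "left inferior pulmonary vein",
  "right superior pulmonary vein", "right inferior pulmonary vein",
  "left atrioventricular septum", "left atrial appendage",
  "left anterior descending artery", "aortic valve")

phantom_landmarks <- function(spec, role = "moving") {
  d <- spec$grid_shape
  sp <- spec$spacing
  center <- (d - 1) / 2 * sp
  semi <- spec$chamber_semi_axes_mm + spec$wall_thickness * sp + 2 * sp
  # 13 fixed, well-separated directions on the surrogate surface
  theta <- seq(0, 2 * pi, length.out = 14)[1:13] + 0.3
  phi <- rep(c(-0.9, -0.3, 0.3, 0.9), length.out = 13)
  dirs <- cbind(cos(phi) * cos(theta), cos(phi) * sin(theta), sin(phi))
  coords <- sweep(sweep(dirs, 2, semi, `*`), 2, center, `+`)
  landmark_set(landmark_names, coords, role = role)
}

#' Generate a synthetic LA phantom
#'
#' Builds the noise-free class image (blood pool at the blood mean, wall
#' at the healthy/fibrotic means, background at 0), applies Rician noise
#' `|(S + g1) + i g2|` with `g ~ N(0, sigma)`, and returns the magnitude
#' image together with the noise-free ground-truth masks, the achieved
#' fibrotic percentage, and 13 labelled landmarks.
#'
#' The wall is the in-plane annulus obtained by dilating each axial
#' chamber cross-section by `wall_thickness` pixels and removing the
#' chamber, so a matched-radius morphological wall extraction recovers it
#' exactly.  Fibrotic voxels form contiguous patches grown on the wall to
#' the achievable count nearest `f * |wall|`.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `la_phantom`: `image` ([image_volume()]),
#'   `truth` (list with `blood_pool_mask`, `wall_mask`, `fibrosis_mask`,
#'   `true_percent_mf`, `landmarks`, `applied_transform` (NULL unless set
#'   by [generate_paired_study()])).
#' @export
generate_la_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing
  semi_vox <- spec$chamber_semi_axes_mm / sp
  center <- (d + 1) / 2
  # wall grows in-plane only, so the axial axis needs just 1 voxel margin
  if (any(semi_vox[1:2] + spec$wall_thickness + 1 > (d[1:2] - 1) / 2) ||
      semi_vox[3] + 1 > (d[3] - 1) / 2)
    stop("chamber (plus wall margin) does not fit inside the grid",
         call. = FALSE)
  ii <- (seq_len(d[1]) - center[1]) / semi_vox[1]
  jj <- (seq_len(d[2]) - center[2]) / semi_vox[2]
  kk <- (seq_len(d[3]) - center[3]) / semi_vox[3]
  r2 <- outer(outer(ii^2, jj^2, `+`), kk^2, `+`)
  chamber <- r2 <= 1

  wall <- axial_dilate(label_map(chamber, "blood_pool", sp),
                       radius = spec$wall_thickness)$mask & !chamber
  n_wall <- sum(wall)
  target <- as.integer(round(spec$fibrosis_fraction * n_wall))

  with_seed(spec$seed, {
    fib <- grow_patches(wall, target, spec$n_patches, offsets6)
    mu <- spec$intensity_means
    signal <- array(0, d)
    signal[chamber] <- mu[1]
    signal[wall & !fib] <- mu[2]
    signal[fib] <- mu[3]
    img <- if (spec$noise_sigma > 0) {
      g1 <- array(stats::rnorm(prod(d), 0, spec$noise_sigma), d)
      g2 <- array(stats::rnorm(prod(d), 0, spec$noise_sigma), d)
      sqrt((signal + g1)^2 + g2^2)
    } else signal
    lm <- phantom_landmarks(spec)
    structure(list(
      image = image_volume(img, spacing = sp),
      truth = list(
        blood_pool_mask = label_map(chamber, "blood_pool", sp),
        wall_mask = label_map(wall, "wall", sp),
        fibrosis_mask = label_map(fib, "fibrosis", sp),
        true_percent_mf = 100 * target / n_wall,
        landmarks = lm,
        applied_transform = NULL)),
      class = "la_phantom")
  })
}

#' Generate a paired baseline / post-pacing phantom study
#'
#' The post-timepoint phantom carries fibrosis fraction
#' `f_baseline + delta_f` and its landmarks are moved by a known rigid
#' transform (rotation about the axial axis through the volume centre plus
#' an in-plane shift), recorded in `post$truth$applied_transform` as the
#' mapping from baseline to post landmark space.
#'
#' @param spec_baseline baseline [phantom_spec()].
#' @param delta_f fibrosis-fraction increment (baseline f + delta in
#'   `[0, 1)`).
#' @param rigid_jitter numeric pair `(angle_deg, shift_mm)` for the
#'   recorded pose change.
#' @param seed integer; sub-seeds for the two timepoints derive from it.
#' @return List with elements `baseline` and `post`, each an `la_phantom`.
#' @export
generate_paired_study <- function(spec_baseline, delta_f = 0.02,
                                  rigid_jitter = c(5, 2), seed = 1L) {
  f_post <- spec_baseline$fibrosis_fraction + delta_f
  if (f_post < 0 || f_post >= 1)
    stop("baseline fraction + delta_f must stay in [0, 1)", call. = FALSE)
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))
  spec_b <- spec_baseline
  spec_b$seed <- sub[1]
  spec_p <- spec_baseline
  spec_p$fibrosis_fraction <- f_post
  spec_p$seed <- sub[2]
  baseline <- generate_la_phantom(spec_b)
  post <- generate_la_phantom(spec_p)
  center <- (spec_baseline$grid_shape - 1) / 2 * spec_baseline$spacing
  tr <- rigid_transform(angle_deg = rigid_jitter[1],
                        translation = c(rigid_jitter[2], 0, 0),
                        center = center)
  post$truth$landmarks <- transform_points(tr, baseline$truth$landmarks)
  post$truth$landmarks$role <- "fixed"
  post$truth$applied_transform <- tr
  list(baseline = baseline, post = post)
}

#' Generate a synthetic Masson's-trichrome slide
#'
#' An RGB image with a near-white background, an elliptical tissue region
#' of red (non-fibrotic) pixels, and contiguous blue (collagen) blobs
#' covering exactly `round(f * n_tissue)` tissue pixels.
#'
#' @param width,height image size in pixels.
#' @param fibrosis_fraction target blue fraction f of tissue pixels,
#'   `[0, 1]`.
#' @param background_fraction fraction of image pixels outside the tissue
#'   ellipse (feasible range about 0.22-0.95).
#' @param n_blobs number of blue blob seeds.
#' @param seed integer seed; identical calls are bit-identical.
#' @return A list of class `trichrome_slide`: `rgb` (`height x width x 3`
#'   array in `[0, 1]`), `true_f`, `n_tissue`, `n_blue`.
#' @export
generate_trichrome_image <- function(width = 512L, height = 512L,
                                     fibrosis_fraction = 0.2,
                                     background_fraction = 0.3,
                                     n_blobs = 5L, seed = 1L) {
  f <- fibrosis_fraction
  if (f < 0 || f > 1) stop("`fibrosis_fraction` must be in [0, 1]",
                           call. = FALSE)
  scale2 <- 4 * (1 - background_fraction) / pi
  if (scale2 > 1 || background_fraction >= 1)
    stop("impossible background fraction: tissue ellipse does not fit",
         call. = FALSE)
  s <- sqrt(scale2)
  yy <- (seq_len(height) - (height + 1) / 2) / (s * height / 2)
  xx <- (seq_len(width) - (width + 1) / 2) / (s * width / 2)
  tissue <- outer(yy^2, xx^2, `+`) <= 1
  n_tissue <- sum(tissue)
  target <- as.integer(round(f * n_tissue))
  tissue3 <- array(tissue, c(height, width, 1))   # reuse 3D growth helpers
  blue3 <- with_seed(seed, grow_patches(tissue3, target, n_blobs, offsets4))
  blue <- blue3[, , 1]
  hsv_px <- function(h, s_, v) grDevices::col2rgb(grDevices::hsv(h, s_, v)) / 255
  col_bg <- hsv_px(0.10, 0.03, 0.98)
  col_red <- hsv_px(355 / 360, 0.60, 0.75)
  col_blue <- hsv_px(220 / 360, 0.65, 0.55)
  rgb <- array(0, c(height, width, 3))
  for (ch in 1:3) {
    plane <- array(col_bg[ch], c(height, width))
    plane[tissue & !blue] <- col_red[ch]
    plane[blue] <- col_blue[ch]
    rgb[, , ch] <- plane
  }
  structure(list(rgb = rgb, true_f = if (n_tissue) target / n_tissue else 0,
                 n_tissue = n_tissue, n_blue = target),
            class = "trichrome_slide")
}

#' @export
print.la_phantom <- function(x, ...) {
  cat(sprintf("<la_phantom> %s voxels, true %%MF = %.2f\n",
              paste(dim(x$image$data), collapse = "x"),
              x$truth$true_percent_mf))
  invisible(x)
}
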