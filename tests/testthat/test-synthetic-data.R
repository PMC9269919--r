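test_that("noise-free phantom has exact class intensities and ground truth", {
  spec <- small_spec(noise_sigma = 0, fibrosis_fraction = 0.10, seed = 21)
  ph <- generate_la_phantom(spec)
  tr <- ph$truth
  # set relations
  expect_true(all(tr$fibrosis_mask$mask <= tr$wall_mask$mask))
  expect_false(any(tr$wall_mask$mask & tr$blood_pool_mask$mask))
  # achieved fraction within one-voxel quantization of the request
  n_wall <- sum(tr$wall_mask$mask)
  expect_lt(abs(tr$true_percent_mf - 10), 100 / n_wall)
  expect_equal(tr$true_percent_mf,
               100 * sum(tr$fibrosis_mask$mask) / n_wall)
  # noise-free limit: every blood-pool voxel at mu_blood exactly
  expect_true(all(ph$image$data[tr$blood_pool_mask$mask] ==
                    spec$intensity_means[1]))
  expect_true(all(ph$image$data[tr$fibrosis_mask$mask] ==
                    spec$intensity_means[3]))
  # 13 unique labelled landmarks
  expect_equal(length(tr$landmarks$labels), 13L)
  expect_equal(anyDuplicated(tr$landmarks$labels), 0L)
})

test_that("identical seeds give bit-identical phantoms; different seeds differ", {
  spec <- small_spec(noise_sigma = 15, fibrosis_fraction = 0.08, seed = 22)
  a <- generate_la_phantom(spec)
  b <- generate_la_phantom(spec)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$fibrosis_mask$mask, b$truth$fibrosis_mask$mask)
  spec2 <- spec; spec2$seed <- 23L
  c <- generate_la_phantom(spec2)
  expect_false(identical(a$image$data, c$image$data))
})

test_that("fibrotic voxels form contiguous patches on the wall", {
  ph <- generate_la_phantom(small_spec(noise_sigma = 0,
                                       fibrosis_fraction = 0.10,
                                       n_patches = 2L, seed = 24))
  fib <- ph$truth$fibrosis_mask$mask
  # count 6-connected components by flood fill; must be <= seeds used
  remaining <- which(fib)
  d <- dim(fib)
  comp <- 0L
  visited <- array(FALSE, d)
  while (length(remaining)) {
    comp <- comp + 1L
    queue <- remaining[1]
    visited[queue] <- TRUE
    while (length(queue)) {
      ijk <- arrayInd(queue, d)
      nxt <- c()
      for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        nb <- sweep(ijk, 2, o, `+`)
        keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
          nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
        nb <- nb[keep, , drop = FALSE]
        lin <- nb[, 1] + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
        lin <- lin[fib[lin] & !visited[lin]]
        visited[lin] <- TRUE
        nxt <- c(nxt, lin)
      }
      queue <- unique(nxt)
    }
    remaining <- setdiff(which(fib & !visited), integer(0))
    remaining <- which(fib & !visited)
  }
  expect_lte(comp, 2L)
})

test_that("Rician background obeys the Rayleigh mean/SD relations", {
  sigma <- 20
  ph <- generate_la_phantom(phantom_spec(grid_shape = c(48L, 48L, 24L),
                                         chamber_semi_axes_mm = c(8, 8, 8),
                                         noise_sigma = sigma, seed = 25))
  bg <- !(ph$truth$blood_pool_mask$mask | ph$truth$wall_mask$mask)
  x <- ph$image$data[bg]
  n <- length(x)
  expect_gte(n, 1e4)
  mu_th <- sigma * sqrt(pi / 2)
  sd_th <- sigma * sqrt(2 - pi / 2)
  expect_lt(abs(mean(x) - mu_th), 3 * sd_th / sqrt(n))
  # SE of the sample SD of a Rayleigh variate, normal approximation
  expect_lt(abs(sd(x) - sd_th), 3 * sd_th / sqrt(2 * (n - 1)) * 2)
})

test_that("noise-free NI calibration brackets the plausible threshold range", {
  spec <- small_spec(noise_sigma = 0, fibrosis_fraction = 0.05, seed = 26)
  ph <- generate_la_phantom(spec)
  nz <- iir_normalize(ph$image, ph$truth$blood_pool_mask,
                      ph$truth$wall_mask)
  ni_healthy <- unique(nz$nw$ni[!ph$truth$fibrosis_mask$mask[nz$nw$idx]])
  ni_fib <- unique(nz$nw$ni[ph$truth$fibrosis_mask$mask[nz$nw$idx]])
  expect_equal(ni_healthy, 0.6)
  expect_equal(ni_fib, 1.4)
})

test_that("paired studies carry the requested increment and a consistent transform", {
  spec <- small_spec(noise_sigma = 0, fibrosis_fraction = 0.05, seed = 27)
  pr <- generate_paired_study(spec, delta_f = 0.02, rigid_jitter = c(11, 3),
                              seed = 27)
  n_wall <- sum(pr$baseline$truth$wall_mask$mask)
  expect_lt(abs((pr$post$truth$true_percent_mf -
                   pr$baseline$truth$true_percent_mf) - 2.0),
            2 * 100 / n_wall)
  mapped <- transform_points(pr$post$truth$applied_transform,
                             pr$baseline$truth$landmarks$coords)
  expect_lt(max(abs(mapped - pr$post$truth$landmarks$coords)), 1e-9)

  # no increment, no jitter: identical truth fractions up to quantization
  pr0 <- generate_paired_study(spec, delta_f = 0, rigid_jitter = c(0, 0),
                               seed = 28)
  expect_equal(pr0$baseline$truth$true_percent_mf,
               pr0$post$truth$true_percent_mf)
  expect_equal(pr0$post$truth$applied_transform$rotation, diag(3))
  expect_error(generate_paired_study(spec, delta_f = 0.99), "\\[0, 1\\)")
})

test_that("trichrome slides hit the requested blue fraction exactly", {
  sl <- generate_trichrome_image(192, 160, fibrosis_fraction = 0.30,
                                 seed = 31)
  expect_lt(abs(sl$n_blue / sl$n_tissue - 0.30), 1 / sl$n_tissue + 1e-12)
  sl0 <- generate_trichrome_image(96, 96, fibrosis_fraction = 0, seed = 31)
  expect_equal(sl0$n_blue, 0L)
  a <- generate_trichrome_image(64, 64, 0.2, seed = 5)
  b <- generate_trichrome_image(64, 64, 0.2, seed = 5)
  expect_identical(a$rgb, b$rgb)
})
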