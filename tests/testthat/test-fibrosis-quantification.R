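make_grid <- function(vals, dims = c(4, 4, 4)) {
  image_volume(array(vals, dims), spacing = c(1, 1, 1))
}

test_that("IIR normalization divides by the blood-pool mean and is scale invariant", {
  d <- c(6, 6, 4)
  set.seed(51)
  img <- image_volume(array(runif(prod(d), 50, 150), d))
  pool <- label_map(array(rep(c(TRUE, FALSE), length.out = prod(d)), d))
  wall <- label_map(array(rep(c(FALSE, TRUE), length.out = prod(d)), d))
  nz <- iir_normalize(img, pool, wall)
  expect_equal(nz$stats$mu_bp, mean(img$data[pool$mask]))
  # direct-summation oracle for mu_NI over the wall voxel list
  expect_equal(nz$nw$mu_ni,
               sum(img$data[wall$mask] / nz$stats$mu_bp) / sum(wall$mask))

  # constant image: NI = 1 everywhere on the wall, sigma 0
  cimg <- make_grid(7.5, d)
  nzc <- iir_normalize(cimg, pool, wall)
  expect_true(all(nzc$nw$ni == 1))
  expect_equal(nzc$nw$sigma_ni, 0)

  # multiplying all intensities leaves %MF identical; offsets do not
  t1 <- fibrosis_threshold(nz$nw)
  p1 <- percent_mf_volumetric(nz$nw, t1)
  for (c_scale in c(2, 7, 0.35)) {
    scaled <- image_volume(img$data * c_scale, spacing = img$spacing)
    nzs <- iir_normalize(scaled, pool, wall)
    ps <- percent_mf_volumetric(nzs$nw, fibrosis_threshold(nzs$nw))
    expect_identical(ps$percent_mf, p1$percent_mf)
    expect_identical(ps$mf_voxels, p1$mf_voxels)
  }
  shifted <- image_volume(img$data + 40, spacing = img$spacing)
  nzo <- iir_normalize(shifted, pool, wall)
  expect_false(isTRUE(all.equal(nzo$nw$ni, nz$nw$ni)))

  expect_error(iir_normalize(img, label_map(array(FALSE, d)), wall),
               "empty")
})

test_that("threshold is mean IIR + k SD with configurable k", {
  nw <- normalized_wall(c(0.95, 1.05))  # mu 1.0, sd ~0.0707
  expect_equal(fibrosis_threshold(nw), 1 + 2 * sd(c(0.95, 1.05)))
  # forced arithmetic: mu 1.0 sigma 0.05 -> 1.10
  nw2 <- normalized_wall(c(1 - 0.05 / sqrt(2), 1 + 0.05 / sqrt(2)))
  expect_equal(fibrosis_threshold(nw2), 1.10)
  expect_equal(fibrosis_threshold(nw2, k_sd = 4), 1.20)
  # mu 0.9 sigma 0.2 -> 1.3, top of the observed threshold range
  nw3 <- normalized_wall(c(0.9 - 0.2 / sqrt(2), 0.9 + 0.2 / sqrt(2)))
  expect_equal(fibrosis_threshold(nw3), 1.3)
  # degenerate: zero SD
  nw4 <- normalized_wall(c(1, 1, 1))
  expect_equal(fibrosis_threshold(nw4), 1)
  expect_error(fibrosis_threshold(normalized_wall(1)), "fewer than 2")
})

test_that("volumetric %MF counts strict exceedances times voxel volume", {
  ni <- c(rep(0.8, 90), rep(1.5, 10))
  nw <- normalized_wall(ni, spacing = c(0.625, 0.625, 0.975))
  out <- percent_mf_volumetric(nw, 1.2)
  expect_equal(out$mf_voxels, 10L)
  expect_equal(out$percent_mf, 10)
  expect_equal(out$wall_volume_mm3, 100 * 0.625^2 * 0.975)
  # 100 fibrotic voxels at the acquisition spacing
  nw2 <- normalized_wall(rep(2, 100), spacing = c(0.625, 0.625, 0.975))
  expect_equal(percent_mf_volumetric(nw2, 1)$mf_volume_mm3, 38.0859375)
  # boundary equality is non-fibrotic (strict >)
  expect_equal(percent_mf_volumetric(normalized_wall(rep(1.2, 5)), 1.2)$percent_mf,
               0)
})

test_that("noise-free binary wall: %MF = 100f below f = 0.2, 0 above", {
  for (f in c(0.02, 0.05, 0.1, 0.15)) {
    n <- 2000L
    k <- round(f * n)
    nw <- normalized_wall(c(rep(1.4, k), rep(0.6, n - k)))
    pm <- percent_mf_volumetric(nw, fibrosis_threshold(nw))
    expect_equal(pm$percent_mf, 100 * k / n, label = paste("f =", f))
  }
  for (f in c(0.25, 0.4)) {
    n <- 2000L
    k <- round(f * n)
    nw <- normalized_wall(c(rep(1.4, k), rep(0.6, n - k)))
    pm <- percent_mf_volumetric(nw, fibrosis_threshold(nw))
    expect_equal(pm$percent_mf, 0, label = paste("f =", f))
  }
})

test_that("Gaussian fibrosis-free wall converges to 100*pnorm(-2) percent", {
  set.seed(52)
  ni <- rnorm(2e5, mean = 1, sd = 0.08)
  nw <- normalized_wall(ni)
  pm <- percent_mf_volumetric(nw, fibrosis_threshold(nw))
  expect_lt(abs(pm$percent_mf - 100 * pnorm(-2)), 0.5)
})

test_that("slice-wise %MF picks the argmax slice with low-k tie break", {
  d <- c(4, 4, 8)
  arr <- array(0.5, d)
  wall <- array(TRUE, d)
  arr[1:2, 1:2, 5] <- 2      # 4 fibrotic voxels in slice 5
  arr[1, 1, 3] <- 2          # 1 in slice 3
  nw <- normalized_wall(arr[wall], idx = which(wall), dim = d)
  out <- percent_mf_slicewise(nw, 1.0)
  expect_equal(out$slice, 5L)
  expect_equal(out$percent_mf, 100 * 4 / 16)
  expect_false(out$tie)

  # tie: equal counts in slices 2 and 6 -> lowest k wins, flagged
  arr2 <- array(0.5, d)
  arr2[1:2, 1, 2] <- 2
  arr2[3:4, 2, 6] <- 2
  nw2 <- normalized_wall(arr2[wall], idx = which(wall), dim = d)
  out2 <- percent_mf_slicewise(nw2, 1.0)
  expect_equal(out2$slice, 2L)
  expect_true(out2$tie)

  # exhaustive per-slice scan oracle on a phantom
  ph <- generate_la_phantom(small_spec(fibrosis_fraction = 0.08, seed = 53))
  nz <- iir_normalize(ph$image, ph$truth$blood_pool_mask, ph$truth$wall_mask)
  tf <- fibrosis_threshold(nz$nw)
  got <- percent_mf_slicewise(nz$nw, tf)
  kidx <- arrayInd(nz$nw$idx, nz$nw$dim)[, 3]
  best <- 0; bestk <- NA; bestpct <- NA
  for (k in sort(unique(kidx))) {
    cnt <- sum(nz$nw$ni[kidx == k] > tf)
    if (cnt > best) {
      best <- cnt; bestk <- k
      bestpct <- 100 * cnt / sum(kidx == k)
    }
  }
  expect_equal(got$slice, bestk)
  expect_equal(got$percent_mf, bestpct)

  # no enhancement anywhere is an error distinct from 0%%
  expect_error(percent_mf_slicewise(normalized_wall(rep(0.5, 10)), 1.0),
               "no enhanced voxel")
})

test_that("d_abs keeps sign and group_summary matches printed-precision arithmetic", {
  expect_equal(d_abs(5, 5), 0)
  expect_equal(d_abs(3.59, 2.94), -0.65)
  expect_equal(d_abs(1.27, 2.80), 1.53)

  gs <- group_summary(c(2, 4, 4, 4, 5, 5, 7, 9))
  expect_equal(gs$mean, 5)
  expect_equal(gs$sd, sd(c(2, 4, 4, 4, 5, 5, 7, 9)))
  expect_equal(gs$median, 4.5)
  expect_equal(gs$iqr, IQR(c(2, 4, 4, 4, 5, 5, 7, 9), type = 7))
  one <- group_summary(3.2)
  expect_equal(one$mean, 3.2)
  expect_equal(one$median, 3.2)
  expect_true(is.na(one$sd))
  expect_error(group_summary(numeric(0)), "no values")
})

test_that("in-situ scans are refused for IIR quantification", {
  ph <- generate_la_phantom(small_spec(seed = 54))
  seg <- extract_wall(ph$truth$blood_pool_mask, radius = 3)
  expect_error(quantify_fibrosis(ph$image, ph$truth$blood_pool_mask,
                                 seg$wall, timepoint = "in_situ"),
               "in-situ")
})
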