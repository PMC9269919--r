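test_that("NEMA-4 SNR arithmetic, scale invariance and Rayleigh recovery", {
  d <- c(30, 30, 6)
  img <- array(0, d)
  sig <- array(FALSE, d); sig[12:18, 12:18, 3] <- TRUE
  img[sig] <- 100
  rois <- lapply(list(c(1, 1), c(1, 26), c(26, 1), c(26, 26)), function(p) {
    m <- array(FALSE, d); m[p[1]:(p[1] + 4), p[2]:(p[2] + 4), 3] <- TRUE
    label_map(m)
  })
  # fill noise ROIs so each has SD exactly 1
  for (r in rois) {
    vals <- rep(c(0, 2), length.out = sum(r$mask))
    img[r$mask] <- vals / sd(vals)   # rescale to unit SD
  }
  vol <- image_volume(img)
  res <- nema4_snr(vol, label_map(sig), rois)
  expect_equal(res$snr, 66)
  # doubling intensities leaves SNR unchanged
  res2 <- nema4_snr(image_volume(img * 2), label_map(sig), rois)
  expect_equal(res2$snr, res$snr)
  expect_error(nema4_snr(vol, label_map(sig), rois[1:3]), "4 noise")

  # Rayleigh background with known sigma
  sigma <- 15; mu <- 600
  ph <- generate_la_phantom(phantom_spec(grid_shape = c(40L, 40L, 20L),
                                         chamber_semi_axes_mm = c(6, 6, 6),
                                         noise_sigma = sigma, seed = 71))
  dd <- dim(ph$image$data)
  mk <- function(is, js) {
    m <- array(FALSE, dd); m[is, js, ] <- TRUE; label_map(m, spacing = ph$image$spacing)
  }
  nrois <- list(mk(1:4, 1:4), mk(1:4, 37:40), mk(37:40, 1:4),
                mk(37:40, 37:40))
  got <- nema4_snr(ph$image, ph$truth$blood_pool_mask, nrois)
  n <- sum(nrois[[1]]$mask) * 4
  sd_th <- sigma * sqrt(2 - pi / 2)
  se <- sd_th / sqrt(2 * n)
  expected <- 0.66 * mean(ph$image$data[ph$truth$blood_pool_mask$mask]) / sd_th
  expect_lt(abs(got$snr - expected), 3 * expected * se / sd_th * 2)
})

test_that("Dice matches its definition and conventions", {
  d <- c(6, 6, 2)
  set.seed(72)
  a <- array(runif(prod(d)) > 0.5, d)
  expect_equal(dice(label_map(a), label_map(a)), 100)
  b <- array(FALSE, d)
  expect_equal(dice(label_map(a), label_map(b)), 0)
  expect_equal(dice(label_map(b), label_map(b)), 100)
  # |A|=|B|=100 overlap 50 -> 50
  big <- c(10, 10, 2)
  x <- array(FALSE, big); y <- array(FALSE, big)
  x[1:100] <- TRUE; y[51:150] <- TRUE
  expect_equal(dice(label_map(x), label_map(y)), 50)
  # symmetry
  expect_equal(dice(label_map(x), label_map(y)), dice(label_map(y), label_map(x)))
})

test_that("pairwise mean Dice enumerates unordered pairs", {
  d <- c(8, 8, 2)
  set.seed(73)
  masks <- lapply(1:3, function(i) label_map(array(runif(prod(d)) > 0.4, d)))
  got <- pairwise_mean_dice(masks)
  manual <- c(dice(masks[[1]], masks[[2]]), dice(masks[[1]], masks[[3]]),
              dice(masks[[2]], masks[[3]]))
  expect_equal(got$mean, mean(manual))
  expect_equal(got$sd, sd(manual))
  same <- pairwise_mean_dice(list(masks[[1]], masks[[1]], masks[[1]]))
  expect_equal(same$mean, 100)
  expect_equal(same$sd, 0)
  expect_error(pairwise_mean_dice(masks[1]), "at least 2")
})

test_that("boundary scores match an all-pairs distance oracle", {
  d <- c(10, 10, 6)
  a <- array(FALSE, d); a[3:7, 3:7, 2:4] <- TRUE
  b <- array(FALSE, d); b[4:8, 3:7, 2:4] <- TRUE
  tol <- 2
  got <- boundary_scores(label_map(a), label_map(b), tolerance = tol)
  ba <- which(brute_boundary(a)); bb <- which(brute_boundary(b))
  pa <- arrayInd(ba, d); pb <- arrayInd(bb, d)
  mind <- function(p, q) apply(p, 1, function(r)
    sqrt(min(colSums((t(q) - r)^2))))
  prec <- 100 * mean(mind(pa, pb) <= tol)
  rec <- 100 * mean(mind(pb, pa) <= tol)
  expect_equal(got$precision, prec)
  expect_equal(got$recall, rec)
  expect_equal(got$f1, 2 * prec * rec / (prec + rec))

  expect_equal(boundary_scores(label_map(a), label_map(a))$f1, 100)
  # candidate uniformly 1 voxel outside, tolerance 2 -> perfect
  grown <- array(FALSE, d); grown[2:8, 2:8, 2:4] <- TRUE
  expect_equal(boundary_scores(label_map(grown), label_map(a), 2)$f1, 100)
  # infinite tolerance: 100 for any two non-empty masks
  expect_equal(boundary_scores(label_map(a), label_map(b), Inf)$f1, 100)
})

test_that("relative volume error is the signed fraction", {
  d <- c(10, 10, 2)
  ref <- array(FALSE, d); ref[1:100] <- TRUE
  cand <- array(FALSE, d); cand[1:110] <- TRUE
  expect_equal(relative_volume_error(label_map(cand), label_map(ref)), 0.10)
  expect_equal(relative_volume_error(label_map(ref), label_map(ref)), 0)
  empty <- label_map(array(FALSE, d))
  expect_equal(relative_volume_error(empty, label_map(ref)), -1)
  expect_error(relative_volume_error(label_map(ref), empty), "empty")
})

test_that("ICC and R follow the reliability formulas and recover simulated components", {
  # forced arithmetic
  expect_equal(reliability_from_components(1, 1, k = 1), 0.5)
  expect_equal(reliability_from_components(1, 1, k = 2), 2 / 3)
  expect_equal(reliability_from_components(0, 5, k = 1), 1)
  expect_error(reliability_from_components(1, 0), "degenerate")

  # zero within-condition variance -> ICC 1
  m <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(icc_intra(m)$icc, 1)

  # Monte-Carlo recovery: sigma2_w = 1, sigma2_b = 4, 200 x 3
  set.seed(74)
  nc <- 200; nr <- 3
  mu <- rnorm(nc, 0, 2)
  mm <- matrix(rnorm(nc * nr, rep(mu, nr), 1), nc, nr)
  got <- icc_intra(mm)
  expect_lt(abs(got$icc - 0.8), 0.05)
  expect_lt(abs(got$sigma2_w - 1), 0.25)

  # R >= ICC for the same components; k = 1 collapses to the ICC formula
  expect_gte(reliability_from_components(1, 4, k = 2),
             reliability_from_components(1, 4, k = 1))
  arr <- array(rnorm(40 * 3 * 2, rep(rnorm(40, 0, 2), 6), 1), c(40, 3, 2))
  rres <- inter_rater_r(arr)
  expect_equal(rres$k, 2L)
  expect_equal(rres$r,
               reliability_from_components(rres$sigma2_w, rres$sigma2_b, 2))
  expect_true(rres$r > 0 && rres$r <= 1)
  expect_error(inter_rater_r(array(rnorm(40), c(20, 2, 1))), "2 operators")
})
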