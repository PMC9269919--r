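# Independent brute-force oracles used across the suite.  They are
# deliberately naive (per-pixel scans, full enumeration) and share no code
# with the implementation paths they check.

# 2D dilation by per-pixel disk test
brute_dilate_slice <- function(slice, radius) {
  d <- dim(slice)
  out <- matrix(FALSE, d[1], d[2])
  on <- which(slice, arr.ind = TRUE)
  if (nrow(on) == 0L) return(out)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    out[i, j] <- any((on[, 1] - i)^2 + (on[, 2] - j)^2 <= radius^2)
  }
  out
}

# exact two-sided signed-rank p by explicit enumeration of all 2^n signs
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
brute_mann_whitney_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(n1 + n2, n1)
  sums <- apply(sets, 2, function(ix) sum(r[ix]))
  lower <- mean(sums <= obs + 1e-9)
  upper <- mean(sums >= obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# small, fast phantom spec for pipeline tests
small_spec <- function(...) {
  phantom_spec(grid_shape = c(28L, 28L, 20L),
               chamber_semi_axes_mm = c(4.5, 4.0, 7.0),
               wall_thickness = 3L, ...)
}

# boundary voxels by definition: mask voxels with a non-mask 6-neighbour
brute_boundary <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (lin in which(mask)) {
    ijk <- arrayInd(lin, d)
    nb <- rbind(ijk + c(1, 0, 0), ijk - c(1, 0, 0), ijk + c(0, 1, 0),
                ijk - c(0, 1, 0), ijk + c(0, 0, 1), ijk - c(0, 0, 1))
    vals <- apply(nb, 1, function(p) {
      if (any(p < 1) || any(p > d)) FALSE else mask[p[1], p[2], p[3]]
    })
    out[lin] <- !all(vals)
  }
  out
}
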