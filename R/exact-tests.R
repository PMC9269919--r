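# Exact small-sample nonparametric tests.
#
# Both tests compute the full conditional null distribution of the rank
# statistic given the observed (mid)ranks: for the signed-rank test, over
# all 2^n sign assignments; for the Mann-Whitney test, over all
# choose(n1 + n2, n1) group assignments.  The distributions are built with
# a generating-function recursion, which enumerates the same assignment
# space without materializing it, so the p-values are exact also in the
# presence of ties (midranks).  Two-sided p = min(1, 2 * min(lower tail,
# upper tail)) on the discrete support.

# distribution of 2*W+ over all sign assignments; ranks2 = 2 * midranks
# (integers).  Returns probability vector over support 0..sum(ranks2).
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total - r + 1L)]
    f <- g
  }
  f / 2^length(ranks2)
}

# distribution of 2*(rank sum of group A) over all assignments of n1 labels
# to the pooled scaled ranks.  f[[k]][s+1] = number of size-k subsets with
# scaled-rank sum s.
rank_sum_null <- function(ranks2, n1) {
  total <- sum(ranks2)
  f <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (r in ranks2) {
    for (k in seq(from = n1 - 1L, to = 0L)) {   # descending: each rank used once
      row <- f[k + 1L, ]
      nz <- which(row != 0)
      if (length(nz))
        f[k + 2L, nz + r] <- f[k + 2L, nz + r] + row[nz]
    }
  }
  f[n1 + 1L, ] / choose(length(ranks2), n1)
}

two_sided_exact_p <- function(dist, stat2) {
  support <- seq_along(dist) - 1L
  lower <- sum(dist[support <= stat2])
  upper <- sum(dist[support >= stat2])
  min(1, 2 * min(lower, upper))
}

#' Exact Wilcoxon signed-rank test
#'
#' Computes the `W+` statistic (sum of ranks of positive differences,
#' using midranks for tied magnitudes, zeros dropped) and its exact
#' two-sided p-value from the full conditional distribution over all
#' `2^n` sign assignments.
#'
#' @param differences numeric vector of paired differences.
#' @return A list of class `exact_test_result`: `statistic` (W+),
#'   `p_two_sided`, `n` (nonzero differences used), `n_zeros` dropped,
#'   `method`, `ties` flag.
#' @examples
#' # 9 pairs, the two negatives smallest in magnitude: p = 10/512
#' wilcoxon_signed_rank_exact(c(-1, -2, 3:9))$p_two_sided
#' @export
wilcoxon_signed_rank_exact <- function(differences) {
  d <- as.double(differences)
  if (any(!is.finite(d))) stop("differences must be finite", call. = FALSE)
  n_zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all differences are zero: signed-rank test undefined",
         call. = FALSE)
  r <- rank(abs(d))                     # midranks for ties
  ties <- anyDuplicated(abs(d)) > 0L
  w_plus <- sum(r[d > 0])
  ranks2 <- as.integer(round(2 * r))
  dist <- signed_rank_null(ranks2)
  p <- two_sided_exact_p(dist, as.integer(round(2 * w_plus)))
  structure(list(statistic = w_plus, p_two_sided = p, n = n,
                 n_zeros = as.integer(n_zeros), method = "signed_rank",
                 ties = ties),
            class = "exact_test_result")
}

#' Exact Mann-Whitney U test
#'
#' Computes `U` for the first sample (number of (a, b) pairs with a > b,
#' ties counting one half) and its exact two-sided p-value from the full
#' conditional distribution over all `choose(n1 + n2, n1)` assignments of
#' the pooled midranks.
#'
#' @param sample_a,sample_b numeric vectors, both non-empty.
#' @return A list of class `exact_test_result`: `statistic` (U of
#'   `sample_a`), `p_two_sided`, `n1`, `n2`, `method`, `ties` flag.
#' @examples
#' # complete separation, 9 vs 3: p = 2/220
#' mann_whitney_u_exact(11:19, 1:3)$p_two_sided
#' @export
mann_whitney_u_exact <- function(sample_a, sample_b) {
  a <- as.double(sample_a)
  b <- as.double(sample_b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (any(!is.finite(c(a, b)))) stop("values must be finite", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)                     # midranks
  ties <- anyDuplicated(pooled) > 0L
  ra <- sum(r[seq_len(n1)])
  u <- ra - n1 * (n1 + 1) / 2
  ranks2 <- as.integer(round(2 * r))
  dist <- rank_sum_null(ranks2, n1)
  p <- two_sided_exact_p(dist, as.integer(round(2 * ra)))
  structure(list(statistic = u, p_two_sided = p, n1 = n1, n2 = n2,
                 method = "mann_whitney", ties = ties),
            class = "exact_test_result")
}

#' @export
print.exact_test_result <- function(x, ...) {
  cat("<exact_test_result> ", x$method, ": statistic = ", x$statistic,
      ", exact two-sided p = ", format(x$p_two_sided, digits = 4), "\n",
      sep = "")
  invisible(x)
}
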