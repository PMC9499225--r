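# Independent oracles used across the suite. These deliberately take
# different computational routes from the package code they check.

# Closed-form pooled two-sample t (dark/second group minus pale/first).
oracle_pooled_t <- function(x, y) {
  n1 <- length(y); n2 <- length(x)
  sp2 <- (sum((y - mean(y))^2) + sum((x - mean(x))^2)) / (n1 + n2 - 2)
  tt <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, df = n1 + n2 - 2, p = 2 * pt(-abs(tt), n1 + n2 - 2))
}

# Brute-force Fisher exact p for an r x c table: grid-enumerate the free
# (r-1) x (c-1) block and filter on the margins (a different algorithm
# from the package's recursive fill).
oracle_fisher_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  r <- nrow(tab); cc <- ncol(tab)
  free_rows <- seq_len(r - 1L); free_cols <- seq_len(cc - 1L)
  ranges <- list()
  for (i in free_rows) for (j in free_cols)
    ranges[[paste(i, j)]] <- 0:min(rs[i], cs[j])
  grid <- as.matrix(expand.grid(ranges))
  logp <- function(m) {
    sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
      lgamma(sum(m) + 1) - sum(lgamma(m + 1))
  }
  lp_obs <- logp(tab)
  total <- 0
  for (g in seq_len(nrow(grid))) {
    m <- matrix(0, r, cc)
    # ranges were built row-major (i outer, j inner)
    m[free_rows, free_cols] <- matrix(grid[g, ], r - 1L, cc - 1L,
                                      byrow = TRUE)
    m[free_rows, cc] <- rs[free_rows] - rowSums(m[free_rows, free_cols,
                                                  drop = FALSE])
    if (any(m[free_rows, cc] < 0)) next
    m[r, ] <- cs - colSums(m[free_rows, , drop = FALSE])
    if (any(m[r, ] < 0)) next
    lp <- logp(m)
    if (lp <= lp_obs + 1e-7) total <- total + exp(lp)
  }
  min(1, total)
}

# Exact circular-arc profile without going through the generator: k points
# spaced `step` radians on a circle of radius R, arbitrary pose.
oracle_arc_points <- function(R, step, n, rot = 0, shift = c(0, 0),
                              scale = 1) {
  theta <- (seq_len(n) - 1L) * step - (n - 1L) * step / 2
  pts <- cbind(R * sin(theta), R * cos(theta))
  rotm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2L)
  sweep(pts %*% t(rotm) * scale, 2L, -shift)
}

# 99% binomial acceptance interval for a rejection count.
binom_bounds <- function(n, alpha) {
  qbinom(c(0.005, 0.995), n, alpha) / n
}
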