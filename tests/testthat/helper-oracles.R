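# Independent oracles used across the suite.  These deliberately use
# naive per-pixel loops / direct formulas so they share no code with the
# implementation they check.

# exhaustive 8-neighborhood edge rule on one slice (matrix)
oracle_slice_edges <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(FALSE, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    if (!m[y, x]) next
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      yy <- y + dy; xx <- x + dx
      bg <- yy < 1 || yy > ny || xx < 1 || xx > nx || !m[yy, xx]
      if (bg) { out[y, x] <- TRUE }
    }
  }
  out
}

oracle_edges_3d <- function(mask) {
  out <- array(FALSE, dim(mask))
  for (z in seq_len(dim(mask)[1]))
    out[z, , ] <- oracle_slice_edges(mask[z, , , drop = TRUE])
  out
}

# brute-force between-class variance scan over all 256 thresholds
oracle_otsu <- function(v) {
  v <- as.vector(v)
  best_t <- -1; best_var <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_var + 1e-12) { best_var <- s; best_t <- t }
  }
  best_t
}

# recursive-free flood fill, 26-connectivity, returns label array
oracle_flood_fill <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx_of <- function(z, y, x) c(z, y, x)
  for (i in which(mask)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- list(arrayInd(i, d)[1, ])
    lab[i] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        q <- p + c(dz, dy, dx)
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# two-sided paired-t p-value by numerical integration of the t density
oracle_t_pvalue <- function(tstat, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-10)$value
}

# one-pass (sum, sum of squares) mean and sample SD
oracle_one_pass_sd <- function(x) {
  n <- length(x); s <- sum(x); ss <- sum(x^2)
  sqrt((ss - s^2 / n) / (n - 1))
}

# explicit two-way ANOVA table and ICC(2,1) for a subjects x raters matrix
oracle_icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  resid <- x - outer(rowMeans(x), rep(1, k)) -
    outer(rep(1, n), colMeans(x)) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# small random 8-bit phantom volume for round-trip properties
random_volume <- function() {
  d <- c(sample(1:5, 1), sample(3:8, 1), sample(3:8, 1))
  voxel_volume(array(sample(0:255, prod(d), replace = TRUE), d),
               pixel_size_mm = stats::runif(1, 0.1, 1),
               slice_spacing_mm = stats::runif(1, 0.1, 1))
}

# analytic valley of a two-Gaussian mixture on the integer bin grid
analytic_valley <- function(n1, m1, n2, m2, sd) {
  grid <- (m1 + 1):(m2 - 1)
  dens <- n1 * stats::dnorm(grid, m1, sd) + n2 * stats::dnorm(grid, m2, sd)
  grid[which.min(dens)]
}
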