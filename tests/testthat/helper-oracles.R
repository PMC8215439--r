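# Independent oracles and small fixture builders shared across tests.

# Exhaustive grid search over the penalised least-squares objective
# (no intercept) for d <= 3, coefficients on a regular grid. Uses only
# inner products, never the solver under test.
lasso_grid_oracle <- function(x, y, lambda, pf = rep(1, ncol(x)),
                              step = 0.01, lim = 2) {
  x <- as.matrix(x)
  d <- ncol(x)
  stopifnot(d <= 3)
  g <- seq(-lim, lim, by = step)
  G <- crossprod(x)
  cy <- drop(crossprod(x, y))
  yy <- sum(y^2)
  marg <- lapply(seq_len(d), function(j)
    -2 * g * cy[j] + g^2 * G[j, j] + lambda * pf[j] * abs(g))
  if (d == 1) return(min(yy + marg[[1]]))
  if (d == 2) {
    obj <- yy + outer(marg[[1]], marg[[2]], `+`) + 2 * G[1, 2] * outer(g, g)
    return(min(obj))
  }
  base2 <- outer(marg[[1]], marg[[2]], `+`) + 2 * G[1, 2] * outer(g, g)
  best <- Inf
  for (k in seq_along(g)) {
    m3 <- base2 + marg[[3]][k] +
      2 * G[1, 3] * g[k] * g +                  # adds along w1 (rows)
      rep(2 * G[2, 3] * g[k] * g, each = length(g))  # adds along w2 (cols)
    best <- min(best, min(m3))
  }
  yy + best
}

# Brute-force per-voxel recomputation of regional means (triple loop).
region_means_bruteforce <- function(voxels, labels, region_ids) {
  sums <- setNames(numeric(length(region_ids)), region_ids)
  counts <- setNames(numeric(length(region_ids)), region_ids)
  dm <- dim(voxels)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    l <- labels[i, j, k]
    if (l > 0) {
      key <- as.character(l)
      sums[key] <- sums[key] + voxels[i, j, k]
      counts[key] <- counts[key] + 1
    }
  }
  out <- sums / counts
  out[counts == 0] <- NA
  out
}

# Small cohort that keeps volume-level tests fast.
small_cohort_spec <- function(...) {
  cohort_spec(n_nc = 4, n_mci = 3, n_ad = 4, volume_shape = c(8, 8, 8),
              n_regions = 4, effect_regions = 2L,
              effect_sizes = matrix(c(0, -150, -300), 1), ...)
}

# Well-conditioned random regression instance with an exact OLS solution.
random_instance <- function(m, d, seed, coef_scale = 0.5, noise = 0.1) {
  set.seed(seed)
  x <- matrix(rnorm(m * d), m, d)
  beta <- runif(d, -coef_scale, coef_scale)
  y <- drop(x %*% beta) + rnorm(m, sd = noise)
  list(x = x, y = y, beta = beta)
}
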