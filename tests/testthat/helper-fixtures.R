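# Fixtures are built in code: small volumes with known analytic structure.

# A volume whose values follow a Gaussian edge-spread function H * Phi(x/sigma)
# along x, constant in y/z. The edge sits at world x = 0.
make_esf_volume <- function(sigma, H, step, half_extent = 8 * sigma) {
  xs <- seq(-half_extent, half_extent, by = step)
  vals <- H * stats::pnorm(xs / sigma)
  arr <- array(rep(vals, 9), dim = c(length(xs), 3, 3))
  volume3d(arr, spacing = c(step, 1, 1), origin = c(-half_extent, 0, 0))
}

esf_probe <- function(vol) {
  x0 <- vol$origin[1]
  x1 <- x0 + (dim(vol$data)[1] - 1) * vol$spacing[1]
  line_probe(c(x0, 1, 1), c(x1, 1, 1), step_mm = vol$spacing[1])
}

# Linear ramp 0 -> `height` HU over [ramp_lo, ramp_hi] mm along x,
# flat outside; dx = 0.25 mm.
make_ramp_volume <- function(ramp_lo = 2, ramp_hi = 4, height = 100,
                             extent = 10, dx = 0.25) {
  xs <- seq(0, extent, by = dx)
  vals <- pmin(pmax((xs - ramp_lo) / (ramp_hi - ramp_lo), 0), 1) * height
  arr <- array(rep(vals, 9), dim = c(length(xs), 3, 3))
  volume3d(arr, spacing = c(dx, 1, 1), origin = c(0, 0, 0))
}

# Small, fast phantom spec for unit tests.
small_spec <- function(...) {
  args <- utils::modifyList(list(matrix = 64, n_slices = 2, fov_mm = 180),
                            list(...))
  do.call(phantom_spec, args)
}

# Interface-eroded region mask: drops voxels within one voxel of a slab
# interface along x, where partial-volume rendering mixes compartments.
erode_mask_x <- function(mask, spec, matrix_n = spec$matrix) {
  dx <- spec$fov_mm / matrix_n
  xc <- -(matrix_n - 1) / 2 * dx + (seq_len(matrix_n) - 1) * dx
  breaks <- c(spec$rv_start_mm, spec$edges_mm)
  near <- vapply(xc, function(x) any(abs(x - breaks) <= dx), logical(1))
  mask & !array(near, dim = dim(mask))
}

# Exhaustive permutation p-value for the Friedman design: permutes each
# subject's values over conditions, statistic from stats::friedman.test.
friedman_perm_oracle <- function(m) {
  k <- ncol(m); n <- nrow(m)
  perms <- ctpsharp:::.permutations(k)
  obs <- suppressWarnings(unname(stats::friedman.test(m)$statistic))
  if (!is.finite(obs)) obs <- 0
  grid <- rep(1L, n); total <- 0L; ge <- 0L
  repeat {
    mp <- m
    for (i in seq_len(n)) mp[i, ] <- m[i, perms[[grid[i]]]]
    s <- suppressWarnings(unname(stats::friedman.test(mp)$statistic))
    if (!is.finite(s)) s <- 0
    total <- total + 1L
    if (s >= obs - 1e-12) ge <- ge + 1L
    j <- 1L
    while (j <= n && grid[j] == length(perms)) { grid[j] <- 1L; j <- j + 1L }
    if (j > n) break
    grid[j] <- grid[j] + 1L
  }
  ge / total
}

# Exhaustive sign-flip p-value for the paired Wilcoxon signed-rank test
# (two-sided), for small n without ties or zeros.
wilcoxon_flip_oracle <- function(x, y) {
  d <- x - y
  r <- rank(abs(d))
  n <- length(d)
  v_obs <- sum(r[d > 0])
  flips <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(flips) %*% r
  ev <- n * (n + 1) / 4
  mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-12)
}
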