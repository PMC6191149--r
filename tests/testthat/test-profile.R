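test_that("profile sampling reproduces constant, linear and stored values", {
  cvol <- volume3d(array(100, c(8, 8, 8)))
  p <- sample_profile(cvol, line_probe(c(0, 3, 3), c(6, 3, 3),
                                       step_mm = 0.5))
  expect_true(all(p$values == 100))
  expect_equal(p$positions, seq(0, 6, by = 0.5))

  # linear field HU = 10 x + 2 y - 3 z is reproduced exactly by trilinear
  dims <- c(9, 9, 9)
  arr <- array(0, dims)
  for (i in 1:9) for (j in 1:9) for (k in 1:9)
    arr[i, j, k] <- 10 * (i - 1) + 2 * (j - 1) - 3 * (k - 1)
  lvol <- volume3d(arr)
  pr <- line_probe(c(0.3, 0.2, 0.7), c(7.1, 6.3, 5.9), step_mm = 0.31)
  prof <- sample_profile(lvol, pr)
  u <- (pr$end - pr$start) / sqrt(sum((pr$end - pr$start)^2))
  expected <- sapply(prof$positions, function(s) {
    w <- pr$start + s * u
    10 * w[1] + 2 * w[2] - 3 * w[3]
  })
  expect_equal(prof$values, expected, tolerance = 1e-6)

  # probe along a voxel row hits stored values at voxel centres
  set.seed(12)
  rvol <- volume3d(array(rnorm(512), c(8, 8, 8)))
  rp <- sample_profile(rvol, line_probe(c(0, 4, 4), c(7, 4, 4),
                                        step_mm = 1))
  expect_equal(rp$values, rvol$data[, 5, 5])

  expect_error(sample_profile(cvol, line_probe(c(0, 3, 3), c(40, 3, 3),
                                               step_mm = 0.5)),
               "exits volume")
  expect_error(sample_profile(cvol, line_probe(c(0, 3, 3), c(6, 3, 3),
                                               step_mm = 2)),
               "spacing")
})

test_that("threshold crossings are analytic on ramps and Gaussian edges", {
  vol <- make_ramp_volume()  # 0 -> 100 over [2, 4] mm
  prof <- sample_profile(vol, line_probe(c(0, 1, 1), c(10, 1, 1),
                                         step_mm = 0.05))
  expect_equal(locate_crossing(prof$positions, prof$values, 0.25), 2.5,
               tolerance = 1e-9)
  expect_equal(locate_crossing(prof$positions, prof$values, 0.75), 3.5,
               tolerance = 1e-9)

  # Gaussian ESF: compare against dense numeric root finding on the
  # closed form H * pnorm(x / sigma)
  sigma <- 1
  vol2 <- make_esf_volume(sigma, 200, step = 0.05)
  prof2 <- sample_profile(vol2, esf_probe(vol2))
  for (q in c(0.25, 0.75)) {
    root <- uniroot(function(x) stats::pnorm(x / sigma) - q,
                    c(-6, 6), tol = 1e-12)$root
    got <- locate_crossing(prof2$positions, prof2$values, q)
    expect_equal(got, root - vol2$origin[1], tolerance = 1e-3)
  }
})

test_that("sharpness of ramp and Gaussian edges matches analytic values", {
  vol <- make_ramp_volume()
  prof <- sample_profile(vol, line_probe(c(0, 1, 1), c(10, 1, 1),
                                         step_mm = 0.05))
  res <- compute_sharpness(prof, edge_section(1, 0, 10))
  expect_equal(res$d_mm, 1, tolerance = 1e-9)
  expect_equal(res$m_hu_per_mm, 50, tolerance = 1e-9)
  expect_equal(res$m_hu_per_mm, 0.5 * res$range_hu / res$d_mm)

  # 25-75% width of a Gaussian ESF is 2 * qnorm(0.75) * sigma = 1.3490 sigma
  for (sigma in c(0.5, 2)) {
    v <- make_esf_volume(sigma, 200, step = sigma / 20)
    pr <- sample_profile(v, esf_probe(v))
    r <- compute_sharpness(pr, edge_section(1, 2 * sigma, 14 * sigma))
    expect_equal(r$d_mm, 2 * qnorm(0.75) * sigma, tolerance = 0.02)
    # internal identity m = 0.5 range / d, and range recovers H closely
    expect_equal(r$m_hu_per_mm, 0.5 * r$range_hu / r$d_mm, tolerance = 1e-9)
    expect_equal(r$m_hu_per_mm, 0.5 * 200 / r$d_mm, tolerance = 0.02)
  }
})

test_that("falling edges give identical results to their mirrored rising edge", {
  v <- make_esf_volume(1, 150, step = 0.05)
  vf <- volume3d(v$data[dim(v$data)[1]:1, , , drop = FALSE], v$spacing,
                 v$origin)
  pr <- sample_profile(v, esf_probe(v))
  pf <- sample_profile(vf, esf_probe(vf))
  rr <- compute_sharpness(pr, edge_section(1, 2, 14))
  rf <- compute_sharpness(pf, edge_section(1, 2, 14))
  expect_equal(rf$d_mm, rr$d_mm, tolerance = 1e-9)
  expect_equal(rf$m_hu_per_mm, rr$m_hu_per_mm, tolerance = 1e-9)
})

test_that("d is scale/offset invariant and m scales with intensity", {
  v <- make_esf_volume(0.8, 120, step = 0.05)
  pr <- sample_profile(v, esf_probe(v))
  base <- compute_sharpness(pr, edge_section(1, 2, 11))
  for (c_mult in c(0.5, 3)) {
    v2 <- volume3d(v$data * c_mult + 40, v$spacing, v$origin)
    p2 <- sample_profile(v2, esf_probe(v2))
    r2 <- compute_sharpness(p2, edge_section(1, 2, 11))
    expect_equal(r2$d_mm, base$d_mm, tolerance = 1e-9)
    expect_equal(r2$m_hu_per_mm, base$m_hu_per_mm * c_mult,
                 tolerance = 1e-9)
  }
})

test_that("d is stable under step refinement and monotone in blur width", {
  sigmas <- c(0.6, 0.8, 1.1, 1.5, 2.0)
  ds <- sapply(sigmas, function(s) {
    v <- make_esf_volume(s, 200, step = 0.05)
    pr <- sample_profile(v, esf_probe(v))
    compute_sharpness(pr, edge_section(1, 2 * s, 14 * s))$d_mm
  })
  expect_true(all(diff(ds) > 0))  # monotone degradation with blur

  v <- make_esf_volume(1, 200, step = 0.05)
  p_coarse <- sample_profile(v, line_probe(c(-8, 1, 1), c(8, 1, 1),
                                           step_mm = 0.05))
  p_fine <- sample_profile(v, line_probe(c(-8, 1, 1), c(8, 1, 1),
                                         step_mm = 0.025))
  d1 <- compute_sharpness(p_coarse, edge_section(1, 2, 14))$d_mm
  d2 <- compute_sharpness(p_fine, edge_section(1, 2, 14))$d_mm
  expect_lt(abs(d1 - d2), 0.05)  # halving the step moves d by < step
})

test_that("averaging jittered edges widens the expected profile", {
  # Monte-Carlo version of the motion-blur mechanism: N frames with the
  # edge displaced by iid uniform jitter, averaged, vs the static edge.
  sigma <- 0.8; H <- 250; step <- 0.1
  xs <- seq(-6, 6, by = step)
  measure_d <- function(vals) {
    arr <- array(rep(vals, 9), dim = c(length(xs), 3, 3))
    v <- volume3d(arr, spacing = c(step, 1, 1), origin = c(-6, 0, 0))
    pr <- sample_profile(v, line_probe(c(-6, 1, 1), c(6, 1, 1),
                                       step_mm = step))
    compute_sharpness(pr, edge_section(1, 2, 10))$d_mm
  }
  d_static <- measure_d(H * pnorm(xs / sigma))
  set.seed(77)
  reps <- 60
  for (N in c(2, 4)) {
    d_avg <- replicate(reps, {
      shifts <- runif(N, -0.5, 0.5)
      measure_d(rowMeans(sapply(shifts, function(s)
        H * pnorm((xs - s) / sigma))))
    })
    excess <- mean(d_avg) - d_static
    # strictly wider in expectation, beyond the Monte-Carlo uncertainty
    expect_gt(excess, 2 * sd(d_avg) / sqrt(reps))
  }
})

test_that("degenerate sections are reported as missing with a reason", {
  flat <- volume3d(array(50, c(20, 4, 4)))
  probe <- line_probe(c(0, 2, 2), c(18, 2, 2), step_mm = 0.5)
  secs <- lapply(1:4, function(i) edge_section(i, (i - 1) * 4, i * 4))
  out <- measure_edges(flat, probe, secs)
  expect_equal(nrow(out), 4L)
  expect_true(all(!out$ok))
  expect_true(all(grepl("flat", out$reason)))
  prof <- sample_profile(flat, probe)
  expect_error(compute_sharpness(prof, secs[[1]]), "flat")
})

test_that("envelope fallback orders crossings on non-monotone sections", {
  # spike-shaped artefact before the true edge: 75% crossing on the raw
  # profile would precede a 25% crossing found forward from the low side
  xs <- seq(0, 10, by = 0.1)
  vals <- 100 * pnorm((xs - 6) / 0.4)
  vals[11:13] <- c(90, 95, 90)  # isolated spike at ~1.1 mm
  arr <- array(rep(vals, 9), dim = c(length(xs), 3, 3))
  v <- volume3d(arr, spacing = c(0.1, 1, 1), origin = c(0, 0, 0))
  pr <- sample_profile(v, line_probe(c(0, 1, 1), c(10, 1, 1), step_mm = 0.1))
  r <- compute_sharpness(pr, edge_section(1, 0, 10))
  expect_gt(r$x75_mm, r$x25_mm)
  expect_gt(r$d_mm, 0)
})

test_that("measurement tables enforce key uniqueness and determinism", {
  sp <- small_spec(n_frames = 16, seed = 6)
  cohort <- generate_cohort(2, sp, seed = 6)
  pr <- cohort_probes(cohort)
  avg <- build_averaged_set(cohort, levels = 1)
  t1 <- measure_cohort(avg, pr$probes, pr$sections)
  t2 <- measure_cohort(avg, pr$probes, pr$sections)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(nrow(t1), 2 * 1 * 4)
  expect_error(bind_measurements(t1, t1), "duplicate")
})
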