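test_that("gamma-variate enhancement matches its closed form", {
  tac <- tac_params(300, onset_s = 5, time_to_peak_s = 6, shape = 3)
  expect_equal(enhancement(tac, 5), 0)            # onset
  expect_equal(enhancement(tac, 3), 0)            # before onset
  expect_equal(enhancement(tac, 11), 300)         # peak equals amplitude
  # direct evaluation of A * tau^a * exp(a(1 - tau)) at tau = 2
  expect_equal(enhancement(tac, 17), 300 * 2^3 * exp(-3), tolerance = 1e-12)
  expect_equal(enhancement(tac, c(5, 11)), c(0, 300))
})

test_that("noiseless blur-free phantom is exact away from interfaces", {
  sp <- small_spec(psf_sigma_mm = 0, noise_sigma_hu = 0, motion_amp_mm = 0,
                   n_frames = 6, seed = 1)
  ph <- generate_phantom(sp)
  for (reg in c("lv_blood", "septal_myo", "epicardial")) {
    mask <- erode_mask_x(ph$masks$masks[[reg]], sp)
    for (fi in c(1L, 4L, 6L)) {
      expected <- sp$region_hu[[reg]] +
        enhancement(sp$tacs[[reg]], ph$volume$frame_times[fi])
      vals <- ph$volume$frames[[fi]][mask]
      expect_equal(max(abs(vals - expected)), 0, tolerance = 1e-10)
    }
  }
})

test_that("phantom generation is deterministic under a fixed seed", {
  sp <- small_spec(n_frames = 3, motion_amp_mm = 0.5, seed = 99)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$frames, b$volume$frames)
})

test_that("fbp-like additive noise has the configured standard deviation", {
  # static single frame, >= 1e5 voxels
  sp <- small_spec(n_slices = 32, n_frames = 1, noise_sigma_hu = 25,
                   seed = 5)
  sp0 <- sp; sp0$noise_sigma_hu <- 0
  noisy <- generate_phantom(sp)$volume$frames[[1]]
  clean <- generate_phantom(sp0)$volume$frames[[1]]
  expect_gte(length(noisy), 1e5)
  expect_equal(sd(noisy - clean), 25, tolerance = 0.02)
})

test_that("ir-like surrogate trades noise for sharpness against fbp-like", {
  sp_f <- small_spec(n_slices = 8, n_frames = 1, seed = 8)
  sp_i <- sp_f; sp_i$recon <- "ir_like"
  sp_f0 <- sp_f; sp_f0$noise_sigma_hu <- 0
  sp_i0 <- sp_i; sp_i0$noise_sigma_hu <- 0
  f <- generate_phantom(sp_f)$volume$frames[[1]]
  i <- generate_phantom(sp_i)$volume$frames[[1]]
  f0 <- generate_phantom(sp_f0)
  i0 <- generate_phantom(sp_i0)
  # lower residual noise for the iterative surrogate
  expect_lt(sd(i - i0$volume$frames[[1]]), sd(f - f0$volume$frames[[1]]))
  # wider edges (larger d) on the same noiseless geometry
  ef <- measure_edges(get_frame(f0$volume, 1), f0$masks$probe,
                      f0$masks$sections)
  ei <- measure_edges(get_frame(i0$volume, 1), i0$masks$probe,
                      i0$masks$sections)
  expect_true(all(ei$d_mm > ef$d_mm))
  expect_true(all(ei$m_hu_per_mm < ef$m_hu_per_mm))
})

test_that("region masks are disjoint and cover the probe span", {
  ph <- generate_phantom(small_spec(n_frames = 1, seed = 3))
  total <- Reduce(`+`, lapply(ph$masks$masks, function(m) m * 1L))
  expect_true(all(total == 1L))  # pairwise disjoint and covering
  expect_length(ph$masks$sections, 4L)
  spans <- sapply(ph$masks$sections, function(s) c(s$lo_mm, s$hi_mm))
  expect_true(all(diff(as.vector(spans)) >= 0))  # ordered, disjoint
})

test_that("cohort generation is reproducible and respects variability", {
  sp <- small_spec(n_frames = 2)
  s1 <- cohort_specs(4, sp, seed = 7)
  s2 <- cohort_specs(4, sp, seed = 7)
  expect_identical(s1, s2)
  expect_named(s1, c("S01", "S02", "S03", "S04"))
  # zero variability: subjects differ only in their noise seed
  s0 <- cohort_specs(3, sp, variability = list(amplitude = 0, timing = 0,
                                               noise = 0, position_mm = 0),
                     seed = 7)
  strip_seed <- function(s) { s$seed <- NULL; s }
  expect_identical(strip_seed(s0[[1]]), strip_seed(s0[[2]]))
  expect_identical(strip_seed(s0[[1]]), strip_seed(s0[[3]]))
  expect_false(identical(s0[[1]]$seed, s0[[2]]$seed))
  # non-zero variability perturbs TACs and position
  expect_false(identical(s1[[1]]$tacs, s1[[2]]$tacs))
  expect_false(identical(s1[[1]]$edges_mm, s1[[2]]$edges_mm))
})
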