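#' Gamma-variate time-attenuation curve parameters
#'
#' First-pass contrast enhancement in a compartment is modelled as a
#' gamma-variate curve, the standard empirical form for indicator-dilution
#' kinetics: zero before the onset `t0`, rising to `amplitude_hu` exactly at
#' `t0 + time_to_peak_s`, then washing out at a rate controlled by `shape`.
#'
#' @param amplitude_hu peak enhancement above baseline, HU (>= 0).
#' @param onset_s bolus arrival time t0, s.
#' @param time_to_peak_s time from onset to peak, s (> 0).
#' @param shape gamma-variate shape alpha (> 0); larger values give a
#'   narrower, faster-washing-out bolus.
#' @return an object of class `tac_params`.
#' @export
tac_params <- function(amplitude_hu, onset_s = 0, time_to_peak_s = 5,
                       shape = 3) {
  stopifnot(amplitude_hu >= 0, time_to_peak_s > 0, shape > 0)
  structure(list(amplitude_hu = amplitude_hu, onset_s = onset_s,
                 time_to_peak_s = time_to_peak_s, shape = shape),
            class = "tac_params")
}

#' Evaluate a gamma-variate enhancement curve
#'
#' `A * tau^alpha * exp(alpha * (1 - tau))` with `tau = (t - t0) / tp`,
#' which equals 0 at the onset and peaks at exactly `A` when `t = t0 + tp`.
#'
#' @param tac a [tac_params()].
#' @param t time(s) in seconds; vectorised.
#' @return HU enhancement above baseline at each `t`.
#' @export
enhancement <- function(tac, t) {
  stopifnot(inherits(tac, "tac_params"), all(is.finite(t)))
  tau <- (t - tac$onset_s) / tac$time_to_peak_s
  out <- numeric(length(t))
  pos <- tau > 0
  a <- tac$shape
  out[pos] <- tac$amplitude_hu * tau[pos]^a * exp(a * (1 - tau[pos]))
  out
}

#' Parameterisation of the 4D cardiac phantom
#'
#' Describes a 4-chamber-view cardiac cross-section as a stack of tissue
#' slabs crossed by the canonical measuring line: RV blood pool, septal
#' myocardium, LV blood pool, lateral myocardial wall, epicardial (fatty)
#' tissue. The four slab interfaces are the four representative myocardial
#' edges probed downstream. Each compartment has a baseline HU and a
#' gamma-variate enhancement curve; frames are degraded by an acquisition
#' point-spread blur, optional beat-to-beat rigid motion jitter, and one of
#' two reconstruction surrogates: `fbp_like` (full additive Gaussian noise)
#' or `ir_like` (reduced noise followed by extra smoothing), reproducing the
#' noise/sharpness trade-off between analytic and iterative reconstruction.
#'
#' @param matrix in-plane voxel count (square matrix), >= 32.
#' @param fov_mm in-plane field of view, mm.
#' @param n_slices number of axial slices.
#' @param dz_mm slice spacing, mm.
#' @param n_frames number of time frames (one per heart beat).
#' @param dt_s frame interval, s (nominal 60 bpm -> 1 s).
#' @param region_hu named baseline HU for `rv_blood`, `septal_myo`,
#'   `lv_blood`, `lateral_myo`, `epicardial`.
#' @param tacs named list of [tac_params()] for the same compartments.
#' @param edges_mm world x positions (mm) of the four myocardial edges:
#'   RV/septum, septum/LV, LV/lateral wall, lateral wall/epicardium.
#' @param rv_start_mm world x where RV blood begins (epicardium lies before).
#' @param section_halfwidth_mm half-width of the edge sections centred on
#'   each edge, mm.
#' @param psf_sigma_mm Gaussian acquisition blur (in-plane), mm. The
#'   default (`NULL`) is `max(0.4, 0.6 * fov_mm / matrix)`: 0.4 mm at the
#'   native 512 matrix, and never narrower than 0.6 pixel at reduced
#'   matrices so that the rendered edge profiles stay adequately sampled
#'   (a blur much narrower than the pixel makes measured edge widths
#'   depend on where the edge sits relative to the voxel grid).
#' @param noise_sigma_hu additive Gaussian noise level, HU.
#' @param motion_amp_mm per-frame rigid in-plane displacement drawn
#'   uniformly from [-amp, +amp] per axis, mm.
#' @param recon `"fbp_like"` or `"ir_like"`.
#' @param ir_extra_sigma_mm additional in-plane smoothing for `ir_like`, mm.
#' @param ir_noise_factor noise multiplier for `ir_like`, in (0, 1].
#' @param seed RNG seed for noise and motion; `NULL` uses the session RNG.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix = 512L, fov_mm = 180, n_slices = 16L,
                         dz_mm = 0.5, n_frames = 20L, dt_s = 1.0,
                         region_hu = c(rv_blood = 40, septal_myo = 50,
                                       lv_blood = 40, lateral_myo = 50,
                                       epicardial = -80),
                         tacs = default_tacs(),
                         edges_mm = c(-22, -10, 25, 37),
                         rv_start_mm = -40,
                         section_halfwidth_mm = 3,
                         psf_sigma_mm = NULL, noise_sigma_hu = 25,
                         motion_amp_mm = 0, recon = c("fbp_like", "ir_like"),
                         ir_extra_sigma_mm = 0.6, ir_noise_factor = 0.4,
                         seed = NULL) {
  recon <- match.arg(recon)
  if (is.null(psf_sigma_mm))
    psf_sigma_mm <- max(0.4, 0.6 * fov_mm / matrix)
  regions <- c("rv_blood", "septal_myo", "lv_blood", "lateral_myo",
               "epicardial")
  stopifnot(matrix >= 32, fov_mm > 0, n_slices >= 1, dz_mm > 0,
            n_frames >= 1, dt_s > 0, psf_sigma_mm >= 0, noise_sigma_hu >= 0,
            motion_amp_mm >= 0, ir_extra_sigma_mm >= 0,
            ir_noise_factor > 0, ir_noise_factor <= 1,
            length(edges_mm) == 4, !is.unsorted(edges_mm, strictly = TRUE),
            rv_start_mm < edges_mm[1], section_halfwidth_mm > 0)
  if (!all(regions %in% names(region_hu)))
    stop("region_hu must name all of: ", paste(regions, collapse = ", "))
  if (!all(regions %in% names(tacs)))
    stop("tacs must name all of: ", paste(regions, collapse = ", "))
  structure(
    list(matrix = as.integer(matrix), fov_mm = fov_mm,
         n_slices = as.integer(n_slices), dz_mm = dz_mm,
         n_frames = as.integer(n_frames), dt_s = dt_s,
         region_hu = region_hu[regions], tacs = tacs[regions],
         edges_mm = edges_mm, rv_start_mm = rv_start_mm,
         section_halfwidth_mm = section_halfwidth_mm,
         psf_sigma_mm = psf_sigma_mm, noise_sigma_hu = noise_sigma_hu,
         motion_amp_mm = motion_amp_mm, recon = recon,
         ir_extra_sigma_mm = ir_extra_sigma_mm,
         ir_noise_factor = ir_noise_factor, seed = seed),
    class = "phantom_spec"
  )
}

#' Default compartment enhancement curves
#'
#' Emulates a stress first-pass study: a sharp right-ventricular bolus that
#' has washed out by the LV peak, a strong left-ventricular enhancement, and
#' a slower hyperaemic myocardial curve; epicardial tissue does not enhance.
#'
#' @return named list of [tac_params()].
#' @export
default_tacs <- function() {
  myo <- tac_params(amplitude_hu = 120, onset_s = 8, time_to_peak_s = 8,
                    shape = 2)
  list(
    rv_blood    = tac_params(amplitude_hu = 350, onset_s = 2,
                             time_to_peak_s = 4, shape = 6),
    lv_blood    = tac_params(amplitude_hu = 400, onset_s = 8,
                             time_to_peak_s = 5, shape = 3),
    septal_myo  = myo,
    lateral_myo = myo,
    epicardial  = tac_params(amplitude_hu = 0, onset_s = 0,
                             time_to_peak_s = 1, shape = 1)
  )
}

# Exact voxel-averaged sampling of a 1D piecewise-constant field.
# breaks: slab interfaces (sorted); vals: length(breaks)+1 segment values.
# Returns the mean of the step function over [x - dx/2, x + dx/2] so that
# sub-voxel interface positions produce the correct partial-volume fractions.
.step_boxcar_mean <- function(x, dx, breaks, vals) {
  stopifnot(length(vals) == length(breaks) + 1L)
  cum <- c(0, cumsum(diff(breaks) * vals[seq(2L, length(breaks))]))
  integ <- function(z) {
    j <- findInterval(z, breaks)
    ifelse(j == 0L, (z - breaks[1L]) * vals[1L],
           cum[pmax(j, 1L)] + (z - breaks[pmax(j, 1L)]) * vals[j + 1L])
  }
  (integ(x + dx / 2) - integ(x - dx / 2)) / dx
}

# In-plane Gaussian blur of a matrix, sigma in pixels; replicate boundary.
.blur2d <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  size <- 2L * as.integer(ceiling(4 * sigma_px)) + 1L
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma_px)
  as.matrix(EBImage::filter2(mat, brush, boundary = "replicate"))
}

# In-plane blur applied slice by slice to a 3D array.
.blur_inplane <- function(arr, sigma_px) {
  if (sigma_px <= 0) return(arr)
  for (k in seq_len(dim(arr)[3L]))
    arr[, , k] <- .blur2d(arr[, , k], sigma_px)
  arr
}

.phantom_geometry <- function(spec) {
  nx <- spec$matrix
  dx <- spec$fov_mm / nx
  dz <- spec$dz_mm
  origin <- c(-(nx - 1) / 2 * dx, -(nx - 1) / 2 * dx,
              -(spec$n_slices - 1) / 2 * dz)
  list(nx = nx, ny = nx, nz = spec$n_slices, dx = dx,
       spacing = c(dx, dx, dz), origin = origin,
       xc = origin[1L] + (seq_len(nx) - 1) * dx,
       breaks = c(spec$rv_start_mm, spec$edges_mm))
}

#' Generate a 4D phantom series
#'
#' Renders each frame as a piecewise-constant compartment image (baseline +
#' gamma-variate enhancement at the frame time) with exact partial-volume
#' sampling at slab interfaces, applies an optional per-frame rigid in-plane
#' displacement of the heart (uniform in [-motion_amp, +motion_amp] per
#' axis; only the component along the slab normal displaces the interfaces),
#' blurs by the acquisition PSF, then applies the reconstruction surrogate:
#' `fbp_like` adds i.i.d. Gaussian noise of `noise_sigma_hu`; `ir_like` adds
#' noise of `noise_sigma_hu * ir_noise_factor` and then smooths in-plane by
#' `ir_extra_sigma_mm`. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `volume` (a [volume4d()]) and `masks` (a
#'   `region_masks` object: per-compartment logical grids for the motion-free
#'   reference geometry, the four edge positions in mm, and the canonical
#'   [line_probe()] with its four [edge_section()]s).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  run <- function() .generate_phantom_impl(spec)
  if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
}

.generate_phantom_impl <- function(spec) {
  g <- .phantom_geometry(spec)
  regions <- names(spec$region_hu)
  psf_px <- spec$psf_sigma_mm / g$dx
  ir_px <- spec$ir_extra_sigma_mm / g$dx
  times <- (seq_len(spec$n_frames) - 1) * spec$dt_s

  frames <- vector("list", spec$n_frames)
  for (t_i in seq_len(spec$n_frames)) {
    vals_t <- vapply(regions, function(r) {
      spec$region_hu[[r]] + enhancement(spec$tacs[[r]], times[t_i])
    }, numeric(1))
    seg_vals <- c(vals_t[["epicardial"]], vals_t[["rv_blood"]],
                  vals_t[["septal_myo"]], vals_t[["lv_blood"]],
                  vals_t[["lateral_myo"]], vals_t[["epicardial"]])
    shift <- if (spec$motion_amp_mm > 0)
      stats::runif(2, -spec$motion_amp_mm, spec$motion_amp_mm) else c(0, 0)
    prof <- .step_boxcar_mean(g$xc, g$dx, g$breaks + shift[1L], seg_vals)
    plane <- .blur2d(matrix(prof, g$nx, g$ny), psf_px)
    sig <- array(plane, dim = c(g$nx, g$ny, g$nz))
    if (spec$recon == "fbp_like") {
      if (spec$noise_sigma_hu > 0)
        sig <- sig + array(stats::rnorm(length(sig), 0, spec$noise_sigma_hu),
                           dim = dim(sig))
    } else {
      s <- spec$noise_sigma_hu * spec$ir_noise_factor
      if (s > 0)
        sig <- sig + array(stats::rnorm(length(sig), 0, s), dim = dim(sig))
      sig <- .blur_inplane(sig, ir_px)
    }
    frames[[t_i]] <- sig
  }

  vol <- volume4d(frames, g$spacing, g$origin, times)
  list(volume = vol, masks = .region_masks(spec, g))
}

# Motion-free reference geometry: compartment label masks, edge positions
# and the canonical probe with its four edge sections.
.region_masks <- function(spec, g = .phantom_geometry(spec)) {
  regions <- names(spec$region_hu)
  lab1d <- findInterval(g$xc, g$breaks)  # 0 = epi, 1 = rv, ..., 5 = epi
  lab1d[lab1d == 5L] <- 0L
  region_of <- c("epicardial", "rv_blood", "septal_myo", "lv_blood",
                 "lateral_myo")
  masks <- lapply(seq_along(region_of), function(i) {
    row <- lab1d == (i - 1L)
    array(matrix(row, g$nx, g$ny), dim = c(g$nx, g$ny, g$nz))
  })
  names(masks) <- region_of
  hw <- spec$section_halfwidth_mm
  z_mid <- 0
  start <- c(spec$edges_mm[1L] - 2 * hw - 4, 0, z_mid)
  end <- c(spec$edges_mm[4L] + 2 * hw + 2, 0, z_mid)
  probe <- line_probe(start, end)
  sections <- lapply(1:4, function(e) {
    centre <- spec$edges_mm[e] - start[1L]  # arc length from probe start
    edge_section(e, centre - hw, centre + hw)
  })
  structure(list(masks = masks[regions], edges_mm = spec$edges_mm,
                 probe = probe, sections = sections),
            class = "region_masks")
}

#' Per-subject phantom specifications for a synthetic cohort
#'
#' Jitters the base specification per subject: each compartment's TAC
#' amplitude, onset and time-to-peak, and the noise level, are scaled by
#' independent uniform factors in `1 +/- fraction`, and the heart (the slab
#' geometry) is shifted along the probe axis by a uniform offset in
#' `+/- position_mm` — patients' hearts do not sit at identical positions
#' relative to the reconstruction grid, and a cohort sharing one exact
#' grid alignment would give all subjects the same discretisation phase.
#' Every subject receives its own derived seed, so the cohort is
#' reproducible from `seed`.
#'
#' @param n_subjects number of subjects, >= 1.
#' @param base_spec a [phantom_spec()].
#' @param variability named list of jitter fractions `amplitude`, `timing`,
#'   `noise` (defaults 0.1 each) and the absolute offset `position_mm`
#'   (default 2 mm).
#' @param seed integer seed for the cohort.
#' @return list of `phantom_spec`, named `S01`, `S02`, ...
#' @export
cohort_specs <- function(n_subjects, base_spec = phantom_spec(),
                         variability = list(amplitude = 0.1, timing = 0.1,
                                            noise = 0.1, position_mm = 2),
                         seed = 1L) {
  stopifnot(n_subjects >= 1)
  v <- utils::modifyList(list(amplitude = 0.1, timing = 0.1, noise = 0.1,
                              position_mm = 2),
                         as.list(variability))
  withr::with_seed(seed, {
    subj_seeds <- sample.int(.Machine$integer.max, n_subjects)
    specs <- lapply(seq_len(n_subjects), function(i) {
      s <- base_spec
      s$tacs <- lapply(s$tacs, function(tc) {
        amp <- tc$amplitude_hu * stats::runif(1, 1 - v$amplitude,
                                              1 + v$amplitude)
        tim <- stats::runif(1, 1 - v$timing, 1 + v$timing)
        tac_params(amp, tc$onset_s * tim, tc$time_to_peak_s * tim, tc$shape)
      })
      s$noise_sigma_hu <- s$noise_sigma_hu *
        stats::runif(1, 1 - v$noise, 1 + v$noise)
      if (v$position_mm > 0) {
        off <- stats::runif(1, -v$position_mm, v$position_mm)
        s$edges_mm <- s$edges_mm + off
        s$rv_start_mm <- s$rv_start_mm + off
      }
      s$seed <- subj_seeds[i]
      s
    })
    names(specs) <- sprintf("S%02d", seq_len(n_subjects))
    specs
  })
}

#' Per-subject probes and shared sections of a cohort
#'
#' Each subject's canonical measuring line follows its own heart position;
#' the edge sections are defined as arc-length spans from the probe start
#' and are therefore identical across subjects, reconstruction variants and
#' averaging levels.
#'
#' @param cohort output of [generate_cohort()] (or any named list whose
#'   elements carry a `masks` entry).
#' @return list with `probes` (named list of [line_probe()]) and
#'   `sections` (list of [edge_section()]s).
#' @export
cohort_probes <- function(cohort) {
  probes <- lapply(cohort, function(s) s$masks$probe)
  list(probes = probes, sections = cohort[[1L]]$masks$sections)
}

#' Generate a synthetic cohort of phantom series
#'
#' Convenience wrapper: [cohort_specs()] followed by [generate_phantom()]
#' for each subject.
#'
#' @inheritParams cohort_specs
#' @return named list of `list(volume, masks, spec)` per subject.
#' @export
generate_cohort <- function(n_subjects, base_spec = phantom_spec(),
                            variability = list(amplitude = 0.1,
                                               timing = 0.1, noise = 0.1),
                            seed = 1L) {
  specs <- cohort_specs(n_subjects, base_spec, variability, seed)
  lapply(specs, function(s) c(generate_phantom(s), list(spec = s)))
}
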