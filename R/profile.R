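#' Line probe through a volume
#'
#' A straight measuring line in world coordinates (mm), placed across the
#' heart in the 4-chamber view so that it crosses the RV blood pool, septal
#' myocardium, LV blood pool, lateral wall and epicardial tissue. The same
#' probe geometry is reused across reconstruction variants and averaging
#' levels of a subject so that all measurements share one localisation.
#'
#' @param start,end numeric length-3 world points (mm); must differ.
#' @param step_mm sampling interval along the line, mm; `NULL` defers to
#'   `min(voxel spacing) / 4` at sampling time. Must not exceed the smallest
#'   voxel spacing of the sampled volume.
#' @return an object of class `line_probe`.
#' @export
line_probe <- function(start, end, step_mm = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == 3, length(end) == 3,
            all(is.finite(start)), all(is.finite(end)))
  if (sqrt(sum((end - start)^2)) <= 0) stop("probe start and end coincide")
  if (!is.null(step_mm) && step_mm <= 0) stop("step_mm must be positive")
  structure(list(start = start, end = end, step_mm = step_mm),
            class = "line_probe")
}

#' Edge section of a profile
#'
#' A sub-interval `[lo_mm, hi_mm)` of the probe arc length containing one
#' myocardial edge. Labels follow the four representative localisations:
#' 1 RV/septum, 2 septum/LV, 3 LV/lateral wall, 4 lateral wall/epicardium.
#'
#' @param label edge label (1-4, or any identifier).
#' @param lo_mm,hi_mm section bounds as arc length from the probe start, mm.
#' @param polarity `"auto"` (infer from the data), `"rising"` (low HU at
#'   `lo_mm`) or `"falling"`.
#' @return an object of class `edge_section`.
#' @export
edge_section <- function(label, lo_mm, hi_mm,
                         polarity = c("auto", "rising", "falling")) {
  polarity <- match.arg(polarity)
  stopifnot(is.finite(lo_mm), is.finite(hi_mm), hi_mm > lo_mm)
  structure(list(label = label, lo_mm = lo_mm, hi_mm = hi_mm,
                 polarity = polarity),
            class = "edge_section")
}

# Vectorised trilinear interpolation at continuous 1-based voxel coordinates.
# No installed package offers gridded 3D interpolation, so this is done by
# hand; trilinear interpolation reproduces linear fields exactly.
.trilinear <- function(arr, ijk) {
  d <- dim(arr)
  if (any(ijk < 1 - 1e-9) || any(sweep(ijk, 2L, d + 1e-9, ">")))
    stop("sample point outside volume bounds")
  ijk <- pmin(pmax(ijk, 1), matrix(d, nrow(ijk), 3, byrow = TRUE))
  i0 <- pmax(pmin(floor(ijk), matrix(d - 1L, nrow(ijk), 3, byrow = TRUE)), 1)
  f <- ijk - i0
  out <- numeric(nrow(ijk))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    if (all(w == 0)) next
    out <- out + w * arr[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  out
}

#' Sample an intensity profile along a probe
#'
#' HU values are obtained by trilinear interpolation at uniformly spaced
#' positions from the probe start (inclusive) towards its end; no sample is
#' placed beyond the end. Positions are arc length in mm from the start.
#'
#' @param vol a [volume3d()] (or a [volume4d()] frame via [get_frame()]).
#' @param probe a [line_probe()].
#' @return an object of class `ctp_profile`: list with `positions` (mm),
#'   `values` (HU), `step_mm` and the `probe`.
#' @export
sample_profile <- function(vol, probe) {
  stopifnot(inherits(vol, "volume3d"), inherits(probe, "line_probe"))
  step <- probe$step_mm
  if (is.null(step)) step <- min(vol$spacing) / 4
  if (step > min(vol$spacing) + 1e-9)
    stop("step_mm exceeds the smallest voxel spacing")
  dvec <- probe$end - probe$start
  len <- sqrt(sum(dvec^2))
  if (step > len) stop("step_mm exceeds the probe length")
  u <- dvec / len
  positions <- seq(0, len + 1e-9, by = step)
  positions <- positions[positions <= len + 1e-9]
  pts <- matrix(probe$start, length(positions), 3, byrow = TRUE) +
    outer(positions, u)
  ijk <- world_to_voxel(vol, pts)
  vals <- tryCatch(.trilinear(vol$data, ijk),
                   error = function(e) stop("probe exits volume: ",
                                            conditionMessage(e)))
  structure(list(positions = positions, values = vals, step_mm = step,
                 probe = probe),
            class = "ctp_profile")
}

# Orient a section so the low-intensity side comes first. Polarity "auto"
# compares robust means of the two outer thirds. Returns positions as arc
# length from the low-intensity end plus the (possibly reversed) values.
.orient_section <- function(positions, values, polarity = "auto") {
  n <- length(values)
  if (polarity == "auto") {
    k <- max(1L, n %/% 3L)
    polarity <- if (mean(values[seq_len(k)]) <=
                    mean(values[seq.int(n - k + 1L, n)])) "rising"
                else "falling"
  }
  if (polarity == "rising") {
    list(s = positions - positions[1L], v = values, flipped = FALSE)
  } else {
    list(s = positions[n] - rev(positions), v = rev(values), flipped = TRUE)
  }
}

# Shoulder (plateau) levels of an edge section. "shoulder": split the
# samples at the mid-level between min and max and take the median of each
# half — exact on clean ramps and steps, and robust to noise, whose
# excursions inflate a raw min-max range and with it both d and m.
# "minmax": the raw extremes.
.section_levels <- function(values, normalization = c("shoulder", "minmax")) {
  normalization <- match.arg(normalization)
  if (normalization == "minmax")
    return(list(lo = min(values), hi = max(values)))
  mid <- (min(values) + max(values)) / 2
  list(lo = stats::median(values[values <= mid]),
       hi = stats::median(values[values >= mid]))
}

# First position, scanning from the start, where the normalised values
# reach q; sub-sample linear interpolation between the bracketing samples.
.first_crossing <- function(s, vnorm, q) {
  i <- which(vnorm >= q)[1L]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(s[1L])
  s[i - 1L] + (q - vnorm[i - 1L]) / (vnorm[i] - vnorm[i - 1L]) *
    (s[i] - s[i - 1L])
}

#' Locate a fractional-threshold crossing in an edge section
#'
#' The section is normalised to [0, 1] between its low and high grey-value
#' levels and oriented so the low-intensity side comes first. Scanning from
#' the low side, the first position where the normalised value reaches `q`
#' is returned, with sub-sample linear interpolation between the bracketing
#' samples. `direction = "backward"` instead returns the last upward
#' crossing of `q` at or before `before_mm` (used to pair the 25% crossing
#' with an already located 75% crossing on noisy profiles).
#'
#' @param positions,values the section samples (mm, HU).
#' @param q normalised threshold in (0, 1).
#' @param direction `"forward"` or `"backward"`.
#' @param before_mm for backward scans: oriented position bounding the
#'   search (defaults to the section end).
#' @param polarity as in [edge_section()].
#' @param eps_hu flatness threshold: sections whose HU range is below this
#'   are rejected as degenerate.
#' @param normalization `"shoulder"` (default: low/high plateau levels
#'   estimated as the medians of the samples below/above the mid grey
#'   value, robust to noise) or `"minmax"` (raw section extremes).
#' @return crossing position in mm, measured as oriented arc length from
#'   the low-intensity end of the section.
#' @export
locate_crossing <- function(positions, values, q,
                            direction = c("forward", "backward"),
                            before_mm = NULL, polarity = "auto",
                            eps_hu = 1,
                            normalization = c("shoulder", "minmax")) {
  direction <- match.arg(direction)
  stopifnot(q > 0, q < 1, length(positions) == length(values),
            length(values) >= 2L)
  o <- .orient_section(positions, values, polarity)
  lv <- .section_levels(o$v, normalization)
  rng <- lv$hi - lv$lo
  if (rng < eps_hu)
    stop("flat section: HU range ", signif(rng, 3), " below eps_hu = ",
         eps_hu)
  vnorm <- (o$v - lv$lo) / rng
  if (direction == "forward") return(.first_crossing(o$s, vnorm, q))
  if (is.null(before_mm)) before_mm <- o$s[length(o$s)]
  cand <- which(vnorm <= q & o$s <= before_mm)
  if (length(cand) == 0L) return(NA_real_)
  j <- max(cand)
  if (j == length(vnorm)) return(o$s[j])
  .first_crossing(o$s[c(j, j + 1L)], vnorm[c(j, j + 1L)], q)
}

#' Contour sharpness of one edge section
#'
#' Implements the two contour-sharpness statistics: the distance `d` between
#' the 25% and 75% crossings of the section's normalised grey-value range,
#' and the slope `m = (75% - 25% of the grey-value range) / d` in HU/mm. A
#' sharp contour has small `d` and large `m`.
#'
#' The section's low and high grey-value levels are estimated as shoulder
#' (plateau) levels by default — the medians of the samples below and above
#' the mid grey value — rather than the raw extremes, because noise
#' excursions inflate a min-max range and with it both statistics (see
#' [locate_crossing()]); on clean ramps and edges the two conventions
#' coincide. The 75% crossing is located first (the first crossing scanning
#' from the low-intensity side); the 25% crossing is the last upward
#' crossing of 25% preceding it, so that both crossings bracket the same
#' monotone rise and isolated noise excursions in the flat shoulders cannot
#' masquerade as the edge. If no 25% crossing precedes the 75% crossing,
#' both are recomputed on the section's cumulative-maximum envelope, which
#' guarantees `x75 > x25`.
#'
#' @param profile a `ctp_profile` from [sample_profile()].
#' @param section an [edge_section()].
#' @param eps_hu flatness threshold (HU) below which the section is
#'   rejected.
#' @param normalization `"shoulder"` or `"minmax"`, see [locate_crossing()].
#' @return an object of class `sharpness_result`: list with `edge_label`,
#'   `d_mm`, `m_hu_per_mm`, `x25_mm`, `x75_mm` (oriented arc length from the
#'   low-intensity end of the section), `range_hu` (the low-to-high level
#'   difference used for normalisation) and `n_samples`.
#' @export
compute_sharpness <- function(profile, section, eps_hu = 1,
                              normalization = c("shoulder", "minmax")) {
  stopifnot(inherits(profile, "ctp_profile"), inherits(section, "edge_section"))
  inside <- profile$positions >= section$lo_mm &
    profile$positions < section$hi_mm
  if (sum(inside) < 3L)
    stop("section [", section$lo_mm, ", ", section$hi_mm,
         ") contains fewer than 3 samples")
  pos <- profile$positions[inside]
  val <- profile$values[inside]
  o <- .orient_section(pos, val, section$polarity)
  lv <- .section_levels(o$v, normalization)
  rng <- lv$hi - lv$lo
  if (rng < eps_hu)
    stop("flat section: HU range ", signif(rng, 3), " below eps_hu = ",
         eps_hu)
  vnorm <- (o$v - lv$lo) / rng
  x75 <- .first_crossing(o$s, vnorm, 0.75)
  cand <- which(vnorm <= 0.25 & o$s <= x75)
  if (length(cand) > 0L) {
    j <- max(cand)
    x25 <- .first_crossing(o$s[c(j, j + 1L)], vnorm[c(j, j + 1L)], 0.25)
  } else {
    x25 <- NA_real_
  }
  if (!is.finite(x25) || x25 >= x75) {
    env <- cummax(vnorm)  # monotone envelope: crossings are ordered
    x25 <- .first_crossing(o$s, env, 0.25)
    x75 <- .first_crossing(o$s, env, 0.75)
  }
  d <- x75 - x25
  if (!is.finite(d) || d <= 0)
    stop("could not bracket the 25-75% rise in section ", section$label)
  structure(list(edge_label = section$label, d_mm = d,
                 m_hu_per_mm = 0.5 * rng / d, x25_mm = x25, x75_mm = x75,
                 range_hu = rng, n_samples = length(val)),
            class = "sharpness_result")
}

#' @export
print.sharpness_result <- function(x, ...) {
  cat(sprintf("edge %s: d = %.3f mm, m = %.1f HU/mm (range %.1f HU)\n",
              format(x$edge_label), x$d_mm, x$m_hu_per_mm, x$range_hu))
  invisible(x)
}

#' Measure all four myocardial edges of a volume
#'
#' Samples the probe once and computes the sharpness statistics for each
#' edge section. Sections that fail their preconditions (flat, too few
#' samples) are reported as missing with the failure reason rather than
#' silently dropped.
#'
#' @param vol a [volume3d()].
#' @param probe a [line_probe()].
#' @param sections list of [edge_section()]s.
#' @param eps_hu flatness threshold, HU.
#' @return data.frame with one row per section: `edge_label`, `d_mm`,
#'   `m_hu_per_mm`, `x25_mm`, `x75_mm`, `range_hu`, `ok`, `reason`.
#' @export
measure_edges <- function(vol, probe, sections, eps_hu = 1,
                          normalization = c("shoulder", "minmax")) {
  prof <- sample_profile(vol, probe)
  rows <- lapply(sections, function(sec) {
    res <- tryCatch(compute_sharpness(prof, sec, eps_hu, normalization),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(edge_label = sec$label, d_mm = NA_real_,
                 m_hu_per_mm = NA_real_, x25_mm = NA_real_,
                 x75_mm = NA_real_, range_hu = NA_real_, ok = FALSE,
                 reason = res, stringsAsFactors = FALSE)
    } else {
      data.frame(edge_label = res$edge_label, d_mm = res$d_mm,
                 m_hu_per_mm = res$m_hu_per_mm, x25_mm = res$x25_mm,
                 x75_mm = res$x75_mm, range_hu = res$range_hu, ok = TRUE,
                 reason = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Measure a cohort's averaged volumes
#'
#' Applies [measure_edges()] to every (subject, level) volume of an averaged
#' set, reusing each subject's probe and sections across all levels (and,
#' when called per reconstruction variant, across variants), and assembles
#' the long-format measurement table keyed by (subject, recon, level, edge).
#'
#' @param averaged_set output of [build_averaged_set()].
#' @param probes a single [line_probe()] or a named list per subject.
#' @param sections a list of [edge_section()]s or a named list (per subject)
#'   of such lists.
#' @param recon_variant label recorded in the `recon_variant` column.
#' @param eps_hu flatness threshold, HU.
#' @return a `measurement_table` data.frame with columns `subject_id`,
#'   `recon_variant`, `averaging_level`, `edge_label`, `d_mm`,
#'   `m_hu_per_mm`; rows that failed to measure are kept in the attribute
#'   `"missing"` with their reason.
#' @export
measure_cohort <- function(averaged_set, probes, sections,
                           recon_variant = "fbp_like", eps_hu = 1,
                           normalization = c("shoulder", "minmax")) {
  subjects <- names(averaged_set)
  if (is.null(subjects)) subjects <- sprintf("S%02d", seq_along(averaged_set))
  per_subject_probe <- inherits(probes, "line_probe")
  per_subject_sections <- length(sections) > 0 &&
    inherits(sections[[1L]], "edge_section")
  rows <- list()
  for (si in seq_along(averaged_set)) {
    probe <- if (per_subject_probe) probes else probes[[subjects[si]]]
    secs <- if (per_subject_sections) sections else sections[[subjects[si]]]
    for (lev in names(averaged_set[[si]])) {
      em <- measure_edges(averaged_set[[si]][[lev]], probe, secs, eps_hu,
                          normalization)
      em$subject_id <- subjects[si]
      em$recon_variant <- recon_variant
      em$averaging_level <- as.integer(lev)
      rows[[length(rows) + 1L]] <- em
    }
  }
  tab <- do.call(rbind, rows)
  keep <- tab$ok
  out <- tab[keep, c("subject_id", "recon_variant", "averaging_level",
                     "edge_label", "d_mm", "m_hu_per_mm")]
  rownames(out) <- NULL
  key <- with(out, paste(subject_id, recon_variant, averaging_level,
                         edge_label))
  if (anyDuplicated(key))
    stop("duplicate (subject, recon, level, edge) keys in measurement table")
  attr(out, "missing") <- tab[!keep, c("subject_id", "recon_variant",
                                       "averaging_level", "edge_label",
                                       "reason")]
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' Combine measurement tables
#'
#' Row-binds tables from different reconstruction variants or runs,
#' re-checking key uniqueness.
#'
#' @param ... `measurement_table` objects.
#' @return a `measurement_table`.
#' @export
bind_measurements <- function(...) {
  tabs <- list(...)
  out <- do.call(rbind, lapply(tabs, as.data.frame))
  key <- with(out, paste(subject_id, recon_variant, averaging_level,
                         edge_label))
  if (anyDuplicated(key))
    stop("duplicate (subject, recon, level, edge) keys in measurement table")
  miss <- do.call(rbind, lapply(tabs, attr, "missing"))
  attr(out, "missing") <- miss
  class(out) <- c("measurement_table", "data.frame")
  out
}
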