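#' Select the reference frame of a perfusion series
#'
#' The reference time point is the frame with the highest contrast between
#' the left and right ventricular blood pools — high LV enhancement, low RV
#' enhancement — which is the phase of strongest contrast in the region of
#' interest. Returns the frame maximising `mean(HU | lv_mask) -
#' mean(HU | rv_mask)`; ties are broken by the earliest frame.
#'
#' @param vol a [volume4d()].
#' @param lv_mask,rv_mask logical arrays matching the frame shape, non-empty.
#' @return 1-based frame index.
#' @export
select_reference_frame <- function(vol, lv_mask, rv_mask) {
  stopifnot(inherits(vol, "volume4d"))
  dims <- dim(vol$frames[[1L]])
  if (!identical(dim(lv_mask), dims) || !identical(dim(rv_mask), dims))
    stop("masks must match the frame shape")
  if (!any(lv_mask) || !any(rv_mask)) stop("masks must be non-empty")
  contrast <- vapply(vol$frames, function(f) {
    mean(f[lv_mask]) - mean(f[rv_mask])
  }, numeric(1))
  which.max(contrast)  # which.max returns the first maximum
}

#' Plan a temporal-averaging window
#'
#' Chooses the `level_N` consecutive frame indices centred on the reference
#' frame. Odd windows are symmetric (`ref +/- (N-1)/2`); even windows take
#' the extra frame on the later side (`ref - N/2 + 1 ... ref + N/2`), since
#' post-reference frames sit closer to the enhancement plateau. Windows that
#' would overrun the series are shifted — never shortened — so every level
#' averages exactly N frames and still contains the reference.
#'
#' @param n_frames number of frames in the series.
#' @param ref_index 1-based reference frame index.
#' @param level_N number of frames to combine (N >= 1).
#' @param even_side `"late"` (default) or `"early"`: which side receives the
#'   extra frame of an even window.
#' @return an `averaging_plan`: list with `level_N`, `ref_index`,
#'   `frame_indices`.
#' @export
plan_window <- function(n_frames, ref_index, level_N,
                        even_side = c("late", "early")) {
  even_side <- match.arg(even_side)
  stopifnot(level_N >= 1, ref_index >= 1, ref_index <= n_frames)
  if (level_N > n_frames)
    stop("averaging level N (", level_N, ") exceeds the number of frames (",
         n_frames, ")")
  half <- if (level_N %% 2L == 1L) (level_N - 1L) %/% 2L
          else if (even_side == "late") level_N %/% 2L - 1L
          else level_N %/% 2L
  lo <- ref_index - half
  lo <- max(1L, min(lo, n_frames - level_N + 1L))  # shift to fit, keep length N
  idx <- seq.int(lo, length.out = level_N)
  structure(list(level_N = as.integer(level_N),
                 ref_index = as.integer(ref_index),
                 frame_indices = as.integer(idx)),
            class = "averaging_plan")
}

#' Temporally average a series over a planned window
#'
#' The averaged volume is the voxel-wise, equally weighted arithmetic mean
#' of the N selected frames:
#' `I_combined(x, t) = (1/N) * sum_i I(x, t_i)`.
#' The output inherits the series spacing and origin.
#'
#' @param vol a [volume4d()].
#' @param plan an `averaging_plan` from [plan_window()].
#' @return a [volume3d()].
#' @export
temporal_average <- function(vol, plan) {
  stopifnot(inherits(vol, "volume4d"), inherits(plan, "averaging_plan"))
  idx <- plan$frame_indices
  if (any(idx < 1L) || any(idx > length(vol$frames)))
    stop("plan frame indices out of range")
  acc <- Reduce(`+`, vol$frames[idx])
  volume3d(acc / length(idx), vol$spacing, vol$origin)
}

#' Build the averaged dataset for a cohort
#'
#' For every subject, selects the reference frame from the LV/RV blood-pool
#' masks and produces one temporally averaged volume per requested level.
#' A cohort of 29 subjects at levels {1, 2, 3, 4, 6, 8} therefore yields
#' 174 averaged volumes.
#'
#' @param cohort named list of subjects as returned by [generate_cohort()]
#'   (elements with `volume` and `masks`), or of lists with `volume`,
#'   `lv_mask`, `rv_mask`.
#' @param levels integer vector of averaging levels N.
#' @param even_side passed to [plan_window()].
#' @return named list (subjects) of named lists (levels as character) of
#'   [volume3d()]; each subject's element carries the reference index and
#'   the plans as attributes `ref_index` and `plans`.
#' @export
build_averaged_set <- function(cohort, levels = c(1, 2, 3, 4, 6, 8),
                               even_side = "late") {
  stopifnot(length(levels) >= 1)
  lapply(cohort, function(subj) {
    vol <- subj$volume
    lv <- if (!is.null(subj$masks)) subj$masks$masks$lv_blood else subj$lv_mask
    rv <- if (!is.null(subj$masks)) subj$masks$masks$rv_blood else subj$rv_mask
    ref <- select_reference_frame(vol, lv, rv)
    plans <- lapply(levels, function(N)
      plan_window(length(vol$frames), ref, N, even_side))
    avg <- lapply(plans, function(p) temporal_average(vol, p))
    names(avg) <- as.character(levels)
    attr(avg, "ref_index") <- ref
    attr(avg, "plans") <- plans
    avg
  })
}

#' Count the averaged volumes in an averaged set
#' @param averaged_set output of [build_averaged_set()].
#' @return integer total count across subjects and levels.
#' @export
n_averaged_volumes <- function(averaged_set) {
  sum(vapply(averaged_set, length, integer(1)))
}
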