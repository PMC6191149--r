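#' 4D CT volume series
#'
#' A `volume4d` holds an ordered list of 3D voxel grids (HU-valued) acquired
#' over time, together with the voxel spacing, the world coordinate of the
#' centre of voxel (1,1,1), and the acquisition time of each frame. All frames
#' must share the same shape; HU values are stored as doubles so that
#' sub-threshold edge crossings are never quantised away.
#'
#' Coordinate convention: voxel indices are 1-based; the centre of voxel
#' `(i,j,k)` sits at world position `origin + (i-1, j-1, k-1) * spacing`
#' (voxel-centre alignment, world units mm).
#'
#' @param frames list of 3D numeric arrays with identical dimensions, in HU.
#' @param spacing numeric length 3, voxel spacing `(dx, dy, dz)` in mm,
#'   strictly positive.
#' @param origin numeric length 3, world coordinate (mm) of the centre of
#'   voxel (1,1,1).
#' @param frame_times numeric vector of acquisition times in seconds, one per
#'   frame, strictly increasing.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(frames, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     frame_times = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("'frames' must be a non-empty list of 3D arrays")
  dims <- dim(frames[[1L]])
  if (is.null(dims) || length(dims) != 3L)
    stop("each frame must be a 3D array")
  for (f in frames) {
    if (!identical(dim(f), dims))
      stop("all frames must share identical dimensions")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite numbers (mm)")
  if (is.null(frame_times))
    frame_times <- as.numeric(seq_len(length(frames)) - 1L)
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) != length(frames))
    stop("'frame_times' must have one entry per frame")
  if (any(!is.finite(frame_times)) || any(diff(frame_times) <= 0))
    stop("'frame_times' must be finite and strictly increasing")
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "double"
    f
  })
  structure(
    list(frames = frames, spacing = spacing, origin = origin,
         frame_times = frame_times),
    class = "volume4d"
  )
}

#' Single 3D volume with geometry
#'
#' Lightweight container for one 3D HU grid plus spacing/origin, used for
#' temporally averaged volumes and as the input to line-probe sampling.
#' Shares the coordinate convention of [volume4d()].
#'
#' @param data 3D numeric array (HU).
#' @param spacing,origin as in [volume4d()].
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite numbers (mm)")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<volume4d> %d frames of %d x %d x %d voxels\n",
              length(x$frames), d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.4g x %.4g x %.4g mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin:  (%.4g, %.4g, %.4g) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  times:   %s s\n",
              paste(signif(x$frame_times, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Number of frames in a series
#' @param vol a `volume4d`.
#' @return integer frame count.
#' @export
n_frames <- function(vol) length(vol$frames)

#' Extract one frame as a `volume3d`
#' @param vol a `volume4d`.
#' @param i frame index (1-based).
#' @return a `volume3d` carrying the frame and the series geometry.
#' @export
get_frame <- function(vol, i) {
  if (i < 1L || i > length(vol$frames)) stop("frame index out of range")
  volume3d(vol$frames[[i]], vol$spacing, vol$origin)
}

spacing_of <- function(vol) vol$spacing
origin_of <- function(vol) vol$origin
grid_dim <- function(vol) {
  if (inherits(vol, "volume4d")) dim(vol$frames[[1L]]) else dim(vol$data)
}

#' World to continuous voxel coordinates
#'
#' Maps world positions (mm) to continuous 1-based voxel coordinates using
#' the volume's origin and spacing. The inverse of [voxel_to_world()].
#' Out-of-grid coordinates are returned as-is; consumers decide how to treat
#' them.
#'
#' @param vol a `volume3d` or `volume4d`.
#' @param p numeric length 3 (x, y, z in mm) or an n x 3 matrix of points.
#' @return continuous voxel coordinates, same shape as `p`.
#' @export
world_to_voxel <- function(vol, p) {
  if (is.matrix(p)) {
    sweep(sweep(p, 2L, origin_of(vol), "-"), 2L, spacing_of(vol), "/") + 1
  } else {
    (as.numeric(p) - origin_of(vol)) / spacing_of(vol) + 1
  }
}

#' Continuous voxel to world coordinates
#' @param vol a `volume3d` or `volume4d`.
#' @param idx continuous 1-based voxel coordinates (length 3 or n x 3 matrix).
#' @return world coordinates in mm, same shape as `idx`.
#' @export
voxel_to_world <- function(vol, idx) {
  if (is.matrix(idx)) {
    sweep(sweep(idx - 1, 2L, spacing_of(vol), "*"), 2L, origin_of(vol), "+")
  } else {
    (as.numeric(idx) - 1) * spacing_of(vol) + origin_of(vol)
  }
}
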