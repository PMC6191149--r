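#' Read a 4D CT series from NIfTI
#'
#' Reads either a single NIfTI file (3D or 3D+time) or a directory of
#' per-frame 3D NIfTI files. Spacing and origin are taken from the NIfTI
#' header (pixdim and the xform translation). Frame times come from a JSON
#' sidecar (`<name>.json` next to the file, or `frame_times.json` inside the
#' directory) of the form `{"frame_times": [...], "units": "s"}`; in a
#' directory the sidecar times correspond to the lexicographically sorted
#' file names and frames are reordered so that `frame_times` is increasing.
#' When no sidecar is present, frames are assumed 1 s apart (one acquisition
#' per heart beat at a nominal 60 bpm).
#'
#' @param path path to a NIfTI file or to a directory of per-frame NIfTI
#'   files.
#' @return a [volume4d()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.nii(\\.gz)?$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no NIfTI files found in ", path)
    imgs <- lapply(files, RNifti::readNifti)
    arrs <- lapply(imgs, function(im) {
      a <- as.array(im)
      if (length(dim(a)) == 4L && dim(a)[4L] == 1L) a <- a[, , , 1L]
      if (length(dim(a)) != 3L) stop("per-frame files must be 3D: ", path)
      a
    })
    dims <- dim(arrs[[1L]])
    for (a in arrs) if (!identical(dim(a), dims))
      stop("inconsistent frame shapes in ", path)
    geo <- .nifti_geometry(imgs[[1L]])
    times <- .read_sidecar_times(file.path(path, "frame_times.json"),
                                 length(files))
    ord <- order(times)
    volume4d(arrs[ord], geo$spacing, geo$origin, sort(times))
  } else {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    nd <- length(dim(arr))
    if (nd == 3L) arr <- array(arr, dim = c(dim(arr), 1L))
    if (length(dim(arr)) != 4L) stop("expected a 3D or 4D NIfTI: ", path)
    geo <- .nifti_geometry(img)
    nt <- dim(arr)[4L]
    times <- .read_sidecar_times(.sidecar_path(path), nt)
    frames <- lapply(seq_len(nt), function(i) arr[, , , i])
    ord <- order(times)
    volume4d(frames[ord], geo$spacing, geo$origin, sort(times))
  }
}

#' Write a 4D CT series to NIfTI
#'
#' Writes the series as a single 4D NIfTI file (3D when the series has one
#' frame) with voxel sizes in pixdim and the origin in the sform/qform
#' translation, plus a JSON sidecar `<name>.json` persisting `frame_times`.
#'
#' @param vol a [volume4d()].
#' @param path output NIfTI path (`.nii` or `.nii.gz`); the parent directory
#'   must exist.
#' @return `path`, invisibly.
#' @export
write_series <- function(vol, path) {
  stopifnot(inherits(vol, "volume4d"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  nt <- length(vol$frames)
  dt <- if (nt > 1L) min(diff(vol$frame_times)) else 1
  if (nt == 1L) {
    arr <- vol$frames[[1L]]
    pd <- vol$spacing
  } else {
    arr <- array(unlist(vol$frames, use.names = FALSE),
                 dim = c(dim(vol$frames[[1L]]), nt))
    pd <- c(vol$spacing, dt)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pd
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(frame_times = vol$frame_times, units = "s"),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

.sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}

.read_sidecar_times <- function(sidecar, nt) {
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    times <- as.numeric(meta$frame_times)
    if (length(times) != nt)
      stop("sidecar frame_times length (", length(times),
           ") does not match frame count (", nt, ")")
    if (anyDuplicated(times)) stop("sidecar frame_times must be distinct")
    times
  } else {
    as.numeric(seq_len(nt) - 1L)  # 1 s nominal beat-to-beat spacing
  }
}

# Extract spacing and origin from an RNifti image header. The xform is
# diagonal for all volumes this package writes; for rotated xforms we keep
# column norms as spacing and the translation as origin.
.nifti_geometry <- function(img) {
  pd <- RNifti::pixdim(img)
  spacing <- abs(pd[1:3])
  x <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (!inherits(x, "try-error") && is.matrix(x)) x[1:3, 4]
            else c(0, 0, 0)
  list(spacing = as.numeric(spacing), origin = as.numeric(origin))
}
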