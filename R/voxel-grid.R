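#' Define a voxel grid
#'
#' A voxel grid carries the array dimensions, the voxel size in mm and the
#' voxel-to-mm affine shared by every image in an analysis. The default is a
#' desk-scale grid (16 x 20 x 16 voxels at 3 mm) on which the whole pipeline
#' runs in seconds; an acquisition-scale grid (e.g. `dims = c(64, 64, 32)`)
#' is equally valid, the statistics are grid-size agnostic.
#'
#' @param dims Integer vector of 3 voxel counts, each at least 8.
#' @param voxel_size_mm Numeric vector of 3 voxel edge lengths in mm.
#' @param origin_mm mm coordinate of the first voxel (default zero).
#' @return An object of class `voxel_grid` with fields `dims`,
#'   `voxel_size_mm` and `affine` (4 x 4, voxel index to mm, 0-based indices).
#' @examples
#' g <- voxel_grid()
#' g$dims
#' @export
voxel_grid <- function(dims = c(16L, 20L, 16L), voxel_size_mm = c(3, 3, 3),
                       origin_mm = c(0, 0, 0)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, length(voxel_size_mm) == 3L)
  if (any(dims < 8L))
    stop_named("voxel_grid: all dims must be >= 8 (got %s)",
               paste(dims, collapse = "x"))
  if (any(voxel_size_mm <= 0))
    stop_named("voxel_grid: voxel sizes must be positive")
  affine <- diag(4)
  diag(affine)[1:3] <- voxel_size_mm
  affine[1:3, 4] <- origin_mm
  structure(list(dims = dims, voxel_size_mm = as.numeric(voxel_size_mm),
                 affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %s voxels, %s mm\n",
              paste(x$dims, collapse = " x "),
              paste(x$voxel_size_mm, collapse = " x ")))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$dims)

#' Construct a BOLD run
#'
#' Bundles a 4-D time series (x, y, z, t) with its repetition time, brain mask
#' and grid. Frames are the fourth dimension.
#'
#' @param data 4-D numeric array.
#' @param tr_s Repetition time in seconds.
#' @param grid A [voxel_grid()] matching `dim(data)[1:3]`.
#' @param mask Logical 3-D array; default all `TRUE`.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr_s, grid, mask = NULL) {
  stopifnot(length(dim(data)) == 4L)
  if (!is.null(grid) && any(dim(data)[1:3] != grid$dims))
    stop_named("bold_run: data dims %s do not match grid %s",
               paste(dim(data)[1:3], collapse = "x"),
               paste(grid$dims, collapse = "x"))
  if (dim(data)[4] < 2L) stop_named("bold_run: need at least 2 time points")
  if (!all(is.finite(data))) stop_named("bold_run: non-finite values in data")
  if (!is.finite(tr_s) || tr_s <= 0) stop_named("bold_run: tr_s must be > 0")
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  stopifnot(all(dim(mask) == dim(data)[1:3]))
  structure(list(data = data, tr_s = as.numeric(tr_s), grid = grid,
                 mask = mask),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_run: %d x %d x %d voxels, %d frames, TR = %.3f s, %d mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr_s, sum(x$mask)))
  invisible(x)
}

n_frames <- function(run) dim(run$data)[4]

# Flatten a run to a frames x voxels matrix (mask voxels only if mask given).
run_matrix <- function(run, mask = NULL) {
  d <- dim(run$data)
  m <- matrix(run$data, prod(d[1:3]), d[4])
  if (!is.null(mask)) m <- m[as.vector(mask), , drop = FALSE]
  t(m)
}
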