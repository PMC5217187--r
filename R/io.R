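#' Spatial grid metadata for DSC volumes
#'
#' Light container for the voxel grid shared by a DSC series and any mask,
#' probability map or parametric map paired with it: spatial dimensions in
#' on-disk (x, y, z) order, voxel sizes in mm, and the NIfTI affine mapping
#' voxel indices to world coordinates.
#'
#' @param dim integer(3), spatial dimensions (x, y, z).
#' @param pixdim numeric(3), voxel sizes in mm; default 1 mm isotropic.
#' @param affine 4x4 voxel-to-world matrix; default diagonal from `pixdim`.
#' @return An object of class `dsc_grid`.
#' @export
dsc_grid <- function(dim, pixdim = c(1, 1, 1), affine = NULL) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim <= 0L))
    stop("grid `dim` must be three positive integers (x, y, z)")
  pixdim <- as.numeric(pixdim)
  if (length(pixdim) != 3L || any(!is.finite(pixdim)) || any(pixdim <= 0))
    stop("grid `pixdim` must be three positive voxel sizes")
  if (is.null(affine)) affine <- diag(c(pixdim, 1))
  affine <- unclass(affine)
  attributes(affine) <- list(dim = c(4L, 4L))
  if (!identical(dim(affine), c(4L, 4L)))
    stop("grid `affine` must be a 4x4 matrix")
  structure(list(dim = dim, pixdim = pixdim, affine = affine),
            class = "dsc_grid")
}

#' Compare two voxel grids
#'
#' Two volumes are considered to live on the same grid when their spatial
#' shapes match exactly and their affines agree entrywise within `tol`.
#' The pipeline requires all inputs (series, masks, probability maps) to
#' share one grid; no resampling is performed.
#'
#' @param a,b `dsc_grid` objects (or objects carrying a `grid` element or
#'   attribute).
#' @param tol absolute tolerance on affine entries, in mm.
#' @return `TRUE` or `FALSE`.
#' @export
check_grid_compatibility <- function(a, b, tol = 1e-4) {
  a <- as_dsc_grid(a)
  b <- as_dsc_grid(b)
  if (!identical(a$dim, b$dim)) return(FALSE)
  all(abs(a$affine - b$affine) <= tol)
}

as_dsc_grid <- function(x) {
  if (inherits(x, "dsc_grid")) return(x)
  if (is.list(x) && !is.null(x$grid)) return(as_dsc_grid(x$grid))
  g <- attr(x, "grid")
  if (!is.null(g)) return(as_dsc_grid(g))
  stop("no grid metadata found on object of class ", paste(class(x), collapse = "/"))
}

#' Construct a DSC time series
#'
#' The canonical in-memory representation of a 4D DSC acquisition. The
#' signal array is stored with time as the leading axis, `(t, z, y, x)`,
#' so that one voxel's curve is a contiguous slice and per-frame operations
#' never permute spatial content. All indices in this package are 1-based.
#'
#' @param signal 4D numeric array indexed `(t, z, y, x)`, non-negative
#'   signal intensities in arbitrary units.
#' @param te echo time in milliseconds (> 0).
#' @param frame_spacing time between successive frames, in seconds (> 0).
#' @param brain_mask optional logical 3D array `(z, y, x)`; when absent a
#'   mask is derived downstream by Otsu thresholding of the temporal mean.
#' @param grid optional `dsc_grid`; defaults to a unit grid.
#' @return An object of class `dsc_series`.
#' @export
dsc_series <- function(signal, te, frame_spacing, brain_mask = NULL,
                       grid = NULL) {
  if (!is.array(signal) || length(dim(signal)) != 4L)
    stop("`signal` must be a 4D array indexed (t, z, y, x)")
  if (dim(signal)[1] < 8L)
    stop("DSC series must have at least 8 time frames")
  if (any(signal < 0, na.rm = TRUE))
    stop("`signal` must be non-negative")
  te <- as.numeric(te)
  frame_spacing <- as.numeric(frame_spacing)
  if (length(te) != 1L || !is.finite(te) || te <= 0)
    stop("`te` must be a single positive echo time in milliseconds")
  if (length(frame_spacing) != 1L || !is.finite(frame_spacing) ||
      frame_spacing <= 0)
    stop("`frame_spacing` must be a single positive value in seconds")
  sp <- dim(signal)[2:4]                      # (z, y, x)
  if (!is.null(brain_mask)) {
    if (!identical(dim(brain_mask), sp))
      stop("`brain_mask` shape must equal the spatial shape of `signal`")
    brain_mask <- array(as.logical(brain_mask), dim = sp)
  }
  if (is.null(grid)) grid <- dsc_grid(rev(sp)) else grid <- as_dsc_grid(grid)
  if (!identical(grid$dim, rev(sp)))
    stop("grid dimensions do not match the signal's spatial shape")
  structure(list(signal = signal, te = te, frame_spacing = frame_spacing,
                 brain_mask = brain_mask, grid = grid),
            class = "dsc_series")
}

#' @export
print.dsc_series <- function(x, ...) {
  d <- dim(x$signal)
  cat("DSC series: ", d[1], " frames, grid ",
      paste(rev(d[2:4]), collapse = " x "),
      " (x y z)\n", sep = "")
  cat("  TE ", x$te, " ms, frame spacing ", x$frame_spacing, " s, duration ",
      round((d[1] - 1) * x$frame_spacing, 1), " s\n", sep = "")
  cat("  brain mask: ",
      if (is.null(x$brain_mask)) "none (derived on demand)"
      else paste0(sum(x$brain_mask), " voxels"), "\n", sep = "")
  invisible(x)
}

n_frames <- function(series) dim(series$signal)[1]

# 2D matrix view (frames x voxels) of the 4D signal; shares no copy cost
# beyond the dim change.
as_frame_matrix <- function(arr4d) {
  d <- dim(arr4d)
  dim(arr4d) <- c(d[1], prod(d[2:4]))
  arr4d
}

#' Read a 4D DSC series from NIfTI-1
#'
#' Loads a 4D NIfTI file and reorders axes to the internal `(t, z, y, x)`
#' convention. Frame spacing is taken from the call when supplied,
#' otherwise from the header's fourth pixel dimension.
#'
#' @param path a 4D NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param te echo time in milliseconds.
#' @param frame_spacing seconds per frame; if `NULL`, read from the header.
#' @return A [dsc_series()].
#' @export
read_dsc_series <- function(path, te, frame_spacing = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D DSC series, got a ", length(d), "D volume: ", path)
  pd <- RNifti::pixdim(img)
  if (is.null(frame_spacing)) {
    if (length(pd) < 4L || !is.finite(pd[4]) || pd[4] <= 0)
      stop("frame spacing absent from both the call and the NIfTI header: ",
           path)
    frame_spacing <- pd[4]
  }
  grid <- dsc_grid(d[1:3], pixdim = pd[1:3], affine = unclass(RNifti::xform(img)))
  signal <- aperm(array(as.numeric(img), dim = d), c(4L, 3L, 2L, 1L))
  dsc_series(signal, te = te, frame_spacing = frame_spacing, grid = grid)
}

#' Write a 4D DSC series to NIfTI-1
#'
#' @param series a [dsc_series()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype on-disk datatype; parametric data default to `"float"`.
#' @return `path`, invisibly.
#' @export
write_dsc_series <- function(series, path, datatype = "float") {
  arr <- aperm(series$signal, c(4L, 3L, 2L, 1L))   # (x, y, z, t)
  img <- RNifti::asNifti(arr, internal = FALSE)
  RNifti::pixdim(img) <- c(series$grid$pixdim, series$frame_spacing)
  RNifti::sform(img) <- structure(series$grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a 3D map to NIfTI-1
#'
#' Writes a parametric map (CBV, rCBV, K1/K2, baseline), mask or
#' probability map as float32 NIfTI-1. `NaN`/`NA` values (outside the
#' brain mask) are preserved.
#'
#' @param volume 3D array in internal `(z, y, x)` order.
#' @param path output path.
#' @param grid the `dsc_grid` the map lives on.
#' @param datatype on-disk datatype, default `"float"` (float32).
#' @return `path`, invisibly.
#' @export
write_map <- function(volume, path, grid, datatype = "float") {
  grid <- as_dsc_grid(grid)
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("`volume` must be a 3D array (z, y, x)")
  if (!identical(dim(volume), rev(grid$dim)))
    stop("volume shape ", paste(dim(volume), collapse = "x"),
         " does not match grid ", paste(rev(grid$dim), collapse = "x"))
  arr <- aperm(volume * 1.0, c(3L, 2L, 1L))        # (x, y, z)
  img <- RNifti::asNifti(arr, internal = FALSE)
  RNifti::pixdim(img) <- grid$pixdim
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a 3D volume (map, mask or probability map) from NIfTI-1
#'
#' Returns the volume in internal `(z, y, x)` order with a `grid`
#' attribute. `read_label_volume()` additionally checks for non-negative
#' integer labels; `read_probability_map()` checks the range `[0, 1]`.
#'
#' @param path a 3D NIfTI-1 file.
#' @return 3D array `(z, y, x)` with attribute `grid` (a [dsc_grid()]).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { d <- d[1:3]; dim(img) <- d }
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D: ", path)
  pd <- RNifti::pixdim(img)
  grid <- dsc_grid(d, pixdim = pd[1:3], affine = unclass(RNifti::xform(img)))
  out <- aperm(array(as.numeric(img), dim = d), c(3L, 2L, 1L))
  attr(out, "grid") <- grid
  out
}

#' @rdname read_volume
#' @export
read_label_volume <- function(path) {
  v <- read_volume(path)
  if (any(v < 0) || any(abs(v - round(v)) > 1e-6))
    stop("label volume must contain non-negative integers: ", path)
  g <- attr(v, "grid")
  v <- array(as.integer(round(v)), dim = dim(v))
  attr(v, "grid") <- g
  v
}

#' @rdname read_volume
#' @export
read_probability_map <- function(path) {
  v <- read_volume(path)
  if (any(v < -1e-6) || any(v > 1 + 1e-6))
    stop("probability map values must lie in [0, 1]: ", path)
  g <- attr(v, "grid")
  v <- pmin(pmax(v, 0), 1)
  dim(v) <- rev(g$dim)
  attr(v, "grid") <- g
  v
}
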