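#' 3D volume with physical voxel spacing
#'
#' The carrier object of the pipeline: a 3D grid of non-negative integer
#' intensities together with its physical voxel spacing in micrometres.
#' Array dimensions are (rows, cols, pages) = (y, x, z); `spacing` is given
#' per array dimension in the same order.
#'
#' @param voxels 3D integer array of intensities.
#' @param spacing numeric length-3, voxel spacing in µm per array dimension
#'   (dy, dx, dz); all > 0.
#' @param bit_depth 8 or 16.
#' @param name optional text label.
#' @return An object of class `VolumeImage`.
#' @export
volume_image <- function(voxels, spacing, bit_depth = 8L, name = "") {
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 3L, all(dim(voxels) >= 1L))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop("bit_depth must be 8 or 16")
  if (any(voxels < 0) || any(voxels > 2^bit_depth - 1))
    stop("intensities must lie in [0, 2^bit_depth - 1]")
  structure(list(voxels = voxels, spacing = spacing,
                 bit_depth = bit_depth, name = as.character(name)),
            class = "VolumeImage")
}

#' @export
print.VolumeImage <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("VolumeImage '%s': %d x %d x %d voxels, spacing (%g, %g, %g) um, %d-bit\n",
              x$name, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3], x$bit_depth))
  invisible(x)
}

is_isotropic <- function(v) diff(range(v$spacing)) < 1e-9

#' Read a multi-page TIFF stack as a VolumeImage
#'
#' TIFF spacing tags are unreliable across microscope vendors, so the voxel
#' spacing is always supplied by the caller.
#'
#' @param path path to a single- or multi-page greyscale TIFF.
#' @param spacing voxel spacing (dy, dx, dz) in µm.
#' @param name label; defaults to the file name.
#' @return A [volume_image()] with dimensions (rows, cols, pages).
#' @export
load_stack <- function(path, spacing, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, TRUE)))
    stop("non-greyscale TIFF page (expected a single channel)")
  if (length(unique(shapes)) != 1L)
    stop("inconsistent page shapes: ", paste(unique(shapes), collapse = ", "))
  vox <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) vox[, , i] <- pages[[i]]
  bd <- if (max(vox) > 255L) 16L else 8L
  volume_image(vox, spacing, bd, name)
}

#' Write a VolumeImage (or binary mask) as a multi-page TIFF
#'
#' @param v a `VolumeImage` or a 3D logical/0-1 array.
#' @param path output path.
#' @param bit_depth bits per sample for plain arrays (masks are written as
#'   0/255 8-bit).
#' @return `path`, invisibly.
#' @export
save_stack <- function(v, path, bit_depth = NULL) {
  if (inherits(v, "VolumeImage")) {
    vox <- v$voxels
    bd <- v$bit_depth
  } else {
    vox <- v
    if (is.logical(vox)) vox <- array(as.integer(vox) * 255L, dim(vox))
    bd <- if (is.null(bit_depth)) 8L else bit_depth
  }
  mx <- 2^bd - 1
  pages <- lapply(seq_len(dim(vox)[3]), function(k) vox[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = bd)
  invisible(path)
}

#' Convert a volume to 8-bit (256 grey levels)
#'
#' 16-bit input is linearly rescaled so that the observed minimum maps to 0
#' and the observed maximum to 255 (rounded half-up), the ImageJ default;
#' 8-bit input is returned unchanged.
#'
#' @param v a `VolumeImage`.
#' @return An 8-bit `VolumeImage`.
#' @export
to_8bit <- function(v) {
  stopifnot(inherits(v, "VolumeImage"))
  if (v$bit_depth == 8L) return(v)
  rng <- range(v$voxels)
  if (rng[1] == rng[2]) {
    warning("constant-valued volume: mapping all voxels to 0")
    vox <- array(0L, dim(v$voxels))
  } else {
    vox <- array(as.integer(round_half_up(
      255 * (v$voxels - rng[1]) / (rng[2] - rng[1]))), dim(v$voxels))
  }
  volume_image(vox, v$spacing, 8L, v$name)
}

# linear (or nearest-neighbour) resampling along one array axis
resample_axis <- function(arr, axis, old_sp, target, method) {
  n_old <- dim(arr)[axis]
  extent <- n_old * old_sp
  n_new <- max(1L, as.integer(round(extent / target)))
  if (n_new == n_old && abs(old_sp - target) < 1e-12) return(arr)
  # voxel-centre coordinates of the new grid, in old index units
  pos <- ((seq_len(n_new) - 0.5) * target) / old_sp + 0.5
  if (method == "nearest") {
    i0 <- pmin(pmax(round(pos), 1L), n_old)
    idx_list <- list(quote(expr =), quote(expr =), quote(expr =))
    idx_list[[axis]] <- i0
    return(do.call(`[`, c(list(arr), idx_list, list(drop = FALSE))))
  }
  lo <- pmin(pmax(floor(pos), 1), n_old)
  hi <- pmin(lo + 1, n_old)
  w <- pos - lo
  sel <- function(i) {
    idx_list <- list(quote(expr =), quote(expr =), quote(expr =))
    idx_list[[axis]] <- i
    do.call(`[`, c(list(arr), idx_list, list(drop = FALSE)))
  }
  a_lo <- sel(lo)
  a_hi <- sel(hi)
  shp <- c(1L, 1L, 1L)
  shp[axis] <- n_new
  w_arr <- array(rep(w, each = prod(dim(a_lo)[seq_len(axis - 1)])),
                 dim(a_lo))
  a_lo * (1 - w_arr) + a_hi * w_arr
}

#' Resample a volume onto an isotropic grid
#'
#' All geometric computation downstream (distance map, skeleton lengths,
#' radii) assumes isotropic voxels, so anisotropic stacks are resampled once,
#' here. Greyscale volumes use linear interpolation; binary masks use
#' nearest-neighbour so the output stays binary. The physical extent of each
#' axis is preserved to within one target voxel.
#'
#' @param v a `VolumeImage` (greyscale) or 3D logical array (with `spacing`).
#' @param target isotropic voxel size in µm; defaults to the smallest spacing
#'   component.
#' @param spacing required when `v` is a plain array.
#' @return Resampled `VolumeImage`, or logical array for mask input.
#' @export
resample_isotropic <- function(v, target = NULL, spacing = NULL) {
  if (inherits(v, "VolumeImage")) {
    arr <- v$voxels
    sp <- v$spacing
    binary <- FALSE
  } else {
    stopifnot(!is.null(spacing))
    arr <- v
    sp <- rep(as.numeric(spacing), length.out = 3)
    binary <- TRUE
  }
  if (is.null(target)) target <- min(sp)
  stopifnot(target > 0)
  if (target > min(dim(arr) * sp))
    stop("target voxel size exceeds the smallest physical extent")
  method <- if (binary) "nearest" else "linear"
  out <- arr * 1.0
  for (ax in 1:3) out <- resample_axis(out, ax, sp[ax], target, method)
  if (binary) return(array(out > 0.5, dim(out)))
  mx <- 2^v$bit_depth - 1
  vox <- array(as.integer(pmin(pmax(round_half_up(out), 0), mx)), dim(out))
  volume_image(vox, rep(target, 3), v$bit_depth, v$name)
}
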