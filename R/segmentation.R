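#' Greyscale histogram of an 8-bit volume
#'
#' @param v an 8-bit `VolumeImage`.
#' @return Integer vector of length 256 (counts for grey levels 0..255),
#'   summing to the voxel total.
#' @export
grey_histogram <- function(v) {
  stopifnot(inherits(v, "VolumeImage"))
  if (v$bit_depth != 8L) stop("grey_histogram expects an 8-bit volume")
  tabulate(as.integer(v$voxels) + 1L, nbins = 256L)
}

# centered moving average; shrinking window at the edges
smooth_counts <- function(counts, width) {
  half <- width %/% 2
  n <- length(counts)
  cs <- cumsum(c(0, counts))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# local maxima of the smoothed curve, ordered by grey level
find_peaks <- function(s, min_sep = 5L) {
  n <- length(s)
  cand <- which(vapply(seq_len(n), function(i) {
    lo <- max(1L, i - min_sep); hi <- min(n, i + min_sep)
    s[i] > 0 && s[i] == max(s[lo:hi]) && any(s[lo:hi] < s[i])
  }, TRUE))
  if (length(cand) == 0L) return(integer(0))
  # collapse plateaus of equal smoothed value
  keep <- c(TRUE, diff(cand) > min_sep)
  cand[keep]
}

#' Background/tissue threshold at the histogram inflexion point
#'
#' The first threshold separates image background from tissue. It is placed
#' at the inflexion point of the greyscale frequency curve between the first
#' two population peaks, operationalized as the first zero crossing of the
#' second difference of the moving-average-smoothed histogram after the
#' first peak.
#'
#' @param counts length-256 histogram.
#' @param smooth moving-average window width (grey levels).
#' @return Grey level (0-255) of the threshold.
#' @export
find_background_threshold <- function(counts, smooth = 11L) {
  stopifnot(length(counts) == 256L, all(counts >= 0))
  s <- smooth_counts(counts, smooth)
  pk <- find_peaks(s)
  if (length(pk) < 2L)
    stop("histogram is unimodal after smoothing: ",
         "set the background threshold manually")
  p1 <- pk[1]; p2 <- pk[2]
  # curv[j]: second central difference of the smoothed curve at index j
  curv <- c(NA, diff(s, differences = 2L), NA)
  for (j in (p1 + 1):(p2 - 1)) {
    # strict sign change: zero-curvature plateaus (empty grey runs between
    # populations) are not inflexions
    if (!is.na(curv[j - 1]) && !is.na(curv[j]) &&
        curv[j - 1] < 0 && curv[j] > 0)
      return(j - 1L)  # index j holds grey level j - 1
  }
  # fall back to the valley minimum if curvature never crosses zero
  which.min(s[p1:p2]) + p1 - 2L
}

#' Gaussian fit of the tissue voxel population
#'
#' Least-squares fit of `A * exp(-0.5 ((g - mean)/sd)^2)` to the histogram
#' counts over a grey range covering the tissue peak. The default range runs
#' from the background threshold up to a window symmetric about the tissue
#' mode, `mode + (mode - t_background)`, additionally capped at the valley
#' between the tissue and vessel populations (the first grey level after the
#' mode where the smoothed curve stops decreasing): at high vascular density
#' the vessel population is tall enough that the symmetric window alone would
#' drag the fit toward it.
#'
#' @param counts length-256 histogram.
#' @param fit_range integer length-2 grey interval, or NULL for the default.
#' @param t_background background threshold (needed for the default range).
#' @param smooth smoothing width used to locate the tissue mode.
#' @return List `(tissue_mean, tissue_sd, amplitude, fit_range)`.
#' @export
fit_tissue_gaussian <- function(counts, fit_range = NULL, t_background = NULL,
                                smooth = 11L) {
  stopifnot(length(counts) == 256L)
  grey <- 0:255
  if (is.null(fit_range)) {
    if (is.null(t_background))
      t_background <- find_background_threshold(counts, smooth)
    s <- smooth_counts(counts, smooth)
    # the tissue population is the first peak above the background threshold
    # (populations are ordered background < tissue < vessel); the vessel peak
    # can be the taller one on densely vascularized samples, so a global
    # argmax would lock onto the wrong population
    pk_grey <- find_peaks(s) - 1L
    above <- pk_grey[pk_grey > t_background]
    sel <- grey > t_background
    mode_g <- if (length(above)) above[1] else grey[sel][which.max(s[sel])]
    hi <- min(255L, 2L * mode_g - t_background)
    # cap at the tissue/vessel valley: when a brighter population peak exists
    # past the tissue mode, stop at the minimum of the smoothed curve between
    # the two peaks; the symmetric window alone would swallow the vessel peak
    # on densely vascularized samples
    nxt <- pk_grey[pk_grey > mode_g + 2L]
    if (length(nxt)) {
      between <- (mode_g + 1L):nxt[1]
      valley <- between[which.min(s[between + 1L])]  # s index = grey + 1
      hi <- min(hi, valley)
    }
    fit_range <- c(t_background, hi)
  }
  in_r <- grey >= fit_range[1] & grey <= fit_range[2]
  if (sum(in_r) < 4L) stop("fewer than 4 grey levels in the fit range")
  g <- grey[in_r]; y <- as.numeric(counts[in_r])
  if (sum(y) <= 0) stop("no voxels in the fit range")
  mu0 <- weighted.mean(g, y)
  sd0 <- sqrt(weighted.mean((g - mu0)^2, y))
  if (sum(y > 0) < 3L || sd0 < 0.5) {
    # (near-)delta tissue population: the SD is below the grey quantization
    # limit and a Gaussian fit is singular; report the moments with the SD
    # floored at half a grey level
    warning("tissue population narrower than the grey quantization; ",
            "using moment estimates with SD floored at 0.5")
    return(list(tissue_mean = mu0, tissue_sd = max(sd0, 0.5),
                amplitude = max(y), fit_range = fit_range))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-0.5 * ((g - mu)/sg)^2),
                      start = list(A = max(y), mu = mu0, sg = sd0),
                      lower = c(A = 0, mu = fit_range[1] - 10, sg = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("tissue Gaussian fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  list(tissue_mean = unname(cf["mu"]), tissue_sd = unname(cf["sg"]),
       amplitude = unname(cf["A"]), fit_range = fit_range)
}

#' Vessel threshold from the tissue Gaussian
#'
#' `mean + z * sd` of the fitted tissue population, rounded half-up and
#' capped at 255. The default multiplier 1.96 (the 97.5% normal quantile)
#' excludes 97.5% of non-labelled tissue voxels.
#'
#' @param tissue_mean,tissue_sd fitted tissue Gaussian parameters.
#' @param z exclusion multiplier (default 1.96).
#' @return Integer grey threshold.
#' @export
vessel_threshold <- function(tissue_mean, tissue_sd, z = 1.96) {
  stopifnot(tissue_sd > 0)
  min(255L, as.integer(round_half_up(tissue_mean + z * tissue_sd)))
}

#' Histogram model of a volume: counts, tissue Gaussian, both thresholds
#'
#' @param v an 8-bit `VolumeImage`.
#' @param smooth histogram smoothing width.
#' @param z vessel-threshold multiplier.
#' @param fit_range optional explicit Gaussian fit range.
#' @return An object of class `HistogramModel`.
#' @export
histogram_model <- function(v, smooth = 11L, z = 1.96, fit_range = NULL) {
  counts <- grey_histogram(v)
  t_bg <- find_background_threshold(counts, smooth)
  g <- fit_tissue_gaussian(counts, fit_range, t_background = t_bg,
                           smooth = smooth)
  t_v <- vessel_threshold(g$tissue_mean, g$tissue_sd, z)
  if (t_bg >= t_v) stop("degenerate thresholds: t_background >= t_vessel")
  structure(list(counts = counts, tissue_mean = g$tissue_mean,
                 tissue_sd = g$tissue_sd, amplitude = g$amplitude,
                 fit_range = g$fit_range, z = z,
                 t_background = t_bg, t_vessel = t_v),
            class = "HistogramModel")
}

#' @export
print.HistogramModel <- function(x, ...) {
  cat(sprintf(paste0("HistogramModel: t_background = %d, tissue N(%.2f, %.2f),",
                     " t_vessel = mean + %.2f sd = %d\n"),
              x$t_background, x$tissue_mean, x$tissue_sd, x$z, x$t_vessel))
  invisible(x)
}

#' Binarize a volume with the two thresholds
#'
#' @param v an 8-bit `VolumeImage`.
#' @param hm a `HistogramModel` (or list with `t_background`, `t_vessel`).
#' @return An object of class `BinaryMasks`: `tissue_mask` (voxel >=
#'   t_background), `vessel_mask` (voxel >= t_vessel), `spacing`. The vessel
#'   mask is a subset of the tissue mask by construction.
#' @export
binarize <- function(v, hm) {
  stopifnot(inherits(v, "VolumeImage"))
  structure(list(tissue_mask = v$voxels >= hm$t_background,
                 vessel_mask = v$voxels >= hm$t_vessel,
                 spacing = v$spacing),
            class = "BinaryMasks")
}

#' 3D median filter on a binary mask (3x3x3 majority vote)
#'
#' Suppresses artifactual isolated voxels: each voxel is replaced by the
#' majority value of its 3 x 3 x 3 neighbourhood, with symmetric reflection
#' at the grid faces. Equivalent to a 3-voxel median filter on binary data.
#'
#' @param mask 3D logical array.
#' @return Filtered 3D logical array of the same dimensions.
#' @export
median_filter_3d <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  array(cpp_majority3d(as.vector(mask), dim(mask)), dim(mask))
}

#' Full non-visual segmentation of a greyscale stack
#'
#' Histogram thresholds applied per stack, followed (optionally) by the 3D
#' median filter on both masks.
#'
#' @param v an 8-bit `VolumeImage`.
#' @param smooth histogram smoothing width.
#' @param z vessel-threshold multiplier.
#' @param median_filter apply the 3x3x3 majority filter to both masks.
#' @return List `(model, masks)`.
#' @export
segment_volume <- function(v, smooth = 11L, z = 1.96, median_filter = TRUE) {
  hm <- histogram_model(v, smooth = smooth, z = z)
  masks <- binarize(v, hm)
  if (median_filter) {
    masks$tissue_mask <- median_filter_3d(masks$tissue_mask)
    masks$vessel_mask <- median_filter_3d(masks$vessel_mask)
    # the majority vote cannot break nesting of thresholded masks, but keep
    # the invariant explicit
    masks$vessel_mask <- masks$vessel_mask & masks$tissue_mask
  }
  list(model = hm, masks = masks)
}
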