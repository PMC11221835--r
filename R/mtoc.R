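## MTOC detection from the gamma-tubulin channel: percentile contrast
## normalization, rolling-ball background subtraction, then per-cell
## thresholded spot picking. Mirrors the classical ImageJ sequence
## (LUT rescale -> subtract background -> threshold) with every parameter
## explicit and logged in the configuration.

#' Percentile contrast normalization
#'
#' Clips intensities at the given low/high percentiles and maps the clipped
#' range affinely onto [0, 1]. The mapping is monotone, so the ordering of
#' unclipped pixels is preserved. A constant image maps to all zeros (the
#' documented degenerate convention).
#'
#' @param raster numeric matrix of finite, non-negative intensities.
#' @param percentiles numeric(2), low and high clipping percentiles as
#'   fractions (default \code{c(0.001, 0.9999)}).
#' @return Numeric matrix with values in [0, 1].
#' @export
normalizeIntensity <- function(raster, percentiles = c(0.001, 0.9999)) {
  .checkRaster(raster)
  stopifnot(length(percentiles) == 2L, all(percentiles >= 0),
            all(percentiles <= 1), percentiles[1] < percentiles[2])
  q <- stats::quantile(raster, percentiles, names = FALSE)
  if (q[2] <= q[1]) return(matrix(0, nrow(raster), ncol(raster)))
  out <- pmin(pmax(raster, q[1]), q[2])
  (out - q[1]) / (q[2] - q[1])
}

#' Rolling-ball background subtraction
#'
#' Estimates smooth background as the morphological grayscale opening of the
#' image with a disc of the given physical radius and subtracts it, clamping
#' at zero. A flat image maps to zero everywhere; structures smaller than the
#' ball (spots, puncta) are preserved.
#'
#' @param raster numeric matrix of finite, non-negative intensities.
#' @param radius ball radius in um.
#' @param pixelSize pixel size in um/pixel; the radius must be at least one
#'   pixel.
#' @return Numeric matrix, everywhere \code{>= 0}.
#' @export
subtractBackground <- function(raster, radius, pixelSize) {
  .checkRaster(raster)
  stopifnot(length(radius) == 1L, is.finite(radius), pixelSize > 0)
  rpx <- radius / pixelSize
  if (rpx < 1)
    stop("background radius (", radius, " um = ", signif(rpx, 3),
         " px) must be at least one pixel", call. = FALSE)
  mx <- max(raster)
  if (mx == 0) return(raster)
  brush <- EBImage::makeBrush(2L * floor(rpx) + 1L, "disc")
  # EBImage grayscale morphology works on [0, 1]; min/max filters commute
  # with positive scaling, so rescale, open, and scale back
  bg <- EBImage::imageData(EBImage::opening(raster / mx, brush)) * mx
  pmax(raster - bg, 0)
}

#' Locate the MTOC in each cell
#'
#' Per cell: threshold the (pre-processed) tubulin signal inside the cell
#' with the configured data-driven method, label the suprathreshold connected
#' components, keep the component with the largest integrated intensity, and
#' report its intensity-weighted centroid as the MTOC position. Exactly one
#' MTOC is reported per cell; a cell with no suprathreshold tubulin pixel is
#' reported with \code{detected = FALSE} so downstream scoring can exclude
#' it. Ties between components are broken by greater peak intensity, then by
#' smaller component label in scan order. The whole pipeline is
#' deterministic.
#'
#' @param tubulin numeric matrix, gamma-tubulin channel.
#' @param cells a [LabelMask-class] of kind \code{"cell"}.
#' @param config an [AnalysisConfig-class].
#' @param pixelSize pixel size in um/pixel.
#' @param preprocess if TRUE (default) apply [normalizeIntensity()] and
#'   [subtractBackground()] first; set FALSE if \code{tubulin} is already
#'   processed.
#' @return data.frame with one row per cell: \code{cell_label}, \code{row},
#'   \code{col} (real-valued pixel coordinates), \code{peak_intensity},
#'   \code{detected}.
#' @export
detectMtoc <- function(tubulin, cells, config = analysisConfig(), pixelSize,
                       preprocess = TRUE) {
  stopifnot(is(cells, "LabelMask"), maskKind(cells) == "cell")
  .checkRaster(tubulin, "tubulin")
  if (!identical(dim(tubulin), dim(cells)))
    stop("tubulin raster and cell mask must be co-registered", call. = FALSE)
  lab <- labels(cells)
  labs <- sort(unique(lab[lab > 0L]))
  empty <- data.frame(cell_label = integer(), row = numeric(),
                      col = numeric(), peak_intensity = numeric(),
                      detected = logical())
  if (length(labs) == 0L) return(empty)
  proc <- if (preprocess) {
    subtractBackground(normalizeIntensity(tubulin, config@normPercentiles),
                       config@backgroundRadius, pixelSize)
  } else tubulin
  res <- lapply(labs, function(k) {
    inCell <- lab == k
    vals <- proc[inCell]
    thr <- .dataThreshold(vals, config@thresholdMethod,
                          config@thresholdPercentile)
    supra <- inCell & (proc > thr)
    if (!any(supra))
      return(data.frame(cell_label = k, row = NA_real_, col = NA_real_,
                        peak_intensity = 0, detected = FALSE))
    comp <- EBImage::bwlabel(supra)
    ncomp <- max(comp)
    integrated <- peak <- numeric(ncomp)
    for (j in seq_len(ncomp)) {
      v <- proc[comp == j]
      integrated[j] <- sum(v)
      peak[j] <- max(v)
    }
    best <- order(-integrated, -peak, seq_len(ncomp))[1L]
    idx <- which(comp == best, arr.ind = TRUE)
    w <- proc[comp == best]
    pos <- c(sum(idx[, 1L] * w), sum(idx[, 2L] * w)) / sum(w)
    # guard: for non-convex components the weighted centroid can fall outside
    # the owning cell; snap to the component's peak pixel in that case
    pr <- min(max(round(pos[1L]), 1L), nrow(lab))
    pc <- min(max(round(pos[2L]), 1L), ncol(lab))
    if (lab[pr, pc] != k) {
      pk <- idx[which.max(w), , drop = TRUE]
      pos <- as.numeric(pk)
    }
    data.frame(cell_label = k, row = pos[1L], col = pos[2L],
               peak_intensity = max(w), detected = TRUE)
  })
  do.call(rbind, res)
}
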