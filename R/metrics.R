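## Positioning metrics: the in-circle intensity ratio and its normalization
## to control wells, the peripheral-lysosome cell fraction, aggregate -
## lysosome colocalization, and the pixels-above-threshold readout.

#' Boolean disc mask of fixed physical diameter
#'
#' A pixel belongs to the mask iff its centre lies within
#' \code{diameter / 2} (in um) of \code{center}; the mask is clipped at the
#' image bounds. Coordinates are 1-based (row, col) pixel indices with pixel
#' (i, j) centred at (i, j); the centre may be real-valued. A circle always
#' contains at least the pixel under its centre, so diameters below the pixel
#' spacing degenerate to that single pixel. A centre outside the image gives
#' an empty mask with a warning.
#'
#' @param center numeric(2), (row, col) of the circle centre in pixels.
#' @param diameter circle diameter in um.
#' @param pixelSize pixel size in um/pixel.
#' @param dim integer(2), (rows, cols) of the target raster.
#' @return Logical matrix of the requested size.
#' @export
circleMask <- function(center, diameter, pixelSize, dim) {
  stopifnot(length(center) == 2L, length(dim) == 2L, pixelSize > 0)
  if (!is.finite(diameter) || diameter <= 0)
    stop("diameter must be > 0", call. = FALSE)
  out <- matrix(FALSE, dim[1L], dim[2L])
  if (anyNA(center) || center[1L] < 1 || center[1L] > dim[1L] ||
      center[2L] < 1 || center[2L] > dim[2L]) {
    warning("circle centre (", paste(signif(center, 5), collapse = ", "),
            ") lies outside the image; returning an empty mask")
    return(out)
  }
  r <- diameter / 2 / pixelSize
  r0 <- max(1L, floor(center[1L] - r)); r1 <- min(dim[1L], ceiling(center[1L] + r))
  c0 <- max(1L, floor(center[2L] - r)); c1 <- min(dim[2L], ceiling(center[2L] + r))
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - center[1L])^2, (cols - center[2L])^2, `+`)
  out[rows, cols] <- d2 <= r^2
  if (!any(out))
    out[round(center[1L]), round(center[2L])] <- TRUE
  out
}

#' Per-cell in-circle intensity ratio
#'
#' The raw clustering readout of one cell: the summed lysosomal intensity
#' inside the measurement circle centred on the cell's MTOC, divided by the
#' summed intensity over the whole cell. By default the numerator region is
#' the circle intersected with the cell, which bounds the ratio in [0, 1] and
#' excludes bleed-through from neighbouring cells; the raw (unclipped) circle
#' is available via the configuration. The ratio is invariant to positive
#' rescaling of the lysosome channel. Cells with an undetected MTOC or zero
#' whole-cell signal are returned as excluded records with a reason, never
#' dropped silently.
#'
#' @param lysosome numeric matrix, lysosomal-marker channel.
#' @param cellMask logical matrix selecting the cell's pixels.
#' @param mtoc single-row data.frame (or list) with \code{row}, \code{col},
#'   \code{detected}, and optionally \code{cell_label}, as produced by
#'   [detectMtoc()].
#' @param config an [AnalysisConfig-class].
#' @param pixelSize pixel size in um/pixel.
#' @param nucleusMask optional logical matrix of the cell's nuclear pixels,
#'   used only when \code{excludeNucleusFromDenominator} is set.
#' @return One-row data.frame: \code{cell_label}, \code{raw_ratio},
#'   \code{circle_area_px} (pixels actually measured in the numerator),
#'   \code{cell_area_px}, \code{excluded}, \code{reason}.
#' @export
clusteringRatio <- function(lysosome, cellMask, mtoc,
                            config = analysisConfig(), pixelSize,
                            nucleusMask = NULL) {
  .checkRaster(lysosome, "lysosome")
  stopifnot(is.logical(cellMask), identical(dim(lysosome), dim(cellMask)))
  lbl <- if (!is.null(mtoc$cell_label)) as.integer(mtoc$cell_label) else NA_integer_
  rec <- function(ratio, circleA, reason = NA_character_) {
    data.frame(cell_label = lbl, raw_ratio = ratio,
               circle_area_px = circleA, cell_area_px = sum(cellMask),
               excluded = !is.na(reason), reason = reason,
               stringsAsFactors = FALSE)
  }
  if (!isTRUE(as.logical(mtoc$detected)))
    return(rec(NA_real_, NA_integer_, "no MTOC detected"))
  if (!any(cellMask))
    return(rec(NA_real_, NA_integer_, "empty cell mask"))
  circ <- circleMask(c(mtoc$row, mtoc$col), config@circleDiameter, pixelSize,
                     dim(lysosome))
  num <- if (config@clipCircleToCell) circ & cellMask else circ
  den <- cellMask
  if (config@excludeNucleusFromDenominator && !is.null(nucleusMask))
    den <- den & !nucleusMask
  denom <- sum(lysosome[den])
  if (denom <= 0)
    return(rec(NA_real_, sum(num), "empty lysosome signal"))
  rec(sum(lysosome[num]) / denom, sum(num))
}

.wellStat <- function(x, statistic) {
  switch(statistic, mean = mean(x), median = stats::median(x),
         stop("unknown statistic: ", statistic, call. = FALSE))
}

#' Normalize a well's readout to the control
#'
#' The stat-and-divide contract shared by the clustering value and the flow
#' RFP/GFP fold change: summarize the treated well and the pooled control
#' with the same statistic and return their ratio. A control group normalized
#' against itself is exactly 1.
#'
#' @param treated numeric vector of per-cell (or per-event) readouts for one
#'   well.
#' @param control numeric vector of pooled control readouts.
#' @param statistic \code{"mean"} (default) or \code{"median"}.
#' @return numeric(1): the normalized value, or \code{NA} (with a warning)
#'   when the treated well is empty.
#' @examples
#' clusteringValue(c(0.32, 0.34), c(0.30, 0.30))  # 1.1
#' @export
clusteringValue <- function(treated, control, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  control <- control[!is.na(control)]
  if (length(control) == 0L)
    stop("control group is empty; fold changes are undefined", call. = FALSE)
  cs <- .wellStat(control, statistic)
  if (!is.finite(cs) || cs <= 0)
    stop("control statistic must be positive (got ", format(cs), ")",
         call. = FALSE)
  treated <- treated[!is.na(treated)]
  if (length(treated) == 0L) {
    warning("treated well has no measurements; returning NA")
    return(NA_real_)
  }
  .wellStat(treated, statistic) / cs
}

#' Percentage of cells with peripheral lysosomes
#'
#' A cell is flagged "peripheral" when the fraction of its lysosomal
#' intensity falling outside its central region (i.e. in the peripheral
#' region, cell minus central) exceeds \code{threshold}. Returns the
#' percentage of flagged cells over all analyzable cells, together with the
#' per-cell fractions and flags.
#'
#' @param lysosome numeric matrix, lysosomal channel.
#' @param cells a [LabelMask-class] of kind \code{"cell"}.
#' @param central a [LabelMask-class] of kind \code{"central"} derived from
#'   \code{cells} (see [centralRegion()]).
#' @param threshold peripheral intensity fraction above which a cell is
#'   flagged (default 0.5).
#' @param exclude integer vector of cell labels to skip (e.g. border cells).
#' @return List with \code{percentage} (0-100) and \code{cells}, a data.frame
#'   of \code{cell_label}, \code{peripheral_fraction}, \code{peripheral}.
#' @export
peripheralCellFraction <- function(lysosome, cells, central, threshold = 0.5,
                                   exclude = integer()) {
  stopifnot(is(cells, "LabelMask"), is(central, "LabelMask"),
            maskKind(central) == "central",
            identical(dim(cells), dim(central)))
  .checkRaster(lysosome, "lysosome")
  lab <- labels(cells); cen <- labels(central)
  if (any(cen > 0L & cen != lab))
    stop("central mask is not nested within the cell mask", call. = FALSE)
  labs <- setdiff(sort(unique(lab[lab > 0L])), exclude)
  rows <- lapply(labs, function(k) {
    tot <- sum(lysosome[lab == k])
    if (tot <= 0) return(NULL)
    per <- sum(lysosome[lab == k & cen != k]) / tot
    data.frame(cell_label = k, peripheral_fraction = per,
               peripheral = per > threshold)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L)
    stop("no cells with lysosomal signal to analyze", call. = FALSE)
  list(percentage = 100 * mean(rows$peripheral), cells = rows)
}

#' Lysosomal intensity within aggregate areas, per cell
#'
#' Thresholds the aggregate channel within each cell (data-driven method from
#' the configuration), removes aggregate specks below \code{minAggregateArea}
#' pixels, and reports the summed and mean lysosomal intensity inside the
#' remaining aggregate area. A cell without a detected aggregate yields a
#' valid all-zero record.
#'
#' @param lysosome,aggregate co-registered numeric matrices.
#' @param cells a [LabelMask-class] of kind \code{"cell"}.
#' @param config an [AnalysisConfig-class].
#' @param minAggregateArea minimum aggregate component area in px
#'   (default 5).
#' @return data.frame with one row per cell: \code{cell_label},
#'   \code{aggregate_area_px}, \code{lysosome_intensity_in_aggregate},
#'   \code{mean_intensity_in_aggregate}.
#' @export
aggregateColocalization <- function(lysosome, aggregate, cells,
                                    config = analysisConfig(),
                                    minAggregateArea = 5L) {
  .checkRaster(lysosome, "lysosome"); .checkRaster(aggregate, "aggregate")
  stopifnot(is(cells, "LabelMask"), identical(dim(lysosome), dim(aggregate)),
            identical(dim(lysosome), dim(cells)))
  lab <- labels(cells)
  labs <- sort(unique(lab[lab > 0L]))
  res <- lapply(labs, function(k) {
    inCell <- lab == k
    zero <- data.frame(cell_label = k, aggregate_area_px = 0L,
                       lysosome_intensity_in_aggregate = 0,
                       mean_intensity_in_aggregate = 0)
    vals <- aggregate[inCell]
    if (max(vals) <= 0) return(zero)
    thr <- .dataThreshold(vals, config@thresholdMethod,
                          config@thresholdPercentile)
    mask <- inCell & (aggregate > thr)
    if (!any(mask)) return(zero)
    mask <- .filterRelabel(EBImage::bwlabel(mask), minAggregateArea) > 0L
    a <- sum(mask)
    if (a == 0L) return(zero)
    s <- sum(lysosome[mask])
    data.frame(cell_label = k, aggregate_area_px = a,
               lysosome_intensity_in_aggregate = s,
               mean_intensity_in_aggregate = s / a)
  })
  do.call(rbind, res)
}

#' Fraction of pixels above a threshold
#'
#' The normalized pixels-above-threshold readout used for whole-field
#' reporter measurements (e.g. oxidative-stress dyes).
#'
#' @param raster numeric matrix of finite values.
#' @param threshold numeric(1); pixels strictly above it are counted.
#' @return numeric(1) in [0, 1].
#' @export
fractionAboveThreshold <- function(raster, threshold) {
  if (!is.matrix(raster) || length(raster) == 0L)
    stop("raster must be a non-empty matrix", call. = FALSE)
  if (anyNA(raster) || any(!is.finite(raster)))
    stop("raster contains non-finite values", call. = FALSE)
  stopifnot(length(threshold) == 1L, is.finite(threshold))
  sum(raster > threshold) / length(raster)
}
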