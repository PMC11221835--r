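## Segmentation of nuclei and whole-cell territories, and the central /
## peripheral partition of each cell. Morphological primitives come from
## EBImage; this file only fixes the pipeline's conventions (data-driven
## thresholds, seed-preserving propagation, debris rejection).

.checkRaster <- function(raster, what = "raster") {
  if (!is.matrix(raster) || !is.numeric(raster))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (anyNA(raster) || any(!is.finite(raster)))
    stop(what, " contains non-finite values", call. = FALSE)
  if (any(raster < 0))
    stop(what, " contains negative intensities", call. = FALSE)
  invisible(TRUE)
}

## Data-driven threshold on a vector of intensities. Otsu runs on the
## canonical EBImage implementation over a 256-level histogram; a constant
## positive sample thresholds at half its value so that uniformly bright
## support stays suprathreshold.
.dataThreshold <- function(vals, method = "otsu", percentile = 0.99) {
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L || max(vals) <= 0) return(Inf)
  if (min(vals) == max(vals)) return(max(vals) / 2)
  if (method == "percentile") return(stats::quantile(vals, percentile, names = FALSE))
  m <- max(vals)
  as.numeric(EBImage::otsu(EBImage::Image(matrix(vals / m, nrow = 1L)),
                           range = c(0, 1), levels = 256L)) * m
}

## Drop labels below a minimum pixel area and renumber the survivors 1..n in
## first-encounter (column-major scan) order, so numbering is deterministic.
.filterRelabel <- function(lab, minAreaPx) {
  lab <- as.matrix(lab)
  storage.mode(lab) <- "integer"
  if (all(lab == 0L)) return(lab)
  tab <- tabulate(lab)
  keep <- which(tab >= minAreaPx)
  lut <- integer(length(tab))
  if (length(keep)) {
    first <- vapply(keep, function(k) which(lab == k)[1L], integer(1))
    lut[keep[order(first)]] <- seq_along(keep)
  }
  out <- lab
  out[lab > 0L] <- lut[lab[lab > 0L]]
  out
}

#' Segment nuclei from the nuclear-stain channel
#'
#' Gaussian smoothing, a data-driven global threshold (Otsu by default) and
#' connected-component labelling; objects smaller than the configured minimum
#' nuclear area are removed as debris. Deterministic for fixed input and
#' configuration; an all-zero image yields an empty mask, not an error.
#'
#' @param nuclear numeric matrix, nuclear-stain intensities.
#' @param config an [AnalysisConfig-class].
#' @param pixelSize pixel size in um/pixel.
#' @return A [LabelMask-class] of kind \code{"nucleus"}.
#' @seealso [segmentCells()]
#' @export
segmentNuclei <- function(nuclear, config = analysisConfig(), pixelSize) {
  .checkRaster(nuclear, "nuclear")
  stopifnot(is(config, "AnalysisConfig"), pixelSize > 0)
  if (max(nuclear) == 0)
    return(LabelMask(matrix(0L, nrow(nuclear), ncol(nuclear)), "nucleus"))
  sigma <- max(1, 0.5 / pixelSize)  # ~0.5 um smoothing
  sm <- EBImage::imageData(EBImage::gblur(nuclear, sigma = sigma))
  thr <- .dataThreshold(as.vector(sm), config@thresholdMethod,
                        config@thresholdPercentile)
  lab <- EBImage::bwlabel(sm > thr)
  minPx <- max(1, round(config@minNucleusArea / pixelSize^2))
  LabelMask(.filterRelabel(lab, minPx), "nucleus")
}

#' Segment whole-cell territories seeded by nuclei
#'
#' Nucleus-seeded propagation (a watershed-type region growing,
#' \code{EBImage::propagate}) over a smoothed cytoplasmic raster, restricted
#' to the suprathreshold cytoplasmic support (global Otsu by default) united
#' with the nuclei. Each nucleus label grows into exactly one cell carrying
#' the same label; every supported pixel is assigned to at most one cell, and
#' each cell contains its seed nucleus entirely.
#'
#' @param nuclei a [LabelMask-class] of kind \code{"nucleus"} (the seeds).
#' @param cytoplasm numeric matrix delineating cytoplasmic support, typically
#'   a tubulin + lysosome composite co-registered with the nuclei.
#' @param config an [AnalysisConfig-class].
#' @param pixelSize pixel size in um/pixel.
#' @return A [LabelMask-class] of kind \code{"cell"} with the nuclei's
#'   numbering.
#' @export
segmentCells <- function(nuclei, cytoplasm, config = analysisConfig(),
                         pixelSize) {
  stopifnot(is(nuclei, "LabelMask"), maskKind(nuclei) == "nucleus")
  .checkRaster(cytoplasm, "cytoplasm")
  if (!identical(dim(nuclei), dim(cytoplasm)))
    stop("nuclei mask and cytoplasm raster must be co-registered (same size)",
         call. = FALSE)
  seeds <- labels(nuclei)
  if (all(seeds == 0L))
    return(LabelMask(matrix(0L, nrow(seeds), ncol(seeds)), "cell"))
  sigma <- max(1, 0.5 / pixelSize)
  sm <- EBImage::imageData(EBImage::gblur(cytoplasm, sigma = sigma))
  # fluorescence spans decades (dim cytosolic fill vs bright puncta); compute
  # the foreground/background threshold on the log scale so bright organelles
  # cannot drag it above the cytoplasmic fill
  thr <- .dataThreshold(as.vector(log1p(sm)), config@thresholdMethod,
                        config@thresholdPercentile)
  support <- (log1p(sm) > thr) | (seeds > 0L)
  lab <- EBImage::propagate(sm, seeds = seeds, mask = support)
  lab <- as.matrix(EBImage::imageData(lab))
  storage.mode(lab) <- "integer"
  LabelMask(lab, "cell")
}

#' Labels of objects touching the image border
#'
#' @param mask a [LabelMask-class].
#' @return Integer vector of labels with at least one border pixel.
#' @export
borderLabels <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  l <- labels(mask)
  edge <- c(l[1L, ], l[nrow(l), ], l[, 1L], l[, ncol(l)])
  sort(unique(edge[edge > 0L]))
}

#' Central region of each cell
#'
#' For each cell, iterative binary erosion with a 3x3 cross structuring
#' element shrinks the cell mask toward its centre; the central region is the
#' last iterate whose area is still at least \code{fraction} times the cell
#' area. The peripheral region is the cell minus its central region. With
#' \code{fraction = 1} the central region equals the cell. The achieved
#' central area lies within one erosion step above the target, by
#' construction.
#'
#' @param cells a [LabelMask-class] of kind \code{"cell"}.
#' @param fraction target central area fraction, in (0, 1].
#' @return A [LabelMask-class] of kind \code{"central"} with the cells'
#'   numbering; always a subset of \code{cells} per label.
#' @export
centralRegion <- function(cells, fraction) {
  stopifnot(is(cells, "LabelMask"), maskKind(cells) == "cell")
  if (length(fraction) != 1L || !is.finite(fraction) || fraction <= 0 ||
      fraction > 1)
    stop("fraction must be a single value in (0, 1]", call. = FALSE)
  lab <- labels(cells)
  if (fraction == 1 || all(lab == 0L))
    return(LabelMask(lab, "central"))
  kern <- EBImage::makeBrush(3L, "diamond")  # 3x3 cross
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (k in sort(unique(lab[lab > 0L]))) {
    idx <- which(lab == k, arr.ind = TRUE)
    r0 <- max(1L, min(idx[, 1L]) - 1L); r1 <- min(nrow(lab), max(idx[, 1L]) + 1L)
    c0 <- max(1L, min(idx[, 2L]) - 1L); c1 <- min(ncol(lab), max(idx[, 2L]) + 1L)
    cur <- (lab[r0:r1, c0:c1] == k) * 1
    target <- fraction * sum(cur)
    repeat {
      er <- EBImage::imageData(EBImage::erode(cur, kern))
      if (sum(er) >= target) cur <- er else break
    }
    sub <- out[r0:r1, c0:c1]
    sub[cur > 0] <- k
    out[r0:r1, c0:c1] <- sub
  }
  LabelMask(out, "central")
}
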