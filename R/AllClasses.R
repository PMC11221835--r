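#' @import methods
NULL

#' FieldImage: one multi-channel microscope field
#'
#' Container for the co-registered channel rasters of a single imaged field,
#' together with its physical pixel size and plate-well identity. Channels are
#' named by biological role (\code{"nuclear"}, \code{"tubulin"},
#' \code{"lysosome"}, optionally \code{"aggregate"}) rather than by page order,
#' so that acquisition-dependent channel ordering never leaks into analysis
#' code.
#'
#' @slot fieldId character(1), identifier of the field.
#' @slot wellId character(1), plate well the field was acquired from.
#' @slot channels named list of numeric matrices, one per channel role; all
#'   matrices share the same dimensions and hold finite, non-negative
#'   intensities.
#' @slot pixelSize numeric(1), physical pixel size in micrometres per pixel.
#'
#' @seealso [readFieldImage()], [generateField()]
#' @examples
#' fi <- FieldImage(matrix(0, 8, 8), fieldId = "f1", wellId = "A01",
#'                  pixelSize = 0.325)
#' dim(getChannel(fi, "nuclear"))
#' @export
setClass("FieldImage",
  representation(
    fieldId  = "character",
    wellId   = "character",
    channels = "list",
    pixelSize = "numeric"
  )
)

setValidity("FieldImage", function(object) {
  msg <- character()
  ch <- object@channels
  if (length(ch) == 0L)
    msg <- c(msg, "at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    msg <- c(msg, "channels must be uniquely named")
  if (!all(vapply(ch, is.matrix, logical(1))))
    msg <- c(msg, "all channels must be matrices")
  if (length(ch) > 0L && all(vapply(ch, is.matrix, logical(1)))) {
    dims <- vapply(ch, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      msg <- c(msg, "all channel rasters must share identical dimensions")
    bad <- vapply(ch, function(m) anyNA(m) || any(!is.finite(m)) || any(m < 0),
                  logical(1))
    if (any(bad))
      msg <- c(msg, sprintf("channel '%s' contains non-finite or negative intensities",
                            names(ch)[which(bad)[1L]]))
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number (um/pixel)")
  if (length(object@fieldId) != 1L) msg <- c(msg, "fieldId must be character(1)")
  if (length(object@wellId) != 1L) msg <- c(msg, "wellId must be character(1)")
  if (length(msg)) msg else TRUE
})

#' Construct a FieldImage
#'
#' @param ... named channel matrices (e.g. \code{nuclear = m1, tubulin = m2}),
#'   or a single named list of matrices.
#' @param fieldId,wellId identifiers for the field and its well.
#' @param pixelSize physical pixel size in micrometres per pixel.
#' @return A [FieldImage-class] object.
#' @export
FieldImage <- function(..., fieldId = "field", wellId = "well", pixelSize) {
  ch <- list(...)
  if (length(ch) == 1L && is.list(ch[[1L]]) && !is.matrix(ch[[1L]]))
    ch <- ch[[1L]]
  if (length(ch) >= 1L && is.null(names(ch)))
    names(ch) <- c("nuclear", "tubulin", "lysosome", "aggregate")[seq_along(ch)]
  ch <- lapply(ch, function(m) { storage.mode(m) <- "double"; m })
  new("FieldImage", fieldId = as.character(fieldId),
      wellId = as.character(wellId), channels = ch,
      pixelSize = as.numeric(pixelSize))
}

.maskKinds <- c("nucleus", "cell", "central")

#' LabelMask: labelled object raster
#'
#' An integer raster in which 0 marks background and each positive integer k
#' marks the pixels of object k. The \code{kind} records what the objects are:
#' segmented nuclei, whole-cell territories, or the central subregion of each
#' cell used to define the complementary peripheral region.
#'
#' @slot labels integer matrix of object labels (0 = background).
#' @slot kind character(1), one of \code{"nucleus"}, \code{"cell"},
#'   \code{"central"}.
#'
#' @seealso [segmentNuclei()], [segmentCells()], [centralRegion()]
#' @export
setClass("LabelMask",
  representation(labels = "matrix", kind = "character")
)

setValidity("LabelMask", function(object) {
  msg <- character()
  l <- object@labels
  if (!is.integer(l)) msg <- c(msg, "labels must be an integer matrix")
  else if (anyNA(l) || any(l < 0L)) msg <- c(msg, "labels must be non-negative integers")
  if (length(object@kind) != 1L || !object@kind %in% .maskKinds)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(sQuote(.maskKinds), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMask
#'
#' @param labels matrix of non-negative integer labels.
#' @param kind one of \code{"nucleus"}, \code{"cell"}, \code{"central"}.
#' @return A [LabelMask-class] object.
#' @export
LabelMask <- function(labels, kind) {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels, kind = match.arg(kind, .maskKinds))
}

#' AnalysisConfig: run-wide analysis parameters
#'
#' Holds every tunable parameter of the scoring pipeline in one validated
#' object. The geometric parameters are physical (micrometres) and are
#' converted to pixels through each field's own pixel size, so one
#' configuration applies across magnifications. Defaults follow the assay's
#' published constants: a 7 um measurement circle at the MTOC, a strict
#' 1.1-fold hit threshold, and a central region covering 70% of the cell area.
#'
#' @slot circleDiameter numeric(1), diameter (um) of the measurement circle
#'   centred on the MTOC. Default 7.
#' @slot hitFoldThreshold numeric(1), fold-change threshold for hit calling
#'   (strict \code{>}). Default 1.1.
#' @slot centralAreaFraction numeric(1) in (0, 1], fraction of each cell's
#'   area retained by the central region. Default 0.70.
#' @slot controlLabel character(1), compound label marking control wells.
#' @slot perWellStatistic character(1), \code{"mean"} or \code{"median"};
#'   summary used per well and for the pooled control.
#' @slot backgroundRadius numeric(1), rolling-ball radius (um) for background
#'   subtraction. Default 5.
#' @slot thresholdMethod character(1), \code{"otsu"} or \code{"percentile"};
#'   data-driven threshold used for spot and aggregate detection.
#' @slot thresholdPercentile numeric(1) in (0, 1), percentile used when
#'   \code{thresholdMethod = "percentile"}.
#' @slot peripheralIntensityFraction numeric(1) in (0, 1), fraction of a
#'   cell's lysosomal intensity that must lie outside the central region for
#'   the cell to be flagged as having peripheral lysosomes. Default 0.5.
#' @slot normPercentiles numeric(2), low/high clipping percentiles (as
#'   fractions) for intensity normalization. Default c(0.001, 0.9999).
#' @slot minNucleusArea numeric(1), minimum nucleus area in um^2; smaller
#'   objects are treated as debris.
#' @slot clipCircleToCell logical(1), whether the numerator region is
#'   circle-intersect-cell (default TRUE) or the raw circle.
#' @slot excludeNucleusFromDenominator logical(1), whether the whole-cell
#'   denominator excludes the nuclear region. Default FALSE.
#' @slot excludeBorderCells logical(1), whether cells touching the image
#'   border are excluded from scoring. Default TRUE.
#' @slot rngSeed integer(1) or NA, seed recorded with a run.
#'
#' @seealso [analysisConfig()], [readAnalysisConfig()]
#' @export
setClass("AnalysisConfig",
  representation(
    circleDiameter = "numeric",
    hitFoldThreshold = "numeric",
    centralAreaFraction = "numeric",
    controlLabel = "character",
    perWellStatistic = "character",
    backgroundRadius = "numeric",
    thresholdMethod = "character",
    thresholdPercentile = "numeric",
    peripheralIntensityFraction = "numeric",
    normPercentiles = "numeric",
    minNucleusArea = "numeric",
    clipCircleToCell = "logical",
    excludeNucleusFromDenominator = "logical",
    excludeBorderCells = "logical",
    rngSeed = "integer"
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  pos1 <- function(x) length(x) == 1L && is.finite(x) && x > 0
  if (!pos1(object@circleDiameter)) msg <- c(msg, "circleDiameter must be > 0")
  if (!pos1(object@hitFoldThreshold)) msg <- c(msg, "hitFoldThreshold must be > 0")
  if (!(pos1(object@centralAreaFraction) && object@centralAreaFraction <= 1))
    msg <- c(msg, "centralAreaFraction must be in (0, 1]")
  if (!object@perWellStatistic %in% c("mean", "median"))
    msg <- c(msg, "perWellStatistic must be 'mean' or 'median'")
  if (!pos1(object@backgroundRadius)) msg <- c(msg, "backgroundRadius must be > 0")
  if (!object@thresholdMethod %in% c("otsu", "percentile"))
    msg <- c(msg, "thresholdMethod must be 'otsu' or 'percentile'")
  if (!(pos1(object@thresholdPercentile) && object@thresholdPercentile < 1))
    msg <- c(msg, "thresholdPercentile must be in (0, 1)")
  if (!(pos1(object@peripheralIntensityFraction) &&
        object@peripheralIntensityFraction < 1))
    msg <- c(msg, "peripheralIntensityFraction must be in (0, 1)")
  np <- object@normPercentiles
  if (length(np) != 2L || any(!is.finite(np)) || any(np < 0) || any(np > 1) ||
      np[1] >= np[2])
    msg <- c(msg, "normPercentiles must be two increasing fractions in [0, 1]")
  if (!pos1(object@minNucleusArea)) msg <- c(msg, "minNucleusArea must be > 0")
  if (length(msg)) msg else TRUE
})

#' CascadeLedger: auditable record of a screening funnel
#'
#' Ordered stage records of a multi-stage screen: each stage stores its name,
#' input count, the rule applied, output count, and the identities and reasons
#' of everything excluded. Validity enforces the funnel bookkeeping: each
#' stage's input count equals the previous stage's output count, and counts
#' never increase across exclusion stages.
#'
#' @slot stages list of stage records; each a list with elements
#'   \code{stage}, \code{input}, \code{rule}, \code{output}, \code{excluded}
#'   (data.frame with columns \code{compound_id}, \code{reason}).
#'
#' @seealso [runCascade()], [writeCascadeLedger()]
#' @export
setClass("CascadeLedger", representation(stages = "list"))

setValidity("CascadeLedger", function(object) {
  st <- object@stages
  msg <- character()
  need <- c("stage", "input", "rule", "output", "excluded")
  for (i in seq_along(st)) {
    s <- st[[i]]
    if (!all(need %in% names(s))) {
      msg <- c(msg, sprintf("stage %d is missing fields", i)); next
    }
    if (s$input < 0 || s$output < 0)
      msg <- c(msg, sprintf("stage %d has negative counts", i))
    if (s$output > s$input)
      msg <- c(msg, sprintf("stage '%s': output exceeds input", s$stage))
    if (i > 1L && s$input != st[[i - 1L]]$output)
      msg <- c(msg, sprintf(
        "stage '%s': input count %d does not chain from previous output %d",
        s$stage, s$input, st[[i - 1L]]$output))
  }
  if (length(msg)) msg else TRUE
})
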