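#' Build an analysis configuration
#'
#' Constructs a validated [AnalysisConfig-class]. All geometric parameters are
#' physical (micrometres); conversion to pixels happens per field using that
#' field's pixel size. The defaults encode the assay's fixed constants: a 7 um
#' circle placed at the MTOC, a strict 1.1-fold hit threshold, and a central
#' region holding 70% of each cell's area.
#'
#' @param circleDiameter circle diameter in um (default 7).
#' @param hitFoldThreshold fold-change hit threshold, strict \code{>}
#'   (default 1.1).
#' @param centralAreaFraction target central-region area fraction in (0, 1]
#'   (default 0.70).
#' @param controlLabel compound label identifying control wells
#'   (default \code{"DMSO"}).
#' @param perWellStatistic \code{"mean"} (default) or \code{"median"}.
#' @param backgroundRadius rolling-ball background radius in um (default 5).
#' @param thresholdMethod \code{"otsu"} (default) or \code{"percentile"}.
#' @param thresholdPercentile percentile (fraction) used when
#'   \code{thresholdMethod = "percentile"} (default 0.99).
#' @param peripheralIntensityFraction intensity fraction defining a
#'   peripheral-lysosome cell (default 0.5).
#' @param normPercentiles low/high clipping percentiles for contrast
#'   normalization (default \code{c(0.001, 0.9999)}).
#' @param minNucleusArea minimum nucleus area in um^2 (default 3.2, i.e.
#'   about 30 px^2 at 0.325 um/px).
#' @param clipCircleToCell intersect the circle with the cell before
#'   measuring (default TRUE).
#' @param excludeNucleusFromDenominator drop the nuclear region from the
#'   whole-cell denominator (default FALSE; the denominator is literally the
#'   whole cell).
#' @param excludeBorderCells exclude border-touching cells (default TRUE).
#' @param rngSeed optional integer seed recorded with the run.
#' @return An [AnalysisConfig-class] object.
#' @examples
#' cfg <- analysisConfig()
#' cfg@circleDiameter      # 7 um
#' cfg@hitFoldThreshold    # 1.1
#' @export
analysisConfig <- function(circleDiameter = 7,
                           hitFoldThreshold = 1.1,
                           centralAreaFraction = 0.70,
                           controlLabel = "DMSO",
                           perWellStatistic = c("mean", "median"),
                           backgroundRadius = 5,
                           thresholdMethod = c("otsu", "percentile"),
                           thresholdPercentile = 0.99,
                           peripheralIntensityFraction = 0.5,
                           normPercentiles = c(0.001, 0.9999),
                           minNucleusArea = 3.2,
                           clipCircleToCell = TRUE,
                           excludeNucleusFromDenominator = FALSE,
                           excludeBorderCells = TRUE,
                           rngSeed = NA_integer_) {
  new("AnalysisConfig",
      circleDiameter = as.numeric(circleDiameter),
      hitFoldThreshold = as.numeric(hitFoldThreshold),
      centralAreaFraction = as.numeric(centralAreaFraction),
      controlLabel = as.character(controlLabel),
      perWellStatistic = match.arg(perWellStatistic),
      backgroundRadius = as.numeric(backgroundRadius),
      thresholdMethod = match.arg(thresholdMethod),
      thresholdPercentile = as.numeric(thresholdPercentile),
      peripheralIntensityFraction = as.numeric(peripheralIntensityFraction),
      normPercentiles = as.numeric(normPercentiles),
      minNucleusArea = as.numeric(minNucleusArea),
      clipCircleToCell = isTRUE(clipCircleToCell),
      excludeNucleusFromDenominator = isTRUE(excludeNucleusFromDenominator),
      excludeBorderCells = isTRUE(excludeBorderCells),
      rngSeed = as.integer(rngSeed))
}

.configFields <- function() names(formals(analysisConfig))

#' Read / write an analysis configuration as YAML
#'
#' The on-disk form is a flat YAML mapping of the [analysisConfig()] argument
#' names. Unknown keys are rejected so that typos never silently fall back to
#' defaults; missing keys take the documented defaults. The resolved
#' configuration can be written back so every run can log exactly what it
#' used.
#'
#' @param path path to a YAML file.
#' @return \code{readAnalysisConfig}: an [AnalysisConfig-class];
#'   \code{writeAnalysisConfig}: \code{path}, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeAnalysisConfig(analysisConfig(hitFoldThreshold = 1.2), f)
#' readAnalysisConfig(f)@hitFoldThreshold
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(vals), .configFields())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysisConfig, vals)
}

#' @rdname readAnalysisConfig
#' @param config an [AnalysisConfig-class] to serialize.
#' @export
writeAnalysisConfig <- function(config, path) {
  stopifnot(is(config, "AnalysisConfig"))
  sl <- slotNames(config)
  vals <- lapply(sl, function(s) slot(config, s))
  names(vals) <- sl
  if (is.na(vals$rngSeed)) vals$rngSeed <- NULL
  yaml::write_yaml(vals, path)
  invisible(path)
}

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  for (s in slotNames(object))
    cat(sprintf("  %-30s %s\n", s,
                paste(format(slot(object, s)), collapse = ", ")))
})
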