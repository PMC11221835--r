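## End-to-end orchestration: score a field, score a plate against its layout,
## and a self-contained synthetic demonstration run.

#' Score all cells of one field
#'
#' Runs the full per-field pipeline: nucleus segmentation, nucleus-seeded
#' cell segmentation on the tubulin + lysosome composite, MTOC detection, and
#' the per-cell in-circle clustering ratio. Cells with an undetected MTOC,
#' empty lysosomal signal or (by default) touching the image border are
#' returned as excluded records with reasons.
#'
#' @param field a [FieldImage-class] with channels \code{nuclear},
#'   \code{tubulin}, \code{lysosome}.
#' @param config an [AnalysisConfig-class].
#' @param returnMasks also attach the intermediate [LabelMask-class] objects
#'   (attributes \code{"nuclei"} and \code{"cells"}), e.g. for matching
#'   scored cells to external ground truth.
#' @return data.frame with one row per cell: \code{field_id},
#'   \code{well_id}, \code{cell_label}, \code{raw_ratio},
#'   \code{circle_area_px}, \code{cell_area_px}, \code{mtoc_row},
#'   \code{mtoc_col}, \code{excluded}, \code{reason}.
#' @export
scoreField <- function(field, config = analysisConfig(), returnMasks = FALSE) {
  stopifnot(is(field, "FieldImage"))
  px <- pixelSize(field)
  nuclear <- getChannel(field, "nuclear")
  tubulin <- getChannel(field, "tubulin")
  lysosome <- getChannel(field, "lysosome")
  nuclei <- segmentNuclei(nuclear, config, px)
  cells <- segmentCells(nuclei, tubulin + lysosome, config, px)
  border <- if (config@excludeBorderCells) borderLabels(cells) else integer()
  mtocs <- detectMtoc(tubulin, cells, config, px)
  lab <- labels(cells); nlab <- labels(nuclei)
  rows <- lapply(seq_len(nrow(mtocs)), function(i) {
    k <- mtocs$cell_label[i]
    m <- clusteringRatio(lysosome, lab == k, mtocs[i, ], config, px,
                         nucleusMask = nlab == k)
    if (!m$excluded && k %in% border) {
      m$excluded <- TRUE
      m$reason <- "border-touching cell"
    }
    m$mtoc_row <- mtocs$row[i]; m$mtoc_col <- mtocs$col[i]
    m
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_label = integer(), raw_ratio = numeric(),
                      circle_area_px = integer(), cell_area_px = integer(),
                      excluded = logical(), reason = character(),
                      mtoc_row = numeric(), mtoc_col = numeric())
  out <- cbind(data.frame(field_id = fieldId(field), well_id = wellId(field),
                          stringsAsFactors = FALSE)[rep(1L, nrow(out)), ,
                                                    drop = FALSE],
               out, row.names = NULL)
  if (returnMasks) {
    attr(out, "nuclei") <- nuclei
    attr(out, "cells") <- cells
  }
  out
}

#' Score a plate of fields against its layout
#'
#' Scores every field, pools the per-cell ratios by well, and normalizes each
#' well's statistic to the pooled control wells to give the per-well
#' lysosomal clustering value. Wells listed in the layout without any
#' supplied field are skipped with a warning; a run without any scorable
#' control cell aborts, since fold changes would be undefined. The result is
#' deterministic for fixed inputs and configuration, and exclusion counts are
#' tallied per reason.
#'
#' @param fields list of [FieldImage-class] objects; well identity is taken
#'   from each field's \code{wellId}.
#' @param layout plate layout data.frame (see [readPlateLayout()]).
#' @param config an [AnalysisConfig-class].
#' @return List with \code{cells} (per-cell table), \code{wells} (per-well
#'   table: \code{well_id}, \code{compound_id}, \code{is_control},
#'   \code{n_cells}, \code{statistic}, \code{clustering_value}),
#'   \code{exclusions} (named counts per reason), and \code{config}.
#' @export
scorePlate <- function(fields, layout, config = analysisConfig()) {
  stopifnot(is.list(fields), is.data.frame(layout),
            all(c("well_id", "compound_id", "is_control") %in% names(layout)))
  fieldWells <- vapply(fields, wellId, character(1))
  missingWells <- setdiff(layout$well_id, fieldWells)
  if (length(missingWells))
    warning("no field supplied for well(s): ",
            paste(missingWells, collapse = ", "), "; skipping them")
  stray <- setdiff(fieldWells, layout$well_id)
  if (length(stray))
    stop("field(s) reference well(s) absent from the layout: ",
         paste(stray, collapse = ", "), call. = FALSE)
  cells <- do.call(rbind, lapply(fields, scoreField, config = config))
  ok <- cells[!cells$excluded, , drop = FALSE]
  ctrlWells <- layout$well_id[layout$is_control]
  control <- ok$raw_ratio[ok$well_id %in% ctrlWells]
  if (length(control) == 0L)
    stop("no scorable cells in any control well; cannot normalize",
         call. = FALSE)
  stat <- config@perWellStatistic
  wells <- do.call(rbind, lapply(intersect(layout$well_id, fieldWells),
    function(w) {
      r <- ok$raw_ratio[ok$well_id == w]
      data.frame(well_id = w,
                 compound_id = layout$compound_id[layout$well_id == w],
                 is_control = layout$is_control[layout$well_id == w],
                 n_cells = length(r),
                 statistic = if (length(r)) .wellStat(r, stat) else NA_real_,
                 clustering_value = if (length(r))
                   clusteringValue(r, control, stat) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  excl <- table(cells$reason[cells$excluded])
  list(cells = cells, wells = wells,
       exclusions = stats::setNames(as.integer(excl), names(excl)),
       config = config)
}

#' Miniature end-to-end synthetic screen
#'
#' Generates a small screen (60 compounds, 5 planted primary hits), runs the
#' full funnel (primary call, synthetic secondary flux screen with 3 planted
#' passers, one autofluorescent exclusion), scores a two-well image plate
#' (clustered kappa = 0.8 versus dispersed control kappa = 0.2), and computes
#' a flow-cytometry fold change — all from one seed, reproducibly.
#'
#' @param seed integer seed driving every generator.
#' @param quiet suppress the printed summary.
#' @return (invisibly) list with \code{ledger} ([CascadeLedger-class]),
#'   \code{screenTruth}, \code{plate} (the [scorePlate()] result),
#'   \code{flowFoldChange}, and \code{candidates}.
#' @export
runDemo <- function(seed = 7L, quiet = FALSE) {
  seed <- as.integer(seed)
  config <- analysisConfig(rngSeed = seed)
  prim <- generateScreenTable(60, 5, seed = seed)
  primHits <- callHits(prim$table, config@hitFoldThreshold)$hits
  sec <- generateScreenTable(nrow(primHits), min(3L, nrow(primHits)),
                             seed = seed + 1L,
                             compoundIds = primHits$compound_id,
                             stage = "secondary")
  secPass <- sec$truth$compound_id[sec$truth$is_hit]
  flags <- utils::head(secPass, 1L)
  ledger <- runCascade(prim$table, sec$table, flags, config)

  mkWell <- function(kappa, well, s)
    generateField(syntheticCellSpec(clusteredFraction = kappa, seed = s),
                  fieldId = paste0(well, "_f1"), wellId = well)$field
  fields <- list(mkWell(0.2, "A01", seed + 2L), mkWell(0.8, "A02", seed + 3L))
  layout <- data.frame(well_id = c("A01", "A02"),
                       compound_id = c("DMSO", "clustering_compound"),
                       is_control = c(TRUE, FALSE))
  plate <- scorePlate(fields, layout, config)

  ctrl <- generateFlowEvents(4000, ratioMedian = 1.0, seed = seed + 4L)
  trt <- generateFlowEvents(4000, ratioMedian = 2.0, seed = seed + 5L)
  gate <- function(x) gateEvents(x$events, x$truth$dapi_max, x$truth$rfp_min)
  flowFc <- clusteringValue(rfpGfpRatio(gate(trt)$events)$ratios,
                            rfpGfpRatio(gate(ctrl)$events)$ratios, "median")

  if (!quiet) {
    show(ledger)
    cv <- plate$wells$clustering_value[plate$wells$well_id == "A02"]
    cat(sprintf("clustered well clustering value: %.3f (control = 1)\n", cv))
    cat(sprintf("flow RFP/GFP fold change (planted 2.0): %.3f\n", flowFc))
    cat("final candidates:", paste(finalCandidates(ledger), collapse = ", "),
        "\n")
  }
  invisible(list(ledger = ledger, screenTruth = prim$truth, plate = plate,
                 flowFoldChange = flowFc,
                 candidates = finalCandidates(ledger), seed = seed))
}
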