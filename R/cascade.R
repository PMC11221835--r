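## Hit calling and the multi-stage screening funnel. Control normalization
## happens upstream (clusteringValue / flow fold changes); this module
## consumes fold-change tables only and keeps an auditable ledger.

#' Call hits from a fold-change table
#'
#' A compound is a hit iff its fold change is strictly greater than the
#' threshold ("over" the threshold: boundary-equal values are non-hits).
#' Hits are returned sorted by descending fold change, ties broken by
#' compound id. Rows with non-finite fold changes are excluded with a logged
#' reason, never silently dropped. Calling is invariant to input row order.
#'
#' @param rows data.frame with columns \code{compound_id} and
#'   \code{fold_change}.
#' @param threshold positive fold-change threshold (default 1.1).
#' @return List with \code{hits} (sorted data.frame), \code{excluded}
#'   (data.frame of \code{compound_id}, \code{reason}), and
#'   \code{threshold}.
#' @examples
#' tab <- data.frame(compound_id = c("a", "b"), fold_change = c(1.15, 1.10))
#' callHits(tab, 1.1)$hits$compound_id   # "a" only: 1.10 is not over 1.1
#' @export
callHits <- function(rows, threshold = 1.1) {
  stopifnot(is.data.frame(rows),
            all(c("compound_id", "fold_change") %in% names(rows)))
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0)
    stop("threshold must be a single positive number", call. = FALSE)
  bad <- !is.finite(rows$fold_change)
  excluded <- data.frame(compound_id = as.character(rows$compound_id[bad]),
                         reason = rep("non-finite fold change", sum(bad)),
                         stringsAsFactors = FALSE)
  ok <- rows[!bad, , drop = FALSE]
  hits <- ok[ok$fold_change > threshold, , drop = FALSE]
  hits <- hits[order(-hits$fold_change, hits$compound_id), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, excluded = excluded, threshold = threshold)
}

#' Remove autofluorescent compounds from a hit list
#'
#' Autofluorescence is an annotation supplied with the screen (identified
#' empirically on the instrument), not detected from the data. Every flagged
#' id must refer to a compound in the hit table; unknown ids are a validation
#' error.
#'
#' @param hits data.frame of hits with a \code{compound_id} column.
#' @param flags character vector of autofluorescent compound ids.
#' @return List with \code{kept} (filtered hits) and \code{excluded}
#'   (data.frame of \code{compound_id}, \code{reason}).
#' @export
excludeAutofluorescent <- function(hits, flags = character()) {
  stopifnot(is.data.frame(hits), "compound_id" %in% names(hits))
  flags <- as.character(flags)
  unknown <- setdiff(flags, hits$compound_id)
  if (length(unknown))
    stop("autofluorescence flag(s) name unknown compound(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  kept <- hits[!hits$compound_id %in% flags, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       excluded = data.frame(compound_id = flags,
                             reason = rep("autofluorescent", length(flags)),
                             stringsAsFactors = FALSE))
}

.stageRecord <- function(stage, input, rule, output, excluded, kept) {
  list(stage = stage, input = as.integer(input), rule = rule,
       output = as.integer(output), excluded = excluded,
       kept = as.character(kept))
}

#' Run the screening funnel
#'
#' Chains the screen's stages into a validated [CascadeLedger-class]:
#' primary hit call, secondary (flux) hit call, autofluorescence exclusion,
#' and optionally a manual-confirmation stage whose outcome is supplied as an
#' annotation (recorded, not computed). The secondary table must cover
#' exactly the primary hits, so stage counts chain; a secondary compound
#' absent from the primary hits is a consistency error.
#'
#' @param primary data.frame of primary-screen fold changes
#'   (\code{compound_id}, \code{fold_change}).
#' @param secondary data.frame of secondary-screen fold changes for the
#'   primary hits.
#' @param flags character vector of autofluorescent compound ids (must name
#'   compounds present in \code{primary}).
#' @param config an [AnalysisConfig-class]; its \code{hitFoldThreshold} is
#'   used at both call stages.
#' @param manualConfirmed optional character vector of compounds confirmed by
#'   follow-up microscopy; when supplied, a final annotation stage is
#'   recorded.
#' @return A [CascadeLedger-class]; the surviving compounds of the last stage
#'   are available via [finalCandidates()].
#' @export
runCascade <- function(primary, secondary, flags = character(),
                       config = analysisConfig(), manualConfirmed = NULL) {
  thr <- config@hitFoldThreshold
  p <- callHits(primary, thr)
  ruleTxt <- sprintf("fold change > %s", format(thr))
  nonHits <- setdiff(primary$compound_id, p$hits$compound_id)
  ex1 <- rbind(p$excluded,
               data.frame(compound_id = as.character(nonHits),
                          reason = rep(sprintf("fold change <= %s", format(thr)),
                                       length(nonHits)),
                          stringsAsFactors = FALSE))
  st <- list(.stageRecord("primary hit call", nrow(primary), ruleTxt,
                          nrow(p$hits), ex1, p$hits$compound_id))

  extra <- setdiff(secondary$compound_id, p$hits$compound_id)
  if (length(extra))
    stop("secondary table contains compound(s) absent from the primary hits: ",
         paste(extra, collapse = ", "), call. = FALSE)
  missing <- setdiff(p$hits$compound_id, secondary$compound_id)
  if (length(missing))
    stop("secondary table is missing primary hit(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  s <- callHits(secondary, thr)
  nonHits2 <- setdiff(secondary$compound_id, s$hits$compound_id)
  ex2 <- rbind(s$excluded,
               data.frame(compound_id = as.character(nonHits2),
                          reason = rep(sprintf("RFP/GFP fold change <= %s",
                                               format(thr)), length(nonHits2)),
                          stringsAsFactors = FALSE))
  st <- c(st, list(.stageRecord("secondary hit call", nrow(secondary),
                                sprintf("RFP/GFP %s", ruleTxt),
                                nrow(s$hits), ex2, s$hits$compound_id)))

  flags <- as.character(flags)
  unknownFlag <- setdiff(flags, as.character(primary$compound_id))
  if (length(unknownFlag))
    stop("autofluorescence flag(s) name compound(s) absent from the screen: ",
         paste(unknownFlag, collapse = ", "), call. = FALSE)
  af <- excludeAutofluorescent(s$hits, intersect(flags, s$hits$compound_id))
  st <- c(st, list(.stageRecord("autofluorescence exclusion", nrow(s$hits),
                                "remove flagged autofluorescent compounds",
                                nrow(af$kept), af$excluded,
                                af$kept$compound_id)))

  if (!is.null(manualConfirmed)) {
    manualConfirmed <- as.character(manualConfirmed)
    stray <- setdiff(manualConfirmed, af$kept$compound_id)
    if (length(stray))
      stop("manual confirmation names compound(s) not in the remaining hits: ",
           paste(stray, collapse = ", "), call. = FALSE)
    notConf <- setdiff(af$kept$compound_id, manualConfirmed)
    ex4 <- data.frame(compound_id = notConf,
                      reason = rep("not confirmed by follow-up microscopy",
                                   length(notConf)),
                      stringsAsFactors = FALSE)
    st <- c(st, list(.stageRecord("manual confirmation (annotated)",
                                  nrow(af$kept), "supplied annotation",
                                  length(manualConfirmed), ex4,
                                  manualConfirmed)))
  }
  new("CascadeLedger", stages = st)
}

#' Compounds surviving the last cascade stage
#'
#' @param ledger a [CascadeLedger-class].
#' @return Character vector of compound ids.
#' @export
finalCandidates <- function(ledger) {
  stopifnot(is(ledger, "CascadeLedger"))
  st <- stages(ledger)
  if (length(st) == 0L) return(character())
  st[[length(st)]]$kept
}

#' Serialize a cascade ledger to JSON
#'
#' @param ledger a [CascadeLedger-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCascadeLedger <- function(ledger, path) {
  stopifnot(is(ledger, "CascadeLedger"))
  jsonlite::write_json(list(stages = stages(ledger)), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
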