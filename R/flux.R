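## Autophagic-flux readouts: flow-cytometry RFP/GFP ratios with live-cell
## gating, and band-ratio densitometry (HaloTag processing, LC3-II,
## Triton-insoluble fractions). Event input is a plain table of per-event
## intensities; gate thresholds are always explicit configuration.

.checkEvents <- function(events) {
  stopifnot(is.data.frame(events))
  need <- c("gfp", "rfp", "dapi")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("event table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in need) {
    v <- events[[col]]
    if (anyNA(v) || any(!is.finite(v)) || any(v < 0))
      stop("event column '", col, "' must be finite and >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Gate flow-cytometry events
#'
#' Live-cell gating on the DAPI channel (dead cells stain above
#' \code{dapiMax}) and RFP-positivity gating (\code{rfp >= rfpMin}).
#' Categories are assigned in that order so the counts partition the input:
#' \code{kept + dead + rfp_negative = total}.
#'
#' @param events data.frame with columns \code{gfp}, \code{rfp}, \code{dapi}.
#' @param dapiMax maximum DAPI intensity of a live cell.
#' @param rfpMin minimum RFP intensity of an RFP-positive cell.
#' @return List with \code{events} (the gated subset) and \code{counts}
#'   (named: total, kept, dead, rfp_negative).
#' @export
gateEvents <- function(events, dapiMax, rfpMin) {
  .checkEvents(events)
  stopifnot(is.finite(dapiMax), is.finite(rfpMin))
  dead <- events$dapi > dapiMax
  rfpNeg <- !dead & events$rfp < rfpMin
  keep <- !dead & !rfpNeg
  if (!any(keep))
    warning("no events pass the gates; downstream ratios will be missing")
  list(events = events[keep, , drop = FALSE],
       counts = c(total = nrow(events), kept = sum(keep), dead = sum(dead),
                  rfp_negative = sum(rfpNeg)))
}

#' Per-sample RFP/GFP ratio
#'
#' Computes the per-event red/green ratio on gated events and summarizes it
#' with the configured statistic (median by default, robust to the heavy
#' right tail of ratios). Events with zero GFP are excluded and counted.
#' Fold change versus a control sample follows the same stat-and-divide
#' contract as the clustering value: use [clusteringValue()] on the returned
#' ratio vectors.
#'
#' @param events gated event data.frame (see [gateEvents()]).
#' @param statistic \code{"median"} (default) or \code{"mean"}.
#' @return List with \code{value} (the summary; \code{NA} with a warning if
#'   no valid event), \code{ratios} (per-event ratios), \code{n}, and
#'   \code{excluded_zero_gfp}.
#' @export
rfpGfpRatio <- function(events, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  .checkEvents(events)
  valid <- events$gfp > 0
  ratios <- events$rfp[valid] / events$gfp[valid]
  if (length(ratios) == 0L) {
    warning("no events with positive GFP; RFP/GFP ratio is missing")
    return(list(value = NA_real_, ratios = numeric(),
                n = 0L, excluded_zero_gfp = sum(!valid)))
  }
  list(value = .wellStat(ratios, statistic), ratios = ratios,
       n = length(ratios), excluded_zero_gfp = sum(!valid))
}

#' HaloTag processing ratio
#'
#' Fraction of ligand-labelled HaloTag liberated from the HaloTag-LC3B
#' fusion inside lysosomes: \code{100 * halo / (halo + haloLc3b)}, the
#' free-Halo band intensity normalized by the sum of both band intensities
#' and expressed on a 0-100 scale. Vectorized over samples; a zero band sum
#' yields a missing value with a warning.
#'
#' @param halo intensity of the free (processed) HaloTag band.
#' @param haloLc3b intensity of the intact HaloTag-LC3B band.
#' @return Numeric vector in [0, 100].
#' @examples
#' haloProcessingRatio(30, 70)  # 30
#' @export
haloProcessingRatio <- function(halo, haloLc3b) {
  stopifnot(length(halo) == length(haloLc3b))
  if (any(!is.finite(halo)) || any(!is.finite(haloLc3b)) ||
      any(halo < 0) || any(haloLc3b < 0))
    stop("band intensities must be finite and >= 0", call. = FALSE)
  denom <- halo + haloLc3b
  out <- ifelse(denom > 0, 100 * halo / denom, NA_real_)
  if (anyNA(out))
    warning("zero band sum in ", sum(is.na(out)),
            " sample(s); ratio is missing there")
  out
}

#' Densitometric band ratio
#'
#' Plain numerator/denominator band-intensity ratio, the generic operation
#' behind LC3-II / loading-control and insoluble / soluble fraction
#' quantifications. Vectorized; a non-positive denominator yields a missing
#' value with a warning.
#'
#' @param numerator,denominator non-negative band intensities of equal
#'   length.
#' @return Numeric vector of ratios.
#' @export
bandRatio <- function(numerator, denominator) {
  stopifnot(length(numerator) == length(denominator))
  if (any(!is.finite(numerator)) || any(numerator < 0))
    stop("numerator band intensities must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(denominator)) || any(denominator < 0))
    stop("denominator band intensities must be finite and >= 0", call. = FALSE)
  out <- ifelse(denominator > 0, numerator / denominator, NA_real_)
  if (anyNA(out))
    warning("zero denominator in ", sum(is.na(out)),
            " sample(s); ratio is missing there")
  out
}
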