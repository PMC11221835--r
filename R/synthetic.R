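## Synthetic-data generators with ground truth: multi-channel cell fields
## with a parametric clustered fraction of lysosomal puncta, screen tables
## with planted hits, and flow-cytometry event tables. Every generator is a
## pure function of (specification, seed).

## Run expr under a temporary RNG seed, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## Area of the intersection of two discs with radii r1, r2 at distance d.
.lensArea <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - a3
}

## Add a truncated isotropic Gaussian spot to an image in place.
.addSpot <- function(img, center, sigma, amplitude, truncate = 3) {
  t2 <- (truncate * sigma)^2
  r0 <- max(1L, floor(center[1L] - truncate * sigma))
  r1 <- min(nrow(img), ceiling(center[1L] + truncate * sigma))
  c0 <- max(1L, floor(center[2L] - truncate * sigma))
  c1 <- min(ncol(img), ceiling(center[2L] + truncate * sigma))
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - center[1L])^2, (cols - center[2L])^2, `+`)
  img[rows, cols] <- img[rows, cols] +
    amplitude * exp(-d2 / (2 * sigma^2)) * (d2 <= t2)
  img
}

.diskIdx <- function(dims, center, radius) {
  r0 <- max(1L, floor(center[1L] - radius)); r1 <- min(dims[1L], ceiling(center[1L] + radius))
  c0 <- max(1L, floor(center[2L] - radius)); c1 <- min(dims[2L], ceiling(center[2L] + radius))
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - center[1L])^2, (cols - center[2L])^2, `+`)
  sel <- which(d2 <= radius^2, arr.ind = TRUE)
  cbind(rows[sel[, 1L]], cols[sel[, 2L]])
}

#' Specification of a synthetic cell field
#'
#' Geometry, signal and noise parameters of one generated field. Cells are
#' non-overlapping discs on a jittered grid; each carries a nuclear disc, a
#' single bright MTOC spot offset from the nucleus edge, and \code{nPuncta}
#' lysosomal puncta of which a fraction \code{clusteredFraction} (kappa) is
#' placed uniformly inside the measurement circle around the MTOC and the
#' rest uniformly across the cytoplasm (so a dispersed punctum can still fall
#' inside the circle by chance, with probability equal to the circle's
#' cytoplasmic area fraction). Puncta are isotropic Gaussians rendered with
#' compact (3 sigma) support, and all puncta footprints are kept inside
#' their compartment so the planted geometry is exactly recoverable. The
#' tubulin channel carries a dim diffuse cytosolic fill in addition to the
#' MTOC spot, as a GFP-tagged tubulin construct does, which also provides
#' the cytoplasmic support used by cell segmentation.
#'
#' @slot imageSize integer(2), (rows, cols) in px.
#' @slot pixelSize um/pixel (default 0.325, a typical 20x high-content
#'   setup, making the 7 um circle about 21.5 px across).
#' @slot nCells number of cells.
#' @slot cellRadius,cellRadiusJitter cell disc radius and its uniform jitter
#'   (um).
#' @slot nucleusRadius nuclear disc radius (um).
#' @slot mtocOffset distance of the MTOC from the nucleus edge (um).
#' @slot nPuncta lysosomal puncta per cell.
#' @slot clusteredFraction kappa in [0, 1].
#' @slot punctumSigma punctum Gaussian sigma (um).
#' @slot punctumAmplitude,nuclearAmplitude,tubulinAmplitude,cytoplasmFill
#'   signal amplitudes (arbitrary camera units).
#' @slot baseline constant offset added to every channel.
#' @slot photonNoise apply Poisson noise to the rendered signal.
#' @slot readNoiseSd Gaussian read-noise standard deviation.
#' @slot circleDiameter measurement-circle diameter (um) used for planting.
#' @slot seed integer RNG seed.
#' @seealso [syntheticCellSpec()], [generateField()]
#' @export
setClass("SyntheticCellSpec",
  representation(
    imageSize = "integer", pixelSize = "numeric", nCells = "integer",
    cellRadius = "numeric", cellRadiusJitter = "numeric",
    nucleusRadius = "numeric", mtocOffset = "numeric", nPuncta = "integer",
    clusteredFraction = "numeric", punctumSigma = "numeric",
    punctumAmplitude = "numeric", nuclearAmplitude = "numeric",
    tubulinAmplitude = "numeric", cytoplasmFill = "numeric",
    baseline = "numeric", photonNoise = "logical", readNoiseSd = "numeric",
    circleDiameter = "numeric", seed = "integer"
  )
)

setValidity("SyntheticCellSpec", function(object) {
  msg <- character()
  if (object@clusteredFraction < 0 || object@clusteredFraction > 1)
    msg <- c(msg, "clusteredFraction must be in [0, 1]")
  geom <- c(object@pixelSize, object@cellRadius, object@nucleusRadius,
            object@punctumSigma, object@circleDiameter)
  if (any(!is.finite(geom)) || any(geom <= 0))
    msg <- c(msg, "all geometry parameters must be positive")
  if (object@mtocOffset < 0 || object@cellRadiusJitter < 0 ||
      object@readNoiseSd < 0 || object@baseline < 0)
    msg <- c(msg, "mtocOffset, cellRadiusJitter, readNoiseSd and baseline must be >= 0")
  reach <- object@nucleusRadius + object@mtocOffset + object@circleDiameter / 2
  if (reach > object@cellRadius - object@cellRadiusJitter)
    msg <- c(msg, sprintf(
      "measurement circle (reach %.2f um) must fit inside the smallest cell (%.2f um); shrink nucleusRadius/mtocOffset or enlarge cellRadius",
      reach, object@cellRadius - object@cellRadiusJitter))
  if (length(msg)) msg else TRUE
})

#' Build a synthetic field specification
#'
#' @param imageSize integer(2) image size in px.
#' @param pixelSize um/pixel.
#' @param nCells number of cells to plant.
#' @param cellRadius,cellRadiusJitter,nucleusRadius,mtocOffset geometry (um).
#' @param nPuncta puncta per cell.
#' @param clusteredFraction kappa in [0, 1].
#' @param punctumSigma punctum sigma (um).
#' @param punctumAmplitude,nuclearAmplitude,tubulinAmplitude,cytoplasmFill
#'   signal amplitudes.
#' @param baseline constant channel offset.
#' @param photonNoise logical, Poisson noise on the signal.
#' @param readNoiseSd Gaussian read noise sd.
#' @param circleDiameter measurement circle diameter (um).
#' @param seed integer seed.
#' @return A [SyntheticCellSpec-class].
#' @export
syntheticCellSpec <- function(imageSize = c(240L, 240L), pixelSize = 0.325,
                              nCells = 8L, cellRadius = 8,
                              cellRadiusJitter = 0.4, nucleusRadius = 2.5,
                              mtocOffset = 1.0, nPuncta = 40L,
                              clusteredFraction = 0.2, punctumSigma = 0.3,
                              punctumAmplitude = 400, nuclearAmplitude = 600,
                              tubulinAmplitude = 1200, cytoplasmFill = 60,
                              baseline = 0, photonNoise = TRUE,
                              readNoiseSd = 2, circleDiameter = 7,
                              seed = 1L) {
  new("SyntheticCellSpec",
      imageSize = as.integer(imageSize), pixelSize = as.numeric(pixelSize),
      nCells = as.integer(nCells), cellRadius = as.numeric(cellRadius),
      cellRadiusJitter = as.numeric(cellRadiusJitter),
      nucleusRadius = as.numeric(nucleusRadius),
      mtocOffset = as.numeric(mtocOffset), nPuncta = as.integer(nPuncta),
      clusteredFraction = as.numeric(clusteredFraction),
      punctumSigma = as.numeric(punctumSigma),
      punctumAmplitude = as.numeric(punctumAmplitude),
      nuclearAmplitude = as.numeric(nuclearAmplitude),
      tubulinAmplitude = as.numeric(tubulinAmplitude),
      cytoplasmFill = as.numeric(cytoplasmFill),
      baseline = as.numeric(baseline), photonNoise = isTRUE(photonNoise),
      readNoiseSd = as.numeric(readNoiseSd),
      circleDiameter = as.numeric(circleDiameter), seed = as.integer(seed))
}

#' Generate one synthetic field with ground truth
#'
#' Renders the nuclear, tubulin and lysosome channels of a field laid out on
#' a jittered grid (a generation error suggests a larger image when the
#' requested cells cannot fit without overlap), applies Poisson and Gaussian
#' noise last, and returns the field together with a complete truth record:
#' per-cell masks and geometry, the MTOC position, every punctum's position
#' and in-circle flag, the cytoplasmic circle-area fraction used by the
#' analytic expectation kappa + (1 - kappa) * a, and the noise-free in-circle
#' intensity fraction. A fixed seed gives bit-identical output.
#'
#' @param spec a [SyntheticCellSpec-class].
#' @param fieldId,wellId identifiers for the generated [FieldImage-class].
#' @return List with \code{field} (a [FieldImage-class]) and \code{truth}
#'   (list: \code{cells} data.frame, \code{puncta} data.frame,
#'   \code{cellMask} and \code{nucleusMask} [LabelMask-class] objects,
#'   \code{seed}).
#' @export
generateField <- function(spec, fieldId = "synthetic", wellId = "well") {
  stopifnot(is(spec, "SyntheticCellSpec"))
  validObject(spec)
  .withSeed(spec@seed, {
    px <- spec@pixelSize
    H <- spec@imageSize[1L]; W <- spec@imageSize[2L]
    maxRpx <- (spec@cellRadius + spec@cellRadiusJitter) / px
    slot <- ceiling(2 * maxRpx + 4)
    nx <- W %/% slot; ny <- H %/% slot
    if (spec@nCells > nx * ny)
      stop(sprintf(
        "cannot place %d non-overlapping cells in a %dx%d image (capacity %d); use a larger image",
        spec@nCells, H, W, nx * ny), call. = FALSE)
    sigmaPx <- spec@punctumSigma / px
    margin <- 3 * sigmaPx + 1
    ccr <- spec@circleDiameter / 2 / px
    nucR <- spec@nucleusRadius / px
    mtocD <- (spec@nucleusRadius + spec@mtocOffset) / px
    if (ccr - margin <= 0)
      stop("punctumSigma too large: puncta cannot fit inside the measurement circle",
           call. = FALSE)
    if ((spec@cellRadius - spec@cellRadiusJitter) / px - margin <= nucR)
      stop("cell too small: no cytoplasmic room for puncta outside the nucleus",
           call. = FALSE)

    nuclear <- tubulin <- lysosome <- matrix(0, H, W)
    cellLab <- nucLab <- matrix(0L, H, W)
    cellRows <- vector("list", spec@nCells)
    punctaRows <- vector("list", spec@nCells)

    for (k in seq_len(spec@nCells)) {
      gi <- (k - 1L) %/% nx; gj <- (k - 1L) %% nx
      rPx <- (spec@cellRadius + stats::runif(1, -1, 1) * spec@cellRadiusJitter) / px
      slack <- max(slot / 2 - rPx - 1, 0)
      center <- c(gi * slot + slot / 2, gj * slot + slot / 2) +
        stats::runif(2, -1, 1) * slack
      cellIdx <- .diskIdx(c(H, W), center, rPx)
      nucIdx <- .diskIdx(c(H, W), center, nucR)
      cellLab[cellIdx] <- k
      nucLab[nucIdx] <- k
      theta <- stats::runif(1, 0, 2 * pi)
      mtoc <- center + mtocD * c(cos(theta), sin(theta))

      tubulin[cellIdx] <- tubulin[cellIdx] + spec@cytoplasmFill
      nuclear[nucIdx] <- nuclear[nucIdx] + spec@nuclearAmplitude
      tubulin <- .addSpot(tubulin, mtoc, max(0.25 / px, 0.8),
                          spec@tubulinAmplitude)

      n <- spec@nPuncta
      clustered <- stats::runif(n) < spec@clusteredFraction
      pos <- matrix(NA_real_, n, 2L)
      for (i in seq_len(n)) {
        rmax <- if (clustered[i]) ccr - margin else rPx - margin
        orig <- if (clustered[i]) mtoc else center
        repeat {
          rr <- sqrt(stats::runif(1)) * rmax
          th <- stats::runif(1, 0, 2 * pi)
          p <- orig + rr * c(cos(th), sin(th))
          if (sqrt(sum((p - center)^2)) > nucR) break  # keep out of nucleus
        }
        pos[i, ] <- p
        lysosome <- .addSpot(lysosome, p, sigmaPx, spec@punctumAmplitude)
      }
      inCircle <- sqrt((pos[, 1L] - mtoc[1L])^2 + (pos[, 2L] - mtoc[2L])^2) <= ccr
      punctaRows[[k]] <- data.frame(cell_label = k, row = pos[, 1L],
                                    col = pos[, 2L], clustered = clustered,
                                    in_circle = inCircle)

      # analytic circle-to-cytoplasm area fraction of the dispersed domain:
      # (circle ^ placement disc) minus (circle ^ nucleus), over the annulus
      domR <- rPx - margin
      aFrac <- (.lensArea(ccr, domR, mtocD) - .lensArea(ccr, nucR, mtocD)) /
        (pi * (domR^2 - nucR^2))
      circIdx <- .diskIdx(c(H, W), mtoc, ccr)
      circSel <- cellLab[circIdx] == k
      inCircMass <- sum(lysosome[circIdx[circSel, , drop = FALSE]])
      totMass <- sum(lysosome[cellLab == k])
      cellRows[[k]] <- data.frame(
        cell_label = k, row = center[1L], col = center[2L],
        radius_px = rPx, nucleus_radius_px = nucR,
        mtoc_row = mtoc[1L], mtoc_col = mtoc[2L], a_fraction = aFrac,
        in_circle_intensity_fraction = if (totMass > 0) inCircMass / totMass else NA_real_,
        n_puncta = n, n_clustered = sum(clustered))
    }

    addNoise <- function(img) {
      img <- img + spec@baseline
      if (spec@photonNoise)
        img <- matrix(stats::rpois(length(img), img), nrow(img), ncol(img))
      if (spec@readNoiseSd > 0)
        img <- img + stats::rnorm(length(img), 0, spec@readNoiseSd)
      pmax(img, 0)
    }
    field <- FieldImage(nuclear = addNoise(nuclear),
                        tubulin = addNoise(tubulin),
                        lysosome = addNoise(lysosome),
                        fieldId = fieldId, wellId = wellId, pixelSize = px)
    list(field = field,
         truth = list(cells = do.call(rbind, cellRows),
                      puncta = do.call(rbind, punctaRows),
                      cellMask = LabelMask(cellLab, "cell"),
                      nucleusMask = LabelMask(nucLab, "nucleus"),
                      seed = spec@seed))
  })
}

#' Generate a screen table with planted hits
#'
#' Per-compound fold changes emulating a primary (or secondary) screen:
#' non-hits are centred at 1 with Gaussian noise, planted hits sit above the
#' threshold by at least \code{hitMargin} (an exponential effect-size tail on
#' top of the guaranteed margin). Ground-truth labels are returned alongside.
#'
#' @param nCompounds number of compounds.
#' @param nPlantedHits number of planted hits (\code{<= nCompounds}).
#' @param threshold hit threshold the planting is anchored to (default 1.1).
#' @param hitMargin guaranteed margin of planted hits above the threshold
#'   (default 0.05; must be positive, otherwise the effect distribution
#'   cannot separate hits and the call is rejected).
#' @param effectScale mean of the exponential effect-size tail (default
#'   0.15).
#' @param controlNoiseSd Gaussian noise sd on fold changes (default 0.01).
#' @param seed integer seed.
#' @param compoundIds optional character vector of ids (default
#'   \code{C0001...}).
#' @param stage stage tag stored in the table (default \code{"primary"}).
#' @return List with \code{table} (data.frame \code{compound_id},
#'   \code{fold_change}, \code{stage}) and \code{truth} (data.frame
#'   \code{compound_id}, \code{is_hit}).
#' @export
generateScreenTable <- function(nCompounds, nPlantedHits, threshold = 1.1,
                                hitMargin = 0.05, effectScale = 0.15,
                                controlNoiseSd = 0.01, seed = 1L,
                                compoundIds = NULL, stage = "primary") {
  stopifnot(nCompounds >= 0, nPlantedHits >= 0)
  if (nPlantedHits > nCompounds)
    stop("nPlantedHits must not exceed nCompounds", call. = FALSE)
  if (nPlantedHits > 0 && hitMargin <= 0)
    stop("infeasible effect distribution: hitMargin must be positive so planted hits exceed the threshold",
         call. = FALSE)
  if (is.null(compoundIds))
    compoundIds <- sprintf("C%04d", seq_len(nCompounds))
  stopifnot(length(compoundIds) == nCompounds)
  .withSeed(seed, {
    isHit <- rep(FALSE, nCompounds)
    if (nPlantedHits > 0)
      isHit[sample.int(nCompounds, nPlantedHits)] <- TRUE
    fold <- 1 + stats::rnorm(nCompounds, 0, controlNoiseSd)
    if (any(isHit)) {
      n <- sum(isHit)
      f <- threshold + hitMargin + stats::rexp(n, 1 / effectScale) +
        stats::rnorm(n, 0, controlNoiseSd)
      fold[isHit] <- pmax(f, threshold + hitMargin)
    }
    list(table = data.frame(compound_id = compoundIds, fold_change = fold,
                            stage = stage, stringsAsFactors = FALSE),
         truth = data.frame(compound_id = compoundIds, is_hit = isHit,
                            stringsAsFactors = FALSE))
  })
}

#' Generate flow-cytometry events with planted gating truth
#'
#' Event table with exact planted counts of dead cells (DAPI above the gate)
#' and RFP-negative cells (RFP below the gate), and a log-normal RFP/GFP
#' ratio distribution with the requested median on the live RFP-positive
#' events.
#'
#' @param nEvents number of events (the cytometer acquisition count,
#'   e.g. 10000).
#' @param deadFraction fraction of dead (DAPI-high) events.
#' @param rfpNegativeFraction fraction of RFP-negative events among the
#'   live ones.
#' @param ratioMedian planted median RFP/GFP ratio of gated events.
#' @param ratioSdLog log-scale sd of the ratio distribution (default 0.4).
#' @param dapiMax,rfpMin the gates the planting is anchored to.
#' @param seed integer seed.
#' @return List with \code{events} (data.frame \code{gfp}, \code{rfp},
#'   \code{dapi}) and \code{truth} (list with planted counts, gates and
#'   median).
#' @export
generateFlowEvents <- function(nEvents, deadFraction = 0.08,
                               rfpNegativeFraction = 0.05, ratioMedian = 1.0,
                               ratioSdLog = 0.4, dapiMax = 100, rfpMin = 100,
                               seed = 1L) {
  stopifnot(nEvents >= 0,
            deadFraction >= 0, deadFraction <= 1,
            rfpNegativeFraction >= 0, rfpNegativeFraction <= 1)
  .withSeed(seed, {
    nDead <- round(nEvents * deadFraction)
    nNeg <- round((nEvents - nDead) * rfpNegativeFraction)
    nKept <- nEvents - nDead - nNeg
    status <- sample(rep(c("dead", "rfp_negative", "kept"),
                         c(nDead, nNeg, nKept)))
    gfp <- stats::rlnorm(nEvents, log(2000), 0.25)
    rfp <- numeric(nEvents); dapi <- numeric(nEvents)
    dead <- status == "dead"
    neg <- status == "rfp_negative"
    kept <- status == "kept"
    dapi[dead] <- dapiMax * (1.5 + stats::rexp(sum(dead)))
    dapi[!dead] <- stats::runif(sum(!dead), 0, 0.5 * dapiMax)
    rfp[dead] <- stats::rlnorm(sum(dead), log(500), 0.5)
    rfp[neg] <- stats::runif(sum(neg), 0, 0.9 * rfpMin)
    ratio <- stats::rlnorm(sum(kept), log(ratioMedian), ratioSdLog)
    rk <- ratio * gfp[kept]
    while (any(rk < rfpMin)) {     # keep planted positives above the gate
      i <- rk < rfpMin
      ratio[i] <- stats::rlnorm(sum(i), log(ratioMedian), ratioSdLog)
      gfp[kept][i] <- stats::rlnorm(sum(i), log(2000), 0.25)
      rk <- ratio * gfp[kept]
    }
    rfp[kept] <- rk
    list(events = data.frame(gfp = gfp, rfp = rfp, dapi = dapi),
         truth = list(n_dead = nDead, n_rfp_negative = nNeg, n_kept = nKept,
                      dapi_max = dapiMax, rfp_min = rfpMin,
                      ratio_median = ratioMedian))
  })
}
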