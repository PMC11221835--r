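#' Read a multi-page TIFF field
#'
#' Reads one microscope field from a multi-page TIFF and maps pages to named
#' channel roles. Integer rasters are read losslessly (no rescaling to
#' [0, 1]); channel roles always come from \code{channelMap}, never from page
#' order.
#'
#' @param path path to a multi-page TIFF file.
#' @param channelMap named integer vector mapping channel role to page index,
#'   e.g. \code{c(nuclear = 1, tubulin = 2, lysosome = 3)}.
#' @param pixelSize physical pixel size in um/pixel (mandatory; the
#'   measurement circle is physical).
#' @param fieldId,wellId identifiers stored on the returned object; default
#'   \code{fieldId} is the file name.
#' @return A [FieldImage-class].
#' @examples
#' f <- tempfile(fileext = ".tif")
#' writeFieldImage(FieldImage(nuclear = matrix(1:16, 4, 4), pixelSize = 0.325), f)
#' fi <- readFieldImage(f, c(nuclear = 1), pixelSize = 0.325)
#' @export
readFieldImage <- function(path, channelMap, pixelSize,
                           fieldId = basename(path), wellId = "well") {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  if (is.null(names(channelMap)) || any(!nzchar(names(channelMap))))
    stop("channelMap must be a named vector of page indices", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bad <- channelMap[channelMap < 1L | channelMap > length(pages)]
  if (length(bad))
    stop(sprintf("page index %d (channel '%s') out of range: file has %d page(s)",
                 bad[1L], names(bad)[1L], length(pages)), call. = FALSE)
  ch <- lapply(seq_along(channelMap), function(i) {
    p <- pages[[channelMap[i]]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] != 1L)
        stop(sprintf("page %d (channel '%s') has %d samples per pixel; expected grayscale",
                     channelMap[i], names(channelMap)[i], dim(p)[3L]),
             call. = FALSE)
      p <- p[, , 1L]
    }
    p
  })
  names(ch) <- names(channelMap)
  d <- vapply(ch, dim, integer(2))
  if (any(d[1, ] != d[1, 1]) || any(d[2, ] != d[2, 1])) {
    off <- which(d[1, ] != d[1, 1] | d[2, ] != d[2, 1])[1L]
    stop(sprintf("page %d (channel '%s') is %dx%d but page %d is %dx%d: mismatched page shapes",
                 channelMap[off], names(channelMap)[off], d[1, off], d[2, off],
                 channelMap[1L], d[1, 1], d[2, 1]), call. = FALSE)
  }
  FieldImage(ch, fieldId = fieldId, wellId = wellId, pixelSize = pixelSize)
}

#' Write a FieldImage to a multi-page TIFF
#'
#' Channels are written in their stored order, one page per channel, as
#' unsigned integers of the requested bit depth. Integer-valued rasters that
#' fit the bit depth round-trip bit-identically through [readFieldImage()].
#'
#' @param field a [FieldImage-class].
#' @param path output path.
#' @param bitsPerSample 8 or 16 (default 16).
#' @return Named integer vector mapping channel role to page index, invisibly.
#' @export
writeFieldImage <- function(field, path, bitsPerSample = 16L) {
  stopifnot(is(field, "FieldImage"))
  if (!bitsPerSample %in% c(8L, 16L))
    stop("bitsPerSample must be 8 or 16", call. = FALSE)
  mx <- 2^bitsPerSample - 1
  pages <- lapply(field@channels, function(m) {
    if (any(m > mx) || any(m != round(m)))
      stop("channel values must be integers in [0, ", mx,
           "] for ", bitsPerSample, "-bit output", call. = FALSE)
    m / mx
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample)
  invisible(stats::setNames(seq_along(pages), names(field@channels)))
}

#' Read a plate layout
#'
#' Reads the well-to-treatment map of one plate from CSV (or YAML with a
#' top-level \code{wells} list). Required columns: \code{well_id},
#' \code{compound_id}, \code{is_control}; optional: \code{concentration},
#' \code{concentration_units}, \code{autofluorescent}. Duplicate wells are a
#' validation error, and a plate without any control well is a configuration
#' error: fold changes are undefined without a control.
#'
#' @param path path to a CSV or YAML layout file.
#' @return A data.frame with one row per well and logical
#'   \code{is_control} / \code{autofluorescent} columns.
#' @export
readPlateLayout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    if (is.list(y) && !is.null(y$wells)) y <- y$wells
    df <- do.call(rbind, lapply(y, function(w) as.data.frame(w, stringsAsFactors = FALSE)))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("well_id", "compound_id", "is_control")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("layout is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$is_control <- .asFlag(df$is_control, "is_control")
  if ("autofluorescent" %in% names(df))
    df$autofluorescent <- .asFlag(df$autofluorescent, "autofluorescent")
  else df$autofluorescent <- FALSE
  dup <- df$well_id[duplicated(df$well_id)]
  if (length(dup))
    stop("duplicated well_id(s) in layout: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (!any(df$is_control))
    stop("layout has no control well (is_control); at least one is required",
         call. = FALSE)
  df
}

.asFlag <- function(x, what) {
  if (is.logical(x)) return(!is.na(x) & x)
  if (is.numeric(x)) return(!is.na(x) & x != 0)
  x <- tolower(trimws(as.character(x)))
  ok <- x %in% c("true", "false", "t", "f", "1", "0", "yes", "no", "")
  if (!all(ok))
    stop("column '", what, "' has non-boolean value(s): ",
         paste(unique(x[!ok]), collapse = ", "), call. = FALSE)
  x %in% c("true", "t", "1", "yes")
}

#' Write / read a measurement table as CSV
#'
#' CSV round-trip for homogeneous record tables (per-cell measurements,
#' per-well summaries, screen tables). Numeric values are serialized at full
#' double precision (15 significant digits); \code{NA}/\code{NaN} are written
#' as empty cells and read back as missing. An empty table yields a
#' header-only file.
#'
#' @param rows a data.frame of homogeneous records.
#' @param path output (input) CSV path.
#' @return \code{writeTable}: \code{path} invisibly; \code{readTable}: a
#'   data.frame.
#' @export
writeTable <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- vapply(out[[j]], function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 15L),
        character(1))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write table to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, blank.lines.skip = FALSE)
}
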