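#' @rdname FieldImage-class
#' @export
setMethod("fieldId", "FieldImage", function(x) x@fieldId)

#' @rdname FieldImage-class
#' @export
setMethod("wellId", "FieldImage", function(x) x@wellId)

#' @rdname FieldImage-class
#' @export
setMethod("channelNames", "FieldImage", function(x) names(x@channels))

#' @rdname FieldImage-class
#' @export
setMethod("getChannel", "FieldImage", function(x, channel) {
  if (!channel %in% names(x@channels))
    stop("no channel '", channel, "' in field '", x@fieldId, "'; available: ",
         paste(names(x@channels), collapse = ", "), call. = FALSE)
  x@channels[[channel]]
})

#' @rdname FieldImage-class
#' @export
setMethod("pixelSize", "FieldImage", function(x) x@pixelSize)

#' @export
#' @rdname FieldImage-class
setMethod("dim", "FieldImage", function(x) dim(x@channels[[1L]]))

setMethod("show", "FieldImage", function(object) {
  d <- dim(object)
  cat("FieldImage '", object@fieldId, "' (well ", object@wellId, ")\n",
      "  ", d[1L], " x ", d[2L], " px, ", format(object@pixelSize),
      " um/px\n  channels: ", paste(names(object@channels), collapse = ", "),
      "\n", sep = "")
})

#' @rdname LabelMask-class
#' @export
setMethod("maskKind", "LabelMask", function(x) x@kind)

#' @rdname LabelMask-class
#' @export
setMethod("nObjects", "LabelMask", function(x) {
  u <- unique(as.integer(x@labels))
  sum(u > 0L)
})

#' @rdname LabelMask-class
#' @export
setMethod("labels", "LabelMask", function(object, ...) object@labels)

#' @rdname LabelMask-class
#' @export
setMethod("dim", "LabelMask", function(x) dim(x@labels))

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@labels)
  cat("LabelMask (", object@kind, "): ", d[1L], " x ", d[2L], " px, ",
      nObjects(object), " object(s)\n", sep = "")
})

#' @rdname CascadeLedger-class
#' @export
setMethod("stages", "CascadeLedger", function(x) x@stages)

#' @rdname CascadeLedger-class
#' @param object a \code{CascadeLedger}.
#' @export
setMethod("show", "CascadeLedger", function(object) {
  cat("CascadeLedger with", length(object@stages), "stage(s)\n")
  for (s in object@stages) {
    cat(sprintf("  %-28s %5d -> %5d   [%s]\n", s$stage, s$input, s$output,
                s$rule))
    if (nrow(s$excluded)) {
      ids <- s$excluded$compound_id
      shown <- paste(utils::head(ids, 8L), collapse = ", ")
      if (length(ids) > 8L)
        shown <- paste0(shown, ", ... (", length(ids) - 8L, " more)")
      cat("    excluded:", shown, "\n")
    }
  }
})
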