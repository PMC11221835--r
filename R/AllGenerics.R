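#' @rdname FieldImage-class
#' @param object,x a \code{FieldImage} or \code{LabelMask}.
#' @export
setGeneric("fieldId", function(x) standardGeneric("fieldId"))

#' @rdname FieldImage-class
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))

#' @rdname FieldImage-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname FieldImage-class
#' @param channel channel role name.
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @rdname FieldImage-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname LabelMask-class
#' @export
setGeneric("maskKind", function(x) standardGeneric("maskKind"))

#' @rdname LabelMask-class
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname CascadeLedger-class
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))
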