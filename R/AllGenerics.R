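#' Accessors for image and mask objects
#'
#' \code{pixels} returns the intensity matrix of a \linkS4class{ChannelImage};
#' \code{maskLabels} the integer label matrix of a \linkS4class{LabeledMask};
#' \code{nLabels} the number of labelled nuclei; \code{pixelSize} the pixel
#' size in microns; \code{shiftVector} the integer (dx, dy) of a
#' \linkS4class{TranslationVector}.
#'
#' @param x Object.
#' @return The slot value (matrix, integer count, numeric, or length-2
#'   integer vector respectively).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "ChannelImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname accessors
#' @export
setMethod("maskLabels", "LabeledMask", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))
#' @rdname accessors
#' @export
setMethod("nLabels", "LabeledMask", function(x) max(x@labels, 0L))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "ChannelImage", function(x) x@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("pixelSize", "LabeledMask", function(x) x@pixelSizeUm)

#' @rdname accessors
#' @export
setGeneric("shiftVector", function(x) standardGeneric("shiftVector"))
#' @rdname accessors
#' @export
setMethod("shiftVector", "TranslationVector", function(x) c(dx = x@dxPx, dy = x@dyPx))

#' @rdname accessors
#' @export
setGeneric("sceneNuclei", function(x) standardGeneric("sceneNuclei"))
#' @rdname accessors
#' @export
setMethod("sceneNuclei", "SceneTruth", function(x) x@nuclei)

#' @rdname accessors
#' @export
setGeneric("sceneSpots", function(x) standardGeneric("sceneSpots"))
#' @rdname accessors
#' @export
setMethod("sceneSpots", "SceneTruth", function(x) x@spots)

#' @rdname accessors
#' @export
setGeneric("sceneShift", function(x) standardGeneric("sceneShift"))
#' @rdname accessors
#' @export
setMethod("sceneShift", "SceneTruth", function(x) x@shift)

setMethod("dim", "ChannelImage", function(x) dim(x@pixels))
setMethod("dim", "LabeledMask", function(x) dim(x@labels))
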