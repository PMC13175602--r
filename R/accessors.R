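#' Accessors for the package's S4 containers
#'
#' Small generics exposing the slots of [AnnotatedImage-class],
#' [CompositeImage-class], [MosaicLayout-class], [DetectionResult-class] and
#' [ConfusionCounts-class] without direct slot access.
#'
#' @param object an object of the relevant class.
#' @return the slot value (`imageId` a string, `pixels` a matrix, `rois` and
#'   `detectionBoxes` data.frames, sizes integers).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("rois", function(object) standardGeneric("rois"))
#' @rdname accessors
#' @export
setGeneric("diagnosis", function(object) standardGeneric("diagnosis"))
#' @rdname accessors
#' @export
setGeneric("imageWidth", function(object) standardGeneric("imageWidth"))
#' @rdname accessors
#' @export
setGeneric("imageHeight", function(object) standardGeneric("imageHeight"))
#' @rdname accessors
#' @export
setGeneric("detectionBoxes", function(object) standardGeneric("detectionBoxes"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("layout", function(object) standardGeneric("layout"))
#' @rdname accessors
#' @export
setGeneric("tileSize", function(object) standardGeneric("tileSize"))
#' @rdname accessors
#' @export
setGeneric("placement", function(object) standardGeneric("placement"))
#' @rdname accessors
#' @export
setGeneric("regionMask", function(object) standardGeneric("regionMask"))

#' @rdname accessors
setMethod("imageId", "AnnotatedImage", function(object) object@imageId)
#' @rdname accessors
setMethod("imageId", "DetectionResult", function(object) object@imageId)
#' @rdname accessors
setMethod("pixels", "AnnotatedImage", function(object) object@pixels)
#' @rdname accessors
setMethod("rois", "AnnotatedImage", function(object) object@rois)
#' @rdname accessors
setMethod("diagnosis", "AnnotatedImage", function(object) object@diagnosis)
#' @rdname accessors
setMethod("imageWidth", "AnnotatedImage",
          function(object) ncol(object@pixels))
#' @rdname accessors
setMethod("imageHeight", "AnnotatedImage",
          function(object) nrow(object@pixels))
#' @rdname accessors
setMethod("detectionBoxes", "DetectionResult", function(object) object@boxes)
#' @rdname accessors
setMethod("provenance", "CompositeImage", function(object) object@provenance)
#' @rdname accessors
setMethod("layout", "CompositeImage", function(object) object@layout)
#' @rdname accessors
setMethod("tileSize", "MosaicLayout",
          function(object) c(width = object@tileWidth,
                             height = object@tileHeight))
#' @rdname accessors
setMethod("placement", "MosaicLayout", function(object) object@placement)
#' @rdname accessors
setMethod("regionMask", "RegionizationResult", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("kRealized", function(object) standardGeneric("kRealized"))
#' @rdname accessors
setMethod("kRealized", "RegionizationResult", function(object) object@kRealized)
#' @rdname accessors
#' @export
setGeneric("scoreThreshold", function(object) standardGeneric("scoreThreshold"))
#' @rdname accessors
setMethod("scoreThreshold", "RegionizationResult",
          function(object) object@thresholdUsed)

#' @rdname accessors
#' @export
counts <- function(object) {
    stopifnot(is(object, "ConfusionCounts"))
    c(tp = object@tp, fp = object@fp, tn = object@tn, fn = object@fn)
}
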