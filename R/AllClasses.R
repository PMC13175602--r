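#' @import methods
#' @importFrom stats quantile rnorm runif sd setNames
#' @importFrom utils head read.csv write.csv
NULL

.CLASS_LEVELS <- c("benign", "malignant")

## Box tables are plain data.frames in the annotation dialect
## (x, y, width, height, label [, confidence]), 0-based half-open pixels:
## a box covers columns [x, x+width) and rows [y, y+height).
.BOX_COLS <- c("x", "y", "width", "height", "label")

.checkBoxTable <- function(boxes, requireConfidence = FALSE) {
    msgs <- character(0)
    need <- .BOX_COLS
    if (requireConfidence) need <- c(need, "confidence")
    miss <- setdiff(need, names(boxes))
    if (length(miss)) {
        return(sprintf("box table lacks column(s): %s",
                       paste(miss, collapse = ", ")))
    }
    if (nrow(boxes) == 0L) return(character(0))
    if (any(boxes$width < 1L) || any(boxes$height < 1L))
        msgs <- c(msgs, "box width and height must be >= 1 pixel")
    if (any(boxes$x < 0L) || any(boxes$y < 0L))
        msgs <- c(msgs, "box x and y must be >= 0 (0-based coordinates)")
    if (!all(boxes$label %in% .CLASS_LEVELS))
        msgs <- c(msgs, sprintf("box labels must be in {%s}",
                                paste(.CLASS_LEVELS, collapse = ", ")))
    if (requireConfidence &&
        (any(boxes$confidence < 0) || any(boxes$confidence > 1)))
        msgs <- c(msgs, "confidences must lie in [0, 1]")
    msgs
}

.boxesInside <- function(boxes, width, height) {
    nrow(boxes) == 0L ||
        (all(boxes$x + boxes$width <= width) &&
         all(boxes$y + boxes$height <= height))
}

#' AnnotatedImage: a grayscale raster with labeled ROI boxes
#'
#' The central container of the package: a single grayscale image (intensities
#' in \[0, 1\], stored as a numeric matrix with rows = y and columns = x),
#' zero or more rectangular regions of interest in the 0-based half-open box
#' convention, and an image-level benign/malignant diagnosis.
#'
#' @slot imageId character scalar identifier.
#' @slot pixels numeric matrix of intensities in \[0, 1\]; `nrow` is the image
#'   height, `ncol` the width.
#' @slot rois data.frame with columns `x, y, width, height, label`; every box
#'   must lie wholly inside the pixel grid.
#' @slot diagnosis `"benign"` or `"malignant"` (image-level gold standard).
#'
#' @seealso [annotatedImage()], [CompositeImage-class]
#' @exportClass AnnotatedImage
setClass("AnnotatedImage",
    representation(imageId = "character", pixels = "matrix",
                   rois = "data.frame", diagnosis = "character"),
    validity = function(object) {
        msgs <- character(0)
        if (length(object@imageId) != 1L || !nzchar(object@imageId))
            msgs <- c(msgs, "imageId must be a non-empty string")
        px <- object@pixels
        if (!is.numeric(px) || length(dim(px)) != 2L)
            msgs <- c(msgs, "pixels must be a 2D numeric matrix")
        else if (anyNA(px) || min(px) < 0 || max(px) > 1)
            msgs <- c(msgs, "pixel intensities must be finite and in [0, 1]")
        if (length(object@diagnosis) != 1L ||
            !object@diagnosis %in% .CLASS_LEVELS)
            msgs <- c(msgs, "diagnosis must be 'benign' or 'malignant'")
        msgs <- c(msgs, .checkBoxTable(object@rois))
        if (!length(msgs) && !.boxesInside(object@rois,
                                           ncol(px), nrow(px)))
            msgs <- c(msgs, "every ROI box must lie inside the pixel grid")
        if (length(msgs)) msgs else TRUE
    })

#' Construct an AnnotatedImage
#'
#' @param imageId character identifier.
#' @param pixels numeric matrix in \[0, 1\] (rows = y, columns = x).
#' @param rois data.frame of boxes (`x, y, width, height, label`); defaults to
#'   an empty table.
#' @param diagnosis image-level label; defaults to the label of the single ROI
#'   when exactly one is present.
#' @return an [AnnotatedImage-class] object.
#' @examples
#' img <- annotatedImage("a", matrix(0.5, 32, 32),
#'                       roiBox(4, 6, 10, 8, "benign"))
#' imageWidth(img)
#' @export
annotatedImage <- function(imageId, pixels, rois = emptyRoiTable(),
                           diagnosis = NULL) {
    if (is.null(diagnosis)) {
        if (nrow(rois) != 1L)
            stop("diagnosis must be given unless the image has exactly one ROI")
        diagnosis <- as.character(rois$label[1L])
    }
    new("AnnotatedImage", imageId = as.character(imageId), pixels = pixels,
        rois = as.data.frame(rois), diagnosis = diagnosis)
}

#' MosaicLayout: grid geometry and class placement for composite inputs
#'
#' Describes a 1x2 or 2x2 composite: the harmonized tile size and which
#' benign/malignant class slot each grid cell holds. Cells are named 1-based
#' as (row, col). The default 2x2 placement puts benign tiles at (1,1) and
#' (2,2) and malignant tiles at (1,2) and (2,1).
#'
#' @slot kind `"one_by_two"` or `"two_by_two"`.
#' @slot tileWidth,tileHeight harmonized tile size in pixels.
#' @slot placement data.frame with columns `row, col, slot` mapping every grid
#'   cell to a class slot.
#' @seealso [mosaicLayout()]
#' @exportClass MosaicLayout
setClass("MosaicLayout",
    representation(kind = "character", tileWidth = "integer",
                   tileHeight = "integer", placement = "data.frame"),
    validity = function(object) {
        msgs <- character(0)
        if (!object@kind %in% c("one_by_two", "two_by_two"))
            msgs <- c(msgs, "kind must be 'one_by_two' or 'two_by_two'")
        if (object@tileWidth < 8L || object@tileHeight < 8L)
            msgs <- c(msgs, "tile dimensions must be >= 8 px")
        pl <- object@placement
        if (!all(c("row", "col", "slot") %in% names(pl))) {
            msgs <- c(msgs, "placement needs columns row, col, slot")
        } else {
            dims <- .layoutDims(object@kind)
            want <- expand.grid(row = seq_len(dims[1L]),
                                col = seq_len(dims[2L]))
            if (nrow(pl) != nrow(want) ||
                !all(paste(want$row, want$col) %in% paste(pl$row, pl$col)))
                msgs <- c(msgs, "placement must cover every grid cell once")
            nb <- sum(pl$slot == "benign")
            nm <- sum(pl$slot == "malignant")
            if (nb != nm)
                msgs <- c(msgs,
                          "placement must hold equally many benign and malignant slots")
        }
        if (length(msgs)) msgs else TRUE
    })

.layoutDims <- function(kind) {
    if (kind == "two_by_two") c(2L, 2L) else c(1L, 2L)
}

#' Construct a MosaicLayout
#'
#' @param kind `"two_by_two"` (default) or `"one_by_two"`.
#' @param tileWidth,tileHeight harmonized tile size in pixels (default 128).
#' @param placement optional data.frame `row, col, slot`; the default 2x2
#'   placement is benign at (1,1)/(2,2), malignant at (1,2)/(2,1); the default
#'   1x2 placement is benign left, malignant right.
#' @return a [MosaicLayout-class].
#' @examples
#' mosaicLayout("two_by_two", 64, 64)
#' @export
mosaicLayout <- function(kind = c("two_by_two", "one_by_two"),
                         tileWidth = 128L, tileHeight = 128L,
                         placement = NULL) {
    kind <- match.arg(kind)
    if (is.null(placement)) {
        placement <- if (kind == "two_by_two") {
            data.frame(row = c(1L, 1L, 2L, 2L), col = c(1L, 2L, 1L, 2L),
                       slot = c("benign", "malignant",
                                "malignant", "benign"))
        } else {
            data.frame(row = c(1L, 1L), col = c(1L, 2L),
                       slot = c("benign", "malignant"))
        }
    }
    new("MosaicLayout", kind = kind, tileWidth = as.integer(tileWidth),
        tileHeight = as.integer(tileHeight),
        placement = as.data.frame(placement))
}

#' CompositeImage: a mosaic of annotated tiles with exact box bookkeeping
#'
#' An [AnnotatedImage-class] assembled from harmonized source tiles placed at
#' fixed grid cells. Carries the layout and a per-tile provenance table that
#' records, for every source image, its grid cell and the scale/pad transform
#' applied, so each composite box can be traced back to its source box.
#'
#' A 2x2 composite carries exactly four ROI boxes, two per class; the
#' image-level `diagnosis` slot is set to `"malignant"` by convention (the
#' composite mixes classes; region labels carry the information).
#'
#' @slot layout the [MosaicLayout-class] used.
#' @slot provenance data.frame with one row per tile: `cell_row, cell_col,
#'   source_id, scale_x, scale_y, pad_x, pad_y, offset_x, offset_y,
#'   src_x, src_y, src_width, src_height, label`.
#' @exportClass CompositeImage
setClass("CompositeImage", contains = "AnnotatedImage",
    representation(layout = "MosaicLayout", provenance = "data.frame"),
    validity = function(object) {
        msgs <- character(0)
        lay <- object@layout
        dims <- .layoutDims(lay@kind)
        wantW <- dims[2L] * lay@tileWidth
        wantH <- dims[1L] * lay@tileHeight
        if (ncol(object@pixels) != wantW || nrow(object@pixels) != wantH)
            msgs <- c(msgs, sprintf("pixel grid must be %d x %d for this layout",
                                    wantH, wantW))
        nBox <- prod(dims)
        if (nrow(object@rois) != nBox)
            msgs <- c(msgs, sprintf("a %s composite must carry exactly %d boxes",
                                    lay@kind, nBox))
        else if (sum(object@rois$label == "benign") != nBox / 2L)
            msgs <- c(msgs, "composite must carry equally many boxes per class")
        if (nrow(object@provenance) != nBox)
            msgs <- c(msgs, "provenance must record one row per tile")
        if (length(msgs)) msgs else TRUE
    })

#' DetectionResult: confidence-scored labeled boxes for one image
#'
#' The output of a detector on a single image: zero or more axis-aligned
#' boxes, each with a benign/malignant label and a confidence in \[0, 1\].
#' The union of the rasterized boxes is the detected region D used by the
#' overlap metrics.
#'
#' @slot imageId character identifier of the scored image.
#' @slot boxes data.frame `x, y, width, height, label, confidence`.
#' @seealso [detectNodules()], [detectionsToMask()]
#' @exportClass DetectionResult
setClass("DetectionResult",
    representation(imageId = "character", boxes = "data.frame"),
    validity = function(object) {
        msgs <- .checkBoxTable(object@boxes, requireConfidence = TRUE)
        if (length(object@imageId) != 1L)
            msgs <- c(msgs, "imageId must be a single string")
        if (length(msgs)) msgs else TRUE
    })

#' Construct a DetectionResult
#'
#' @param imageId image identifier.
#' @param boxes data.frame `x, y, width, height, label, confidence`; defaults
#'   to an empty table (no detections).
#' @return a [DetectionResult-class].
#' @export
detectionResult <- function(imageId, boxes = emptyDetectionTable()) {
    new("DetectionResult", imageId = as.character(imageId),
        boxes = as.data.frame(boxes))
}

#' RegionizationResult: a top-k\% score-map mask with bookkeeping
#'
#' Returned by [topkMask()]: the binary mask of selected pixels, the requested
#' area percentage, the realized percentage (tie inclusion at the threshold
#' can only enlarge the mask), and the score threshold used (the minimum score
#' among selected pixels).
#'
#' @slot mask integer 0/1 matrix, same shape as the score map.
#' @slot kRequested,kRealized percentages in (0, 100].
#' @slot thresholdUsed numeric score threshold.
#' @slot degenerate logical; `TRUE` when the score map was constant and the
#'   full mask was returned.
#' @exportClass RegionizationResult
setClass("RegionizationResult",
    representation(mask = "matrix", kRequested = "numeric",
                   kRealized = "numeric", thresholdUsed = "numeric",
                   degenerate = "logical"),
    validity = function(object) {
        if (object@kRealized < object@kRequested - 1e-9)
            "kRealized cannot be smaller than kRequested" else TRUE
    })

#' ConfusionCounts: TP/FP/TN/FN tallies with malignant as positive class
#'
#' @slot tp,fp,tn,fn non-negative integer counts. `tp + fp + tn + fn` is the
#'   number of evaluated images.
#' @seealso [confusionCounts()], [classificationRates()]
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
    representation(tp = "integer", fp = "integer", tn = "integer",
                   fn = "integer"),
    validity = function(object) {
        counts <- c(object@tp, object@fp, object@tn, object@fn)
        if (any(counts < 0L)) "counts must be non-negative" else TRUE
    })

#' Empty box tables in the annotation dialects
#'
#' Convenience constructors for zero-row tables with the right columns and
#' types: `emptyRoiTable()` for the annotation dialect and
#' `emptyDetectionTable()` for the detection dialect (adds `confidence`).
#'
#' @return a zero-row data.frame.
#' @export
emptyRoiTable <- function() {
    data.frame(x = integer(0), y = integer(0), width = integer(0),
               height = integer(0), label = character(0))
}

#' @rdname emptyRoiTable
#' @export
emptyDetectionTable <- function() {
    cbind(emptyRoiTable(), data.frame(confidence = numeric(0)))
}

#' Build a one-row ROI box table
#'
#' @param x,y 0-based upper-left corner (x = column, y = row).
#' @param width,height box extent in pixels, >= 1; the box covers the
#'   half-open pixel set \[x, x+width) x \[y, y+height).
#' @param label `"benign"` or `"malignant"`.
#' @return a one-row data.frame in the annotation dialect.
#' @examples
#' roiBox(10, 10, 20, 20, "malignant")
#' @export
roiBox <- function(x, y, width, height, label = "benign") {
    box <- data.frame(x = as.integer(x), y = as.integer(y),
                      width = as.integer(width), height = as.integer(height),
                      label = as.character(label))
    msgs <- .checkBoxTable(box)
    if (length(msgs)) stop(paste(msgs, collapse = "; "))
    box
}

setMethod("show", "AnnotatedImage", function(object) {
    cat(sprintf("%s '%s': %d x %d px, %d ROI box(es), diagnosis %s\n",
                class(object), object@imageId, ncol(object@pixels),
                nrow(object@pixels), nrow(object@rois), object@diagnosis))
})

setMethod("show", "MosaicLayout", function(object) {
    cat(sprintf("MosaicLayout %s, tile %d x %d px\n", object@kind,
                object@tileWidth, object@tileHeight))
    print(object@placement)
})

setMethod("show", "DetectionResult", function(object) {
    cat(sprintf("DetectionResult '%s': %d box(es)\n", object@imageId,
                nrow(object@boxes)))
    if (nrow(object@boxes)) print(object@boxes)
})

setMethod("show", "RegionizationResult", function(object) {
    cat(sprintf(
        "RegionizationResult: k requested %.4g%%, realized %.4g%%, threshold %.6g%s\n",
        object@kRequested, object@kRealized, object@thresholdUsed,
        if (object@degenerate) " (constant score map)" else ""))
})

setMethod("show", "ConfusionCounts", function(object) {
    cat(sprintf("ConfusionCounts: TP %d, FP %d, TN %d, FN %d (n = %d)\n",
                object@tp, object@fp, object@tn, object@fn,
                object@tp + object@fp + object@tn + object@fn))
})
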