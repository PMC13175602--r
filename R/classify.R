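## Confusion-based classification metrics (malignant = positive class), the
## region-to-image aggregation rules for 2x2 composite inputs, and the
## epoch-window mean +/- sd reporting convention.

#' Build ConfusionCounts
#'
#' Either from the four counts directly, or from parallel vectors of
#' predicted and gold labels (`malignant` positive).
#'
#' @param tp,fp,tn,fn non-negative counts, or
#' @param predicted,gold character vectors of labels (used when given).
#' @return a [ConfusionCounts-class].
#' @examples
#' counts(confusionCounts(tp = 466, fp = 19, tn = 76, fn = 73))
#' @export
confusionCounts <- function(tp = 0L, fp = 0L, tn = 0L, fn = 0L,
                            predicted = NULL, gold = NULL) {
    if (!is.null(predicted)) {
        stopifnot(length(predicted) == length(gold))
        tp <- sum(gold == "malignant" & predicted == "malignant")
        fn <- sum(gold == "malignant" & predicted != "malignant")
        tn <- sum(gold == "benign" & predicted == "benign")
        fp <- sum(gold == "benign" & predicted != "benign")
    }
    new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
        tn = as.integer(tn), fn = as.integer(fn))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP). A rate whose denominator is zero is reported as
#' `NA` (undefined), never 0. Values are rounded to 4 decimals.
#'
#' @param x a [ConfusionCounts-class].
#' @return named numeric vector `accuracy, sensitivity, specificity`.
#' @export
classificationRates <- function(x) {
    stopifnot(is(x, "ConfusionCounts"))
    n <- x@tp + x@tn + x@fp + x@fn
    acc <- if (n > 0L) (x@tp + x@tn) / n else NA_real_
    sens <- if (x@tp + x@fn > 0L) x@tp / (x@tp + x@fn) else NA_real_
    spec <- if (x@tn + x@fp > 0L) x@tn / (x@tn + x@fp) else NA_real_
    round(c(accuracy = acc, sensitivity = sens, specificity = spec), 4)
}

## grid cell containing a point, 1-based (row, col); points exactly on a cell
## boundary go to the lower-index cell
.cellOf <- function(cx, cy, lay) {
    dims <- .layoutDims(lay@kind)
    colIdx <- if (cx > 0 && cx %% lay@tileWidth == 0) cx / lay@tileWidth
              else floor(cx / lay@tileWidth) + 1
    rowIdx <- if (cy > 0 && cy %% lay@tileHeight == 0) cy / lay@tileHeight
              else floor(cy / lay@tileHeight) + 1
    c(min(dims[1L], as.integer(rowIdx)), min(dims[2L], as.integer(colIdx)))
}

.cellsOfBoxes <- function(boxes, lay) {
    cells <- t(vapply(seq_len(nrow(boxes)), function(i)
        .cellOf(boxes$x[i] + boxes$width[i] / 2,
                boxes$y[i] + boxes$height[i] / 2, lay),
        integer(2)))
    data.frame(row = cells[, 1L], col = cells[, 2L])
}

#' Image-level label from the (1,1) anchor cell of a 2x2 composite
#'
#' Each detection is assigned to the grid cell containing its box center
#' (boundary ties to the lower-index cell). The label of the
#' highest-confidence detection in cell (1,1) is returned. When no detection
#' falls in (1,1) the confidence-weighted vote over all regions is used
#' instead and flagged; an empty detection set abstains.
#'
#' @param detections a [DetectionResult-class] on the composite.
#' @param layout the composite's [MosaicLayout-class].
#' @return list with `label` (`"benign"`, `"malignant"` or `NA` on abstain),
#'   `confidence`, and `fallback` (`TRUE` when the vote fallback fired).
#' @export
aggregateAnchorCell <- function(detections, layout) {
    boxes <- detectionBoxes(detections)
    if (nrow(boxes) == 0L)
        return(list(label = NA_character_, confidence = NA_real_,
                    fallback = FALSE))
    cells <- .cellsOfBoxes(boxes, layout)
    anchor <- boxes[cells$row == 1L & cells$col == 1L, , drop = FALSE]
    if (nrow(anchor) == 0L) {
        vote <- aggregateVote(detections)
        return(list(label = vote$label, confidence = vote$confidence,
                    fallback = TRUE))
    }
    top <- anchor[which.max(anchor$confidence), ]
    list(label = as.character(top$label), confidence = top$confidence,
         fallback = FALSE)
}

#' Image-level label by confidence-weighted vote over detected regions
#'
#' Sums detection confidences per label; the heavier side wins and an exact
#' tie is called malignant (the clinically conservative side). Empty
#' detection sets abstain. Permutation-invariant in the detection list.
#'
#' @param detections a [DetectionResult-class].
#' @return list with `label` and `confidence` (winning share of the total
#'   confidence mass).
#' @export
aggregateVote <- function(detections) {
    boxes <- detectionBoxes(detections)
    if (nrow(boxes) == 0L)
        return(list(label = NA_character_, confidence = NA_real_))
    wB <- sum(boxes$confidence[boxes$label == "benign"])
    wM <- sum(boxes$confidence[boxes$label == "malignant"])
    label <- if (wM >= wB) "malignant" else "benign"
    total <- wB + wM
    list(label = label,
         confidence = if (total > 0) max(wB, wM) / total else 0.5)
}

#' Mean and standard deviation of a metric over an epoch window
#'
#' Implements the reporting convention of averaging per-epoch metrics over a
#' late, stable window (e.g. epochs 31-40) and quoting mean +/- sample
#' standard deviation. A window of length one reports sd 0 with a flag.
#'
#' @param series data.frame with columns `epoch` and `value` (or a metric
#'   column named by `metric`).
#' @param window integer vector of epochs, e.g. `31:40`.
#' @param metric column to summarize when `value` is absent.
#' @return list `mean`, `sd`, `n`, `degenerate`.
#' @export
epochWindowStats <- function(series, window, metric = "value") {
    col <- if ("value" %in% names(series)) "value" else metric
    if (!col %in% names(series))
        stop(sprintf("series has no column '%s'", col))
    if (!all(window %in% series$epoch))
        stop(sprintf("window epochs %s are outside the series",
                     paste(setdiff(window, series$epoch), collapse = ", ")))
    vals <- series[[col]][match(window, series$epoch)]
    if (length(vals) == 0L) stop("empty epoch window")
    degenerate <- length(vals) == 1L
    list(mean = mean(vals), sd = if (degenerate) 0 else sd(vals),
         n = length(vals), degenerate = degenerate)
}
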