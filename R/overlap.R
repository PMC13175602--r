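## Localization metrics comparing a detected region D with a reference ROI R,
## all scaled to percent:
##   IoU = |R n D| / |R u D| x 100   (intersection over union)
##   IoR = |R n D| / |R|     x 100   (intersection over the reference ROI)
##   IoD = |R n D| / |D|     x 100   (intersection over the detected area)
## IoU <= min(IoR, IoD) always, and when the intersection is nonempty the
## three are tied by the harmonic identity 100/IoU = 100/IoR + 100/IoD - 1.

#' Overlap metrics between a reference ROI mask and a detected mask
#'
#' @param refMask binary mask of the reference ROI R (must be nonempty).
#' @param detMask binary mask of the detected region D; an all-zero mask is
#'   allowed and yields a zero triple with `empty_detection = TRUE`.
#' @return a one-row data.frame: `iou, ior, iod` (percent), `area_R, area_D,
#'   area_I` (pixel counts) and `empty_detection`.
#' @examples
#' R <- boxToMask(roiBox(0, 0, 10, 10), c(20, 20))
#' D <- boxToMask(roiBox(5, 0, 10, 10), c(20, 20))
#' overlapMetrics(R, D)  # IoU 33.33, IoR 50, IoD 50
#' @export
overlapMetrics <- function(refMask, detMask) {
    if (!identical(dim(refMask), dim(detMask)))
        stop(sprintf("mask shape mismatch: %s vs %s",
                     paste(dim(refMask), collapse = "x"),
                     paste(dim(detMask), collapse = "x")))
    aR <- maskArea(refMask)
    if (aR == 0L)
        stop("reference ROI mask is empty; a reference region is required")
    aD <- maskArea(detMask)
    aI <- as.integer(sum(refMask != 0 & detMask != 0))
    if (aD == 0L) {
        return(data.frame(iou = 0, ior = 0, iod = 0, area_R = aR,
                          area_D = 0L, area_I = 0L, empty_detection = TRUE))
    }
    aU <- aR + aD - aI
    data.frame(iou = 100 * aI / aU, ior = 100 * aI / aR,
               iod = 100 * aI / aD, area_R = aR, area_D = aD, area_I = aI,
               empty_detection = FALSE)
}

#' Dataset-level mean of overlap triples
#'
#' Unweighted arithmetic mean of IoU, IoR and IoD over images, rounded to two
#' decimals for reporting (every image counts equally regardless of size).
#'
#' @param triples data.frame of rows from [overlapMetrics()].
#' @return one-row data.frame `iou, ior, iod, n`.
#' @export
overlapSummary <- function(triples) {
    if (nrow(triples) == 0L) stop("no overlap records to summarize")
    data.frame(iou = round(mean(triples$iou), 2),
               ior = round(mean(triples$ior), 2),
               iod = round(mean(triples$iod), 2),
               n = nrow(triples))
}

#' Fraction of correctly classified images with adequate localization
#'
#' Among true positives (gold and predicted malignant) and true negatives
#' (gold and predicted benign) separately, the fraction of records whose IoU
#' meets the threshold (`>=`, so a record at exactly the threshold counts as
#' localized). A class with no correctly classified records gets `NA`, not 0.
#'
#' @param records data.frame with columns `iou`, `predicted`, `gold`
#'   (labels in `benign`/`malignant`; malignant is the positive class).
#' @param threshold IoU threshold in percent, default 30.
#' @return data.frame with one row per class (`TP`, `TN`): `n`, `localized`,
#'   `fraction` (percent).
#' @export
localizedFraction <- function(records, threshold = 30) {
    if (threshold <= 0 || threshold > 100)
        stop("threshold must be a percentage in (0, 100]")
    tp <- records[records$gold == "malignant" &
                  records$predicted == "malignant", , drop = FALSE]
    tn <- records[records$gold == "benign" &
                  records$predicted == "benign", , drop = FALSE]
    one <- function(cls, part) {
        n <- nrow(part)
        loc <- sum(part$iou >= threshold)
        data.frame(class = cls, n = n, localized = loc,
                   fraction = if (n > 0L) 100 * loc / n else NA_real_)
    }
    rbind(one("TP", tp), one("TN", tn))
}

#' Score a composite's detections against its reference ROIs, per nodule
#'
#' For each reference box in a composite (or plain annotated image), the
#' detected region D is the union of the detection boxes whose centers fall
#' in the same grid cell (for composites) or the union of all detections
#' (single images). Returns one overlap triple per nodule plus the gold and
#' predicted label for that region (highest-confidence detection in the
#' cell; `NA` when the cell has no detection).
#'
#' @param image an [AnnotatedImage-class] or [CompositeImage-class].
#' @param detections a [DetectionResult-class] for the same image.
#' @return data.frame: one row per reference box with `image_id, iou, ior,
#'   iod, area_R, area_D, area_I, empty_detection, gold, predicted`.
#' @export
overlapPerNodule <- function(image, detections) {
    shape <- dim(pixels(image))
    refBoxes <- rois(image)
    dets <- detectionBoxes(detections)
    isComposite <- is(image, "CompositeImage")
    out <- NULL
    for (i in seq_len(nrow(refBoxes))) {
        if (isComposite) {
            lay <- layout(image)
            cell <- .cellOf(refBoxes$x[i] + refBoxes$width[i] / 2,
                            refBoxes$y[i] + refBoxes$height[i] / 2, lay)
            pick <- if (nrow(dets)) {
                cells <- .cellsOfBoxes(dets, lay)
                dets[cells$row == cell[1L] & cells$col == cell[2L], ,
                     drop = FALSE]
            } else dets
        } else {
            pick <- dets
        }
        refMask <- boxToMask(refBoxes[i, ], shape)
        detMask <- detectionsToMask(pick, shape)
        tri <- overlapMetrics(refMask, detMask)
        tri$image_id <- imageId(image)
        tri$gold <- as.character(refBoxes$label[i])
        tri$predicted <- if (nrow(pick))
            as.character(pick$label[which.max(pick$confidence)])
        else NA_character_
        out <- rbind(out, tri)
    }
    out
}
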