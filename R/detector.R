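## A deterministic, rule-based nodule detector/classifier. It stands in for a
## trained detection network so the full detect -> overlap -> aggregate ->
## rates pipeline can be exercised on phantoms at desk scale; it makes no
## claim to clinical performance. All thresholds live in one config block.

#' Reference detector configuration
#'
#' @param blurSigma Gaussian smoothing sigma (px) applied before
#'   thresholding.
#' @param darkQuantile hypoechoic threshold percentile: candidate pixels are
#'   those below this quantile of the smoothed image (a percentile below the
#'   median).
#' @param minContrast additional absolute guard: the threshold never rises
#'   above `median - minContrast`, so a blank speckle image yields no
#'   candidates.
#' @param minArea connected components smaller than this (px) are discarded.
#' @param aspectCutoff height/width ratio at or above which a region is
#'   called malignant.
#' @param compactnessCutoff boundary compactness (perimeter^2 / (4 pi area))
#'   at or above which a region is called malignant.
#' @param confidenceGain logistic slope mapping the rule margin to a
#'   confidence.
#' @param contrastScale contrast (intensity drop) mapped to detection
#'   confidence 1.
#' @return a list of class `DetectorConfig`.
#' @export
detectorConfig <- function(blurSigma = 2, darkQuantile = 0.08,
                           minContrast = 0.10, minArea = 60L,
                           aspectCutoff = 1.0, compactnessCutoff = 1.30,
                           confidenceGain = 8, contrastScale = 0.35) {
    cfg <- list(blurSigma = blurSigma, darkQuantile = darkQuantile,
                minContrast = minContrast, minArea = as.integer(minArea),
                aspectCutoff = aspectCutoff,
                compactnessCutoff = compactnessCutoff,
                confidenceGain = confidenceGain,
                contrastScale = contrastScale)
    class(cfg) <- c("DetectorConfig", "list")
    cfg
}

.candidateMask <- function(px, config) {
    sm <- if (config$blurSigma > 0)
        .ebMatrix(EBImage::gblur(EBImage::Image(px),
                                 sigma = config$blurSigma))
    else px
    med <- stats::median(sm)
    thr <- min(stats::quantile(sm, config$darkQuantile),
               med - config$minContrast)
    list(smoothed = sm, mask = (sm < thr) * 1L, median = med)
}

.componentStats <- function(labelled, i) {
    idx <- which(labelled == i, arr.ind = TRUE)
    rr <- range(idx[, 1L]); cc <- range(idx[, 2L])
    list(area = nrow(idx),
         x = cc[1L] - 1L, y = rr[1L] - 1L,
         width = cc[2L] - cc[1L] + 1L, height = rr[2L] - rr[1L] + 1L)
}

#' Detect hypoechoic regions in a grayscale image
#'
#' Smooth, threshold at a percentile below the image median, label connected
#' components, discard small ones, and return a tight box per surviving
#' component. Detection confidence is the component's contrast against the
#' image median, normalized by `contrastScale`; each box is labeled via
#' [classifyRegion()]. Deterministic: identical input and config give
#' identical detections.
#'
#' @param image an [AnnotatedImage-class] (its ROIs are ignored) or a pixel
#'   matrix in \[0, 1\].
#' @param config a [detectorConfig()] list.
#' @return a [DetectionResult-class]; empty when nothing passes the rules.
#' @export
detectNodules <- function(image, config = detectorConfig()) {
    px <- if (is(image, "AnnotatedImage")) pixels(image) else image
    id <- if (is(image, "AnnotatedImage")) imageId(image) else "image"
    cand <- .candidateMask(px, config)
    lab <- EBImage::bwlabel(cand$mask)
    nComp <- max(lab)
    rows <- NULL
    for (i in seq_len(nComp)) {
        st <- .componentStats(lab, i)
        if (st$area < config$minArea) next
        compPix <- cand$smoothed[lab == i]
        contrast <- cand$median - mean(compPix)
        conf <- min(1, max(0, contrast / config$contrastScale))
        cls <- .classifySupport((lab == i) * 1L, st, config)
        rows <- rbind(rows, data.frame(
            x = st$x, y = st$y, width = st$width, height = st$height,
            label = cls$label, confidence = round(conf, 4)))
    }
    if (is.null(rows)) return(detectionResult(id))
    detectionResult(id, rows)
}

.classifySupport <- function(supportMask, st, config) {
    aspect <- st$height / st$width
    compact <- shapeCompactness(supportMask)
    margin <- max(aspect - config$aspectCutoff,
                  compact - config$compactnessCutoff)
    pMal <- 1 / (1 + exp(-config$confidenceGain * margin))
    label <- if (margin >= 0) "malignant" else "benign"  # tie -> malignant
    list(label = label, confidence = max(pMal, 1 - pMal),
         aspect = aspect, compactness = compact)
}

#' Classify the nodule inside a given box
#'
#' Re-derives the hypoechoic support inside the box (same smoothing and
#' thresholding as [detectNodules()]), keeps its largest connected component,
#' and applies the shape rule: malignant iff the component's height/width
#' aspect meets `aspectCutoff` or its boundary compactness meets
#' `compactnessCutoff` (a region exactly at a cutoff is called malignant).
#' Confidence is a logistic transform of the margin to the cutoff.
#'
#' @param image an [AnnotatedImage-class] or pixel matrix.
#' @param box a one-row box table locating the region.
#' @param config a [detectorConfig()] list.
#' @return list `label` (`NA` abstain when the box holds no support),
#'   `confidence`, `aspect`, `compactness`.
#' @export
classifyRegion <- function(image, box, config = detectorConfig()) {
    px <- if (is(image, "AnnotatedImage")) pixels(image) else image
    box <- as.list(box)
    if (box$x + box$width > ncol(px) || box$y + box$height > nrow(px))
        stop("box exceeds the image extent")
    cand <- .candidateMask(px, config)
    inBox <- matrix(0L, nrow = nrow(px), ncol = ncol(px))
    rows <- (box$y + 1L):(box$y + box$height)
    cols <- (box$x + 1L):(box$x + box$width)
    inBox[rows, cols] <- cand$mask[rows, cols]
    if (sum(inBox) == 0L)
        return(list(label = NA_character_, confidence = NA_real_,
                    aspect = NA_real_, compactness = NA_real_))
    lab <- EBImage::bwlabel(inBox)
    areas <- tabulate(lab[lab > 0])
    keep <- which.max(areas)
    st <- .componentStats(lab, keep)
    .classifySupport((lab == keep) * 1L, st, config)
}
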