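## Turning attention score maps and detection outputs into binary detected
## regions D.

#' Threshold a score map at its top-k% of pixels
#'
#' Selects the smallest score threshold `t` such that pixels with score
#' `>= t` make up at least `k`% of the map; all pixels tied at `t` are
#' included, so the realized area fraction can exceed the request (it is
#' reported as `kRealized`). Defined over pixel-count rank, not score value,
#' so the mask at `k1 < k2` is always nested inside the mask at `k2`.
#'
#' A constant score map cannot be partitioned by rank; it yields the full
#' mask with `kRealized = 100` and a warning.
#'
#' @param scores numeric matrix of finite non-negative scores.
#' @param k requested area percentage in (0, 100].
#' @return a [RegionizationResult-class].
#' @examples
#' s <- matrix(seq_len(100), 10)
#' kRealized(topkMask(s, 30))  # 30
#' @export
topkMask <- function(scores, k) {
    if (!is.numeric(k) || length(k) != 1L || k <= 0 || k > 100)
        stop("k must be a percentage in (0, 100]")
    if (anyNA(scores) || any(!is.finite(scores)) || any(scores < 0))
        stop("score map must be finite and non-negative")
    n <- length(scores)
    if (min(scores) == max(scores)) {
        warning("constant score map: returning the full mask")
        mask <- matrix(1L, nrow = nrow(scores), ncol = ncol(scores))
        return(new("RegionizationResult", mask = mask, kRequested = k,
                   kRealized = 100, thresholdUsed = scores[1L],
                   degenerate = TRUE))
    }
    need <- ceiling(n * k / 100)
    thr <- sort(as.vector(scores), decreasing = TRUE)[need]
    sel <- scores >= thr
    mask <- matrix(as.integer(sel), nrow = nrow(scores))
    new("RegionizationResult", mask = mask, kRequested = k,
        kRealized = 100 * sum(sel) / n, thresholdUsed = thr,
        degenerate = FALSE)
}

#' Rasterize a detection result to a detected-region mask
#'
#' The detected region D for an image is the union of its rasterized
#' detection boxes; an empty detection list gives an empty mask.
#'
#' @param detections a [DetectionResult-class] or a box table.
#' @param shape grid size as `c(height, width)`.
#' @return an integer 0/1 matrix.
#' @export
detectionsToMask <- function(detections, shape) {
    boxes <- if (is(detections, "DetectionResult"))
        detectionBoxes(detections) else as.data.frame(detections)
    if (nrow(boxes) == 0L) return(unionMasks(list(), shape))
    unionMasks(lapply(seq_len(nrow(boxes)),
                      function(i) boxToMask(boxes[i, ], shape)))
}
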