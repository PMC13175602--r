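## File formats: 8/16-bit grayscale PNG images, the annotation CSV dialect
## `image_id,x,y,width,height,label`, the detection dialect with a trailing
## `confidence` column, and score maps as plain CSV numeric grids or 16-bit
## PNGs with a sidecar scale factor.

#' Read a grayscale PNG as an intensity matrix
#'
#' Intensities are normalized to \[0, 1\] at load time regardless of bit
#' depth. RGB(A) input is converted to grayscale by channel averaging.
#'
#' @param path PNG file path.
#' @return numeric matrix (rows = y, columns = x) in \[0, 1\].
#' @export
readImagePNG <- function(path) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) px <- apply(px[, , 1:3, drop = FALSE], c(1, 2), mean)
    px
}

#' Write an intensity matrix as a grayscale PNG
#'
#' Written at 8 bits per pixel; [readImagePNG()] reads both 8- and 16-bit
#' input, so externally produced 16-bit maps round-trip through the reader.
#'
#' @param pixels numeric matrix in \[0, 1\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(pixels, path) {
    png::writePNG(pmin(pmax(pixels, 0), 1), path)
    invisible(path)
}

.readBoxCSV <- function(path, needConfidence) {
    cols <- c("image_id", "x", "y", "width", "height", "label")
    if (needConfidence) cols <- c(cols, "confidence")
    tab <- read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(cols, names(tab))
    if (length(miss))
        stop(sprintf("%s: missing column(s) %s", path,
                     paste(miss, collapse = ", ")))
    for (i in seq_len(nrow(tab))) {
        row <- tab[i, ]
        bad <- .checkBoxTable(row, requireConfidence = needConfidence)
        if (length(bad))
            stop(sprintf("%s line %d: %s", path, i + 1L,
                         paste(bad, collapse = "; ")))
    }
    tab
}

#' Read / write annotation tables
#'
#' The annotation dialect is a UTF-8 CSV with header
#' `image_id,x,y,width,height,label`, one row per box, 0-based half-open
#' coordinates. Malformed rows are reported with their file line number.
#'
#' @param path CSV file path.
#' @return `readAnnotations` returns a data.frame with those columns.
#' @export
readAnnotations <- function(path) .readBoxCSV(path, needConfidence = FALSE)

#' @rdname readAnnotations
#' @param annotations data.frame in the annotation dialect.
#' @export
writeAnnotations <- function(annotations, path) {
    write.csv(annotations, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read / write detection tables
#'
#' The detection dialect extends the annotation dialect with a `confidence`
#' column in \[0, 1\].
#'
#' @param path CSV file path.
#' @return `readDetections` returns a data.frame; `splitDetections` turns such
#'   a table into a list of [DetectionResult-class], one per `image_id`.
#' @export
readDetections <- function(path) .readBoxCSV(path, needConfidence = TRUE)

#' @rdname readDetections
#' @param detections a detection table or list of [DetectionResult-class].
#' @export
writeDetections <- function(detections, path) {
    if (is.list(detections) && !is.data.frame(detections))
        detections <- do.call(rbind, lapply(detections, function(d) {
            if (nrow(detectionBoxes(d)) == 0L) return(NULL)
            cbind(image_id = imageId(d), detectionBoxes(d))
        }))
    if (is.null(detections))
        detections <- cbind(data.frame(image_id = character(0)),
                            emptyDetectionTable())
    write.csv(detections, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname readDetections
#' @param table a detection table with an `image_id` column.
#' @export
splitDetections <- function(table) {
    lapply(split(table, table$image_id), function(part) {
        detectionResult(part$image_id[1L],
                        part[, c("x", "y", "width", "height", "label",
                                 "confidence")])
    })
}

#' Read a score map
#'
#' Score maps (per-pixel non-negative relevance grids, e.g. class-activation
#' heatmaps) are accepted either as a headerless CSV numeric grid or as a
#' 16-bit grayscale PNG with a stated scale factor (`value = pixel * scale`).
#'
#' @param path file path (`.csv` or `.png`).
#' @param scale multiplier applied to PNG intensities (ignored for CSV).
#' @return numeric matrix of finite non-negative scores.
#' @export
readScoreMap <- function(path, scale = 1) {
    scores <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
        readImagePNG(path) * scale
    } else {
        as.matrix(read.csv(path, header = FALSE))
    }
    dimnames(scores) <- NULL
    if (anyNA(scores) || any(!is.finite(scores)) || any(scores < 0))
        stop(sprintf("%s: score maps must be finite and non-negative", path))
    scores
}

#' @rdname readScoreMap
#' @param scores numeric score matrix.
#' @export
writeScoreMapCSV <- function(scores, path) {
    utils::write.table(scores, path, row.names = FALSE, col.names = FALSE,
                       sep = ",")
    invisible(path)
}

## flat annotation rows for one image's boxes
.annotationRows <- function(id, boxes) {
    if (nrow(boxes) == 0L)
        return(cbind(data.frame(image_id = character(0)), emptyRoiTable()))
    cbind(image_id = id, boxes[, .BOX_COLS])
}
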