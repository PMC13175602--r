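## Shared coordinate conventions and rasterization primitives.
##
## Boxes are 0-based and half-open: x indexes columns, y indexes rows, the
## origin is the top-left pixel, and a box (x, y, w, h) covers the pixel set
## [x, x+w) x [y, y+h). Masks are integer 0/1 matrices with rows = y and
## columns = x, matching the pixel matrices of AnnotatedImage.

#' Rasterize a box to a binary mask
#'
#' @param box a one-row box table (see [roiBox()]) or a named vector/list with
#'   `x, y, width, height`.
#' @param shape target grid size as `c(height, width)` (matrix `dim()` order).
#' @return an integer 0/1 matrix of dimension `shape` with exactly
#'   `width * height` one-pixels at the half-open extent of `box`.
#' @examples
#' m <- boxToMask(roiBox(5, 0, 10, 10), c(20, 20))
#' sum(m)  # 100
#' @export
boxToMask <- function(box, shape) {
    box <- as.list(box)
    x <- as.integer(box$x); y <- as.integer(box$y)
    w <- as.integer(box$width); h <- as.integer(box$height)
    stopifnot(length(shape) == 2L, w >= 1L, h >= 1L, x >= 0L, y >= 0L)
    H <- as.integer(shape[1L]); W <- as.integer(shape[2L])
    if (x + w > W)
        stop(sprintf("box right edge %d exceeds grid width %d", x + w, W))
    if (y + h > H)
        stop(sprintf("box bottom edge %d exceeds grid height %d", y + h, H))
    mask <- matrix(0L, nrow = H, ncol = W)
    mask[(y + 1L):(y + h), (x + 1L):(x + w)] <- 1L
    mask
}

#' Union of binary masks
#'
#' Pixelwise logical OR of masks sharing one shape; builds the detected
#' region D when a detector emits several boxes.
#'
#' @param masks a list of 0/1 matrices; may be empty only when `shape` is
#'   supplied.
#' @param shape optional `c(height, width)` used for the empty list.
#' @return an integer 0/1 matrix.
#' @export
unionMasks <- function(masks, shape = NULL) {
    if (length(masks) == 0L) {
        if (is.null(shape)) stop("empty mask list requires an explicit shape")
        return(matrix(0L, nrow = shape[1L], ncol = shape[2L]))
    }
    ref <- dim(masks[[1L]])
    out <- matrix(0L, nrow = ref[1L], ncol = ref[2L])
    for (m in masks) {
        if (!identical(dim(m), ref))
            stop(sprintf("mask shape mismatch: %s vs %s",
                         paste(ref, collapse = "x"),
                         paste(dim(m), collapse = "x")))
        out <- pmax(out, (m != 0) * 1L)
    }
    storage.mode(out) <- "integer"
    out
}

#' Number of one-pixels in a mask
#' @param mask a 0/1 matrix.
#' @return integer pixel count.
#' @export
maskArea <- function(mask) as.integer(sum(mask != 0))

#' Tight bounding box of a nonempty mask
#'
#' @param mask a 0/1 matrix.
#' @param label label attached to the returned box (default `"benign"`).
#' @return a one-row box table; rasterizing a box and recovering its tight
#'   bounding box is the identity.
#' @export
tightBox <- function(mask, label = "benign") {
    idx <- which(mask != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("cannot take the bounding box of an empty mask")
    r <- range(idx[, 1L]); c <- range(idx[, 2L])
    roiBox(x = c[1L] - 1L, y = r[1L] - 1L,
           width = c[2L] - c[1L] + 1L, height = r[2L] - r[1L] + 1L,
           label = label)
}

#' Convert a 1-based inclusive corner box to the package convention
#'
#' External annotations sometimes arrive as 1-based inclusive corner pairs
#' (x1, y1, x2, y2). This converts them to the 0-based half-open dialect:
#' `x = x1 - 1`, `width = x2 - x1 + 1`, and likewise for y.
#'
#' @param x1,y1,x2,y2 1-based inclusive corners, `x1 <= x2`, `y1 <= y2`.
#' @param label class label for the returned box.
#' @return a one-row box table.
#' @examples
#' fromOneBasedInclusive(1, 1, 10, 10)  # x 0, y 0, 10 x 10
#' @export
fromOneBasedInclusive <- function(x1, y1, x2, y2, label = "benign") {
    if (any(c(x1, y1, x2, y2) < 1))
        stop("1-based inclusive coordinates must all be >= 1")
    if (x2 < x1 || y2 < y1)
        stop(sprintf("inverted corners: (%d,%d) to (%d,%d)",
                     x1, y1, x2, y2))
    roiBox(x = x1 - 1L, y = y1 - 1L, width = x2 - x1 + 1L,
           height = y2 - y1 + 1L, label = label)
}

## round-half-up; base round() is banker's rounding and platform-dependent
## at .5 for doubles
.roundHalfUp <- function(x) floor(x + 0.5)

## strip an EBImage Image down to a plain numeric matrix
.ebMatrix <- function(img) {
    m <- EBImage::imageData(img)
    dimnames(m) <- NULL
    matrix(as.numeric(m), nrow = nrow(m))
}
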