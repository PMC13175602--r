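## Composite (mosaic) input construction: class balancing by oversampling,
## tile harmonization, fixed-placement 1x2 / 2x2 assembly with exact box
## transformation, and rotational arrangements.

#' Balance classes by oversampling
#'
#' Equalizes benign/malignant counts by sampling the smaller class with
#' replacement using a seeded generator; the larger class is untouched and
#' the output order is deterministic given the seed (originals first, then
#' the oversampled extras).
#'
#' @param images list of [AnnotatedImage-class].
#' @param seed integer seed.
#' @return list of [AnnotatedImage-class] with equal class counts.
#' @export
balanceClasses <- function(images, seed) {
    labs <- vapply(images, diagnosis, character(1))
    for (cls in .CLASS_LEVELS)
        if (!any(labs == cls))
            stop(sprintf("cannot balance: no '%s' images supplied", cls))
    nb <- sum(labs == "benign"); nm <- sum(labs == "malignant")
    if (nb == nm) return(images)
    minority <- if (nb < nm) "benign" else "malignant"
    pool <- which(labs == minority)
    extra <- abs(nb - nm)
    set.seed(as.integer(seed))
    picks <- sample(pool, extra, replace = TRUE)
    c(images, images[picks])
}

#' Harmonize an image to a fixed tile size
#'
#' Resizes preserving aspect ratio to fit within the tile, then pads
#' symmetrically with background 0 to exactly `tileWidth` x `tileHeight`.
#' Every ROI box is scaled by the realized per-axis factors and translated by
#' the padding offsets; box coordinates are rounded half-up. The applied
#' transform is attached as `attr(, "transform")` (fields `scale_x, scale_y,
#' pad_x, pad_y`) so composites can record provenance.
#'
#' @param image an [AnnotatedImage-class].
#' @param tileWidth,tileHeight target tile size in pixels (>= 8).
#' @return a tile-sized [AnnotatedImage-class].
#' @export
harmonizeTile <- function(image, tileWidth, tileHeight) {
    stopifnot(tileWidth >= 8L, tileHeight >= 8L)
    h <- .harmonize(image, as.integer(tileWidth), as.integer(tileHeight))
    out <- h$image
    attr(out, "transform") <- h[c("scale_x", "scale_y", "pad_x", "pad_y")]
    out
}

.harmonize <- function(image, tw, th) {
    px <- pixels(image)
    w0 <- ncol(px); h0 <- nrow(px)
    if (w0 == tw && h0 == th) {
        return(list(image = image, scale_x = 1, scale_y = 1,
                    pad_x = 0L, pad_y = 0L))
    }
    s <- min(tw / w0, th / h0)
    newW <- max(1L, as.integer(.roundHalfUp(w0 * s)))
    newH <- max(1L, as.integer(.roundHalfUp(h0 * s)))
    sx <- newW / w0; sy <- newH / h0
    if (newW != w0 || newH != h0) {
        eb <- EBImage::resize(EBImage::Image(t(px)), w = newW, h = newH)
        px <- t(.ebMatrix(eb))
        px <- pmin(pmax(px, 0), 1)
    }
    padX <- as.integer((tw - newW) %/% 2L)
    padY <- as.integer((th - newH) %/% 2L)
    canvas <- matrix(0, nrow = th, ncol = tw)
    canvas[(padY + 1L):(padY + newH), (padX + 1L):(padX + newW)] <- px
    boxes <- rois(image)
    if (nrow(boxes)) {
        newWb <- .roundHalfUp(boxes$width * sx)
        newHb <- .roundHalfUp(boxes$height * sy)
        if (any(newWb < 1) || any(newHb < 1))
            stop("an ROI collapses to zero size at this tile size; ",
                 "use a larger tile")
        bx <- pmin(.roundHalfUp(boxes$x * sx), newW - newWb)
        by <- pmin(.roundHalfUp(boxes$y * sy), newH - newHb)
        boxes$x <- as.integer(bx + padX)
        boxes$y <- as.integer(by + padY)
        boxes$width <- as.integer(newWb)
        boxes$height <- as.integer(newHb)
    }
    list(image = annotatedImage(imageId(image), canvas, boxes,
                                diagnosis(image)),
         scale_x = sx, scale_y = sy, pad_x = padX, pad_y = padY)
}

.assemble <- function(tiles, layout, compositeId) {
    ## tiles: list with one AnnotatedImage per placement row, same order
    pl <- placement(layout)
    tw <- layout@tileWidth; th <- layout@tileHeight
    dims <- .layoutDims(layout@kind)
    canvas <- matrix(0, nrow = dims[1L] * th, ncol = dims[2L] * tw)
    roisOut <- NULL
    prov <- NULL
    for (i in seq_len(nrow(pl))) {
        src <- tiles[[i]]
        if (nrow(rois(src)) != 1L)
            stop(sprintf("source image '%s' must carry exactly one ROI",
                         imageId(src)))
        slot <- pl$slot[i]
        if (diagnosis(src) != slot)
            stop(sprintf(
                "cell (%d,%d) expects a %s image but '%s' is %s",
                pl$row[i], pl$col[i], slot, imageId(src), diagnosis(src)))
        h <- .harmonize(src, tw, th)
        offX <- (pl$col[i] - 1L) * tw
        offY <- (pl$row[i] - 1L) * th
        canvas[(offY + 1L):(offY + th), (offX + 1L):(offX + tw)] <-
            pixels(h$image)
        box <- rois(h$image)
        srcBox <- rois(src)
        box$x <- box$x + offX
        box$y <- box$y + offY
        roisOut <- rbind(roisOut, box)
        prov <- rbind(prov, data.frame(
            cell_row = pl$row[i], cell_col = pl$col[i],
            source_id = imageId(src),
            scale_x = h$scale_x, scale_y = h$scale_y,
            pad_x = h$pad_x, pad_y = h$pad_y,
            offset_x = offX, offset_y = offY, rotation = 0L,
            src_x = srcBox$x, src_y = srcBox$y,
            src_width = srcBox$width, src_height = srcBox$height,
            label = as.character(srcBox$label)))
    }
    new("CompositeImage", imageId = compositeId, pixels = canvas,
        rois = roisOut, diagnosis = "malignant", layout = layout,
        provenance = prov)
}

#' Build a 2x2 composite from two benign and two malignant images
#'
#' Each source carries exactly one ROI whose label must match its class slot.
#' Tiles are harmonized, blitted at their grid cells, and every ROI is moved
#' into composite coordinates by adding the cell's pixel offset to its
#' upper-left corner, preserving its (harmonized) width and height.
#'
#' @param benignPair,malignantPair lists of two [AnnotatedImage-class] each.
#' @param layout a 2x2 [MosaicLayout-class]; default [mosaicLayout()].
#' @param compositeId identifier for the composite.
#' @return a [CompositeImage-class] with four boxes, two per class.
#' @export
buildMosaic2x2 <- function(benignPair, malignantPair,
                           layout = mosaicLayout("two_by_two"),
                           compositeId = "mosaic") {
    stopifnot(layout@kind == "two_by_two",
              length(benignPair) == 2L, length(malignantPair) == 2L)
    pl <- placement(layout)
    tiles <- vector("list", nrow(pl))
    counters <- c(benign = 0L, malignant = 0L)
    for (i in seq_len(nrow(pl))) {
        slot <- pl$slot[i]
        counters[slot] <- counters[slot] + 1L
        tiles[[i]] <- if (slot == "benign") benignPair[[counters[slot]]]
                      else malignantPair[[counters[slot]]]
    }
    .assemble(tiles, layout, compositeId)
}

#' Build a 1x2 composite (one benign, one malignant tile side by side)
#'
#' @param benign,malignant single-ROI [AnnotatedImage-class] sources.
#' @param layout a 1x2 [MosaicLayout-class]; default benign left.
#' @param compositeId identifier for the composite.
#' @return a [CompositeImage-class] with two boxes, one per class.
#' @export
buildMosaic1x2 <- function(benign, malignant,
                           layout = mosaicLayout("one_by_two"),
                           compositeId = "mosaic") {
    stopifnot(layout@kind == "one_by_two")
    pl <- placement(layout)
    tiles <- lapply(pl$slot, function(s) if (s == "benign") benign
                                         else malignant)
    .assemble(tiles, layout, compositeId)
}

## ring order of the 2x2 cells used for cyclic tile rotation (clockwise)
.RING <- data.frame(row = c(1L, 1L, 2L, 2L), col = c(1L, 2L, 2L, 1L))

#' Rotational arrangements of a 2x2 composite
#'
#' Generates the 90/180/270-degree arrangements of a 2x2 composite. In the
#' default `"tiles"` mode the four tiles are permuted cyclically around the
#' grid (quadrant rotation) and the boxes are regenerated by pure
#' translation; pixels within each tile are untouched, so image orientation
#' is preserved. The `"pixels"` mode instead rotates the whole raster
#' (requires square tiles) and transforms boxes accordingly. Each arrangement
#' keeps exactly two boxes per class, and the three outputs plus the original
#' have pairwise-distinct tile placements.
#'
#' @param composite a 2x2 [CompositeImage-class].
#' @param mode `"tiles"` (default) or `"pixels"`.
#' @return list of three [CompositeImage-class] (90, 180, 270 degrees).
#' @export
rotationalArrangements <- function(composite, mode = c("tiles", "pixels")) {
    mode <- match.arg(mode)
    lay <- layout(composite)
    if (lay@kind != "two_by_two")
        stop("rotational arrangements are defined for 2x2 composites only")
    lapply(c(90L, 180L, 270L), function(deg) {
        if (mode == "tiles") .rotateTiles(composite, deg)
        else .rotatePixels(composite, deg)
    })
}

.ringIndex <- function(row, col) {
    which(.RING$row == row & .RING$col == col)
}

.rotateTiles <- function(composite, deg) {
    lay <- layout(composite)
    tw <- lay@tileWidth; th <- lay@tileHeight
    steps <- deg %/% 90L
    prov <- provenance(composite)
    boxes <- rois(composite)
    px <- pixels(composite)
    canvas <- matrix(0, nrow = nrow(px), ncol = ncol(px))
    newProv <- prov
    newBoxes <- boxes
    newPlace <- placement(lay)
    for (i in seq_len(nrow(prov))) {
        ringPos <- .ringIndex(prov$cell_row[i], prov$cell_col[i])
        newPos <- (ringPos - 1L + steps) %% 4L + 1L
        nr <- .RING$row[newPos]; nc <- .RING$col[newPos]
        oldX <- prov$offset_x[i]; oldY <- prov$offset_y[i]
        newX <- (nc - 1L) * tw; newY <- (nr - 1L) * th
        canvas[(newY + 1L):(newY + th), (newX + 1L):(newX + tw)] <-
            px[(oldY + 1L):(oldY + th), (oldX + 1L):(oldX + tw)]
        newBoxes$x[i] <- boxes$x[i] - oldX + newX
        newBoxes$y[i] <- boxes$y[i] - oldY + newY
        newProv$cell_row[i] <- nr; newProv$cell_col[i] <- nc
        newProv$offset_x[i] <- newX; newProv$offset_y[i] <- newY
        newPlace$slot[newPlace$row == nr & newPlace$col == nc] <-
            prov$label[i]
    }
    newLay <- mosaicLayout("two_by_two", tw, th, newPlace)
    new("CompositeImage",
        imageId = sprintf("%s_r%d", imageId(composite), deg),
        pixels = canvas, rois = newBoxes, diagnosis = "malignant",
        layout = newLay, provenance = newProv)
}

.rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

.rotatePixels <- function(composite, deg) {
    lay <- layout(composite)
    if (lay@tileWidth != lay@tileHeight)
        stop("pixel rotation requires square tiles")
    steps <- deg %/% 90L
    px <- pixels(composite)
    boxes <- rois(composite)
    prov <- provenance(composite)
    for (s in seq_len(steps)) {
        H <- nrow(px)
        px <- .rot90cw(px)
        newX <- H - boxes$y - boxes$height
        boxes$y <- boxes$x
        boxes$x <- newX
        tmp <- boxes$width; boxes$width <- boxes$height; boxes$height <- tmp
    }
    prov$rotation <- (prov$rotation + deg) %% 360L
    for (i in seq_len(nrow(prov))) {
        cx <- boxes$x[i] + boxes$width[i] / 2
        cy <- boxes$y[i] + boxes$height[i] / 2
        prov$cell_col[i] <- min(2L, as.integer(cx %/% lay@tileWidth) + 1L)
        prov$cell_row[i] <- min(2L, as.integer(cy %/% lay@tileHeight) + 1L)
        prov$offset_x[i] <- (prov$cell_col[i] - 1L) * lay@tileWidth
        prov$offset_y[i] <- (prov$cell_row[i] - 1L) * lay@tileHeight
    }
    newPlace <- placement(lay)
    for (i in seq_len(nrow(prov)))
        newPlace$slot[newPlace$row == prov$cell_row[i] &
                      newPlace$col == prov$cell_col[i]] <- prov$label[i]
    newLay <- mosaicLayout("two_by_two", lay@tileWidth, lay@tileHeight,
                           newPlace)
    new("CompositeImage",
        imageId = sprintf("%s_p%d", imageId(composite), deg),
        pixels = px, rois = boxes, diagnosis = "malignant",
        layout = newLay, provenance = prov)
}

#' Recover source boxes from a composite's provenance
#'
#' Inverts, for every composite box, the recorded tile translation (and, in
#' pixel-rotation mode, the raster rotation) and the harmonization
#' scale/padding, returning the reconstructed source-image boxes next to the
#' recorded originals. Reconstruction is exact when no scaling occurred and
#' within 1 px otherwise (rounding).
#'
#' @param composite a [CompositeImage-class].
#' @return data.frame with recovered `x, y, width, height` and recorded
#'   `src_x, src_y, src_width, src_height` per box.
#' @export
recoverSourceBoxes <- function(composite) {
    prov <- provenance(composite)
    boxes <- rois(composite)
    lay <- layout(composite)
    Tl <- lay@tileWidth  # square tiles whenever rotation != 0
    out <- prov[, c("source_id", "src_x", "src_y", "src_width",
                    "src_height")]
    out$x <- out$y <- out$width <- out$height <- NA_real_
    for (i in seq_len(nrow(prov))) {
        bx <- boxes$x[i] - prov$offset_x[i]
        by <- boxes$y[i] - prov$offset_y[i]
        bw <- boxes$width[i]; bh <- boxes$height[i]
        rot <- prov$rotation[i]
        while (rot > 0L) {  # undo one 90-degree clockwise step at a time
            newY <- Tl - bx - bw
            bx <- by; by <- newY
            tmp <- bw; bw <- bh; bh <- tmp
            rot <- rot - 90L
        }
        out$x[i] <- (bx - prov$pad_x[i]) / prov$scale_x[i]
        out$y[i] <- (by - prov$pad_y[i]) / prov$scale_y[i]
        out$width[i] <- bw / prov$scale_x[i]
        out$height[i] <- bh / prov$scale_y[i]
    }
    out
}

#' Build a composite dataset from annotated sources
#'
#' Balances the source list by oversampling, shuffles each class with the
#' seeded generator, pairs sources deterministically into composites, and
#' optionally appends the three rotational arrangements of every 2x2
#' composite. Emits the composites plus a flat annotation table (one row per
#' composite box) in the annotation CSV dialect.
#'
#' @param sources list of single-ROI [AnnotatedImage-class].
#' @param layout a [MosaicLayout-class].
#' @param seed integer seed driving balancing and pairing.
#' @param includeRotations append rotational arrangements (2x2 only).
#' @param rotationMode `"tiles"` or `"pixels"` (see
#'   [rotationalArrangements()]).
#' @return list with `composites` (list of [CompositeImage-class]) and
#'   `annotations` (data.frame `image_id, x, y, width, height, label`).
#' @export
buildMosaicDataset <- function(sources, layout = mosaicLayout("two_by_two"),
                               seed = 1L, includeRotations = TRUE,
                               rotationMode = "tiles") {
    balanced <- balanceClasses(sources, seed)
    labs <- vapply(balanced, diagnosis, character(1))
    ben <- balanced[labs == "benign"]
    mal <- balanced[labs == "malignant"]
    perClass <- if (layout@kind == "two_by_two") 2L else 1L
    n <- min(length(ben), length(mal)) %/% perClass
    if (n == 0L)
        stop(sprintf(
            "not enough images per class to form a composite: %d benign, %d malignant, need %d each",
            length(ben), length(mal), perClass))
    set.seed(as.integer(seed) + 1L)
    ben <- ben[sample.int(length(ben))]
    mal <- mal[sample.int(length(mal))]
    composites <- list()
    for (i in seq_len(n)) {
        id <- sprintf("mosaic_%04d", i)
        take <- ((i - 1L) * perClass + 1L):(i * perClass)
        comp <- if (layout@kind == "two_by_two")
            buildMosaic2x2(ben[take], mal[take], layout, id)
        else buildMosaic1x2(ben[[take]], mal[[take]], layout, id)
        composites <- c(composites, list(comp))
        if (includeRotations && layout@kind == "two_by_two")
            composites <- c(composites,
                            rotationalArrangements(comp, rotationMode))
    }
    ann <- do.call(rbind, lapply(composites, function(cp)
        .annotationRows(imageId(cp), rois(cp))))
    list(composites = composites, annotations = ann)
}
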