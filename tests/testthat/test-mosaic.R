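test_that("balanceClasses oversamples the minority deterministically", {
    src <- c(lapply(1:3, function(i)
                 flatImage(paste0("b", i), 32, 32, roiBox(2, 2, 6, 6, "benign"))),
             lapply(1:5, function(i)
                 flatImage(paste0("m", i), 32, 32,
                           roiBox(2, 2, 6, 6, "malignant"))))
    out <- balanceClasses(src, seed = 3)
    labs <- vapply(out, diagnosis, character(1))
    expect_equal(sum(labs == "benign"), 5L)
    expect_equal(sum(labs == "malignant"), 5L)
    # majority untouched, originals preserved in order
    expect_identical(vapply(out[1:8], imageId, character(1)),
                     vapply(src, imageId, character(1)))
    # determinism
    out2 <- balanceClasses(src, seed = 3)
    expect_identical(vapply(out, imageId, character(1)),
                     vapply(out2, imageId, character(1)))
    # already balanced -> unchanged
    expect_identical(balanceClasses(src[c(1:3, 4:6)], seed = 1),
                     src[c(1:3, 4:6)])
    expect_error(balanceClasses(src[1:3], seed = 1), "malignant")
})

test_that("harmonizeTile scales, pads and transforms boxes as expected", {
    img <- flatImage("a", 100, 100, roiBox(10, 10, 20, 20, "benign"))
    h <- harmonizeTile(img, 50, 50)
    expect_equal(unlist(rois(h)[, 1:4]),
                 c(x = 5, y = 5, width = 10, height = 10))
    # scaled box still covers the same relative area (overlap = 100%)
    expect_equal(attr(h, "transform")$scale_x, 0.5)

    same <- harmonizeTile(img, 100, 100)          # identity
    expect_equal(pixels(same), pixels(img))
    expect_equal(rois(same), rois(img))

    wide <- flatImage("w", 200, 100, roiBox(0, 0, 40, 40, "benign"))
    hw <- harmonizeTile(wide, 100, 100)
    tr <- attr(hw, "transform")
    expect_equal(tr$scale_x, 0.5)
    expect_equal(tr$pad_y, 25L)                   # 25 px top and bottom
    expect_equal(tr$pad_x, 0L)
    expect_equal(imageWidth(hw), 100L)
    expect_equal(imageHeight(hw), 100L)
    # padded rows are background 0
    expect_true(all(pixels(hw)[1:25, ] == 0))

    tiny <- flatImage("t", 100, 100, roiBox(0, 0, 2, 2, "benign"))
    expect_error(harmonizeTile(tiny, 10, 10), "larger tile")
})

test_that("2x2 composites place boxes at tile offsets with labels intact", {
    s <- fourSources(100L)
    lay <- mosaicLayout("two_by_two", 100, 100)
    comp <- buildMosaic2x2(s$b, s$m, lay, "c1")
    bx <- rois(comp)
    expect_equal(nrow(bx), 4L)
    expect_setequal(paste(bx$x, bx$y),
                    c("10 10", "110 10", "10 110", "110 110"))
    expect_true(all(bx$width == 20 & bx$height == 20))
    expect_equal(sum(bx$label == "benign"), 2L)
    # benign boxes sit in cells (1,1) and (2,2)
    ben <- bx[bx$label == "benign", ]
    expect_setequal(paste(ben$x, ben$y), c("10 10", "110 110"))
    # rasterized composite ROI areas = sum of harmonized box areas
    areas <- vapply(seq_len(4), function(i)
        maskArea(boxToMask(bx[i, ], dim(pixels(comp)))), integer(1))
    expect_equal(sum(areas), 4L * 400L)
    # wrong class in a slot
    expect_error(buildMosaic2x2(s$m, s$b, lay), "expects a benign")
})

test_that("1x2 composites shift the right tile by the tile width", {
    s <- fourSources(100L)
    lay <- mosaicLayout("one_by_two", 100, 100)
    comp <- buildMosaic1x2(s$b[[1]], s$m[[1]], lay, "c12")
    expect_equal(imageWidth(comp), 200L)
    expect_equal(imageHeight(comp), 100L)
    bx <- rois(comp)
    expect_equal(bx$x[bx$label == "malignant"], 110)
    expect_equal(bx$x[bx$label == "benign"], 10)
    # swapped layout exchanges offsets
    swapped <- mosaicLayout("one_by_two", 100, 100,
                            placement = data.frame(row = c(1L, 1L),
                                                   col = c(1L, 2L),
                                                   slot = c("malignant",
                                                            "benign")))
    comp2 <- buildMosaic1x2(s$b[[1]], s$m[[1]], swapped)
    bx2 <- rois(comp2)
    expect_equal(bx2$x[bx2$label == "malignant"], 10)
    expect_equal(bx2$x[bx2$label == "benign"], 110)
})

test_that("tile rotations permute cells cyclically and preserve bookkeeping", {
    s <- fourSources(100L)
    comp <- buildMosaic2x2(s$b, s$m, mosaicLayout("two_by_two", 100, 100))
    rots <- rotationalArrangements(comp)
    expect_length(rots, 3L)
    placements <- lapply(c(list(comp), rots), function(cp) {
        pr <- provenance(cp)
        paste(pr$source_id, pr$cell_row, pr$cell_col, collapse = ";")
    })
    expect_equal(length(unique(unlist(placements))), 4L)  # pairwise distinct
    for (cp in rots) {
        expect_equal(sum(rois(cp)$label == "benign"), 2L)
        expect_equal(sum(rois(cp)$label == "malignant"), 2L)
    }
    # 180 degrees: each tile moved two cells along the ring (diagonal swap)
    pr0 <- provenance(comp); pr180 <- provenance(rots[[2]])
    for (i in seq_len(4)) {
        expect_equal(pr180$cell_row[i], 3L - pr0$cell_row[i])
        expect_equal(pr180$cell_col[i], 3L - pr0$cell_col[i])
    }
    # applying the 90-degree permutation four times returns to start
    r90x4 <- comp
    for (k in 1:4) r90x4 <- rotationalArrangements(r90x4)[[1]]
    expect_equal(provenance(r90x4)$cell_row, pr0$cell_row)
    expect_equal(provenance(r90x4)$cell_col, pr0$cell_col)
    expect_equal(rois(r90x4)$x, rois(comp)$x)
    # unsupported layout
    c12 <- buildMosaic1x2(s$b[[1]], s$m[[1]], mosaicLayout("one_by_two", 100, 100))
    expect_error(rotationalArrangements(c12), "2x2")
})

test_that("pixel-rotation mode transforms boxes consistently with the raster", {
    s <- fourSources(100L)
    comp <- buildMosaic2x2(s$b, s$m, mosaicLayout("two_by_two", 100, 100))
    rots <- rotationalArrangements(comp, mode = "pixels")
    shape <- dim(pixels(comp))
    for (cp in rots) {
        expect_equal(dim(pixels(cp)), shape)  # square composite
        expect_equal(sum(rois(cp)$label == "benign"), 2L)
        # recovered source boxes invert the rotation exactly (no scaling here)
        rec <- recoverSourceBoxes(cp)
        expect_equal(rec$x, rec$src_x)
        expect_equal(rec$y, rec$src_y)
        expect_equal(rec$width, rec$src_width)
        expect_equal(rec$height, rec$src_height)
    }
    # 90-degree raster content matches a direct rotation of the original
    m0 <- pixels(comp)
    expect_equal(pixels(rots[[1]]), t(m0[nrow(m0):1, ]))
})

test_that("provenance inversion recovers source boxes within 1 px", {
    set.seed(12)
    mk <- function(id, lab) {
        w <- sample(80:180, 1); h <- sample(80:180, 1)
        bw <- sample(15:30, 1); bh <- sample(15:30, 1)
        flatImage(id, w, h, roiBox(sample(0:(w - bw), 1),
                                   sample(0:(h - bh), 1), bw, bh, lab))
    }
    for (rep in 1:5) {
        comp <- buildMosaic2x2(
            list(mk("b1", "benign"), mk("b2", "benign")),
            list(mk("m1", "malignant"), mk("m2", "malignant")),
            mosaicLayout("two_by_two", 96, 96))
        for (cp in c(list(comp), rotationalArrangements(comp))) {
            rec <- recoverSourceBoxes(cp)
            expect_true(all(abs(rec$x - rec$src_x) <= 1))
            expect_true(all(abs(rec$y - rec$src_y) <= 1))
            expect_true(all(abs(rec$width - rec$src_width) <= 1))
            expect_true(all(abs(rec$height - rec$src_height) <= 1))
        }
    }
})

test_that("buildMosaicDataset counts, pairing and determinism", {
    s <- fourSources(64L)
    src <- c(s$b, s$m)
    lay <- mosaicLayout("two_by_two", 64, 64)
    withRot <- buildMosaicDataset(src, lay, seed = 2, includeRotations = TRUE)
    expect_length(withRot$composites, 4L)      # 1 base + 3 rotations
    expect_equal(nrow(withRot$annotations), 16L)
    noRot <- buildMosaicDataset(src, lay, seed = 2, includeRotations = FALSE)
    expect_length(noRot$composites, 1L)
    expect_equal(nrow(noRot$annotations), 4L)
    # same seed -> byte-identical annotation CSV
    f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
    writeAnnotations(buildMosaicDataset(src, lay, seed = 9)$annotations, f1)
    writeAnnotations(buildMosaicDataset(src, lay, seed = 9)$annotations, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    expect_error(buildMosaicDataset(s$b, lay, seed = 1), "no 'malignant'")
    expect_error(buildMosaicDataset(list(s$b[[1]], s$m[[1]]), lay, seed = 1),
                 "not enough images")
})
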