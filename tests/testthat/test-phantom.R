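test_that("phantoms are deterministic and carry exact ground-truth boxes", {
    p <- phantomParams(seed = 21)
    a <- generatePhantom(p, "malignant", "x", seed = 21)
    b <- generatePhantom(p, "malignant", "x", seed = 21)
    expect_identical(pixels(a), pixels(b))
    expect_identical(rois(a), rois(b))
    # ROI is the tight bounding box of the rendered support
    expect_equal(rois(a), tightBox(attr(a, "support"), "malignant"))
    # background speckle has mean intensity near 0.5
    expect_equal(mean(pixels(generatePhantom(p, "benign", "y", seed = 3))),
                 0.5, tolerance = 0.05)
})

test_that("class encodes orientation: benign wide, malignant tall", {
    p <- phantomParams(seed = 1)
    for (s in 1:8) {
        ben <- attr(generatePhantom(p, "benign", "b", seed = s), "nodule")
        mal <- attr(generatePhantom(p, "malignant", "m", seed = s + 50),
                    "nodule")
        expect_gt(ben$a / ben$b, 1)   # horizontal semi-axis longer
        expect_gte(mal$b / mal$a, 1)  # vertical semi-axis longer
    }
    # benign bounding boxes are wider than tall (no boundary perturbation)
    for (s in 1:5) {
        bx <- rois(generatePhantom(p, "benign", "b", seed = s))
        expect_gt(bx$width / bx$height, 1)
    }
})

test_that("irregularity amplitude roughens the boundary monotonically", {
    amps <- c(0.02, 0.12, 0.25)
    for (s in 1:5) {
        comp <- vapply(amps, function(a) {
            p <- phantomParams(irregularityAmplitude = a, seed = s)
            img <- generatePhantom(p, "malignant", "m", seed = s)
            shapeCompactness(attr(img, "support"))
        }, numeric(1))
        expect_true(all(diff(comp) > 0))
    }
})

test_that("degenerate settings are flagged, impossible ones refused", {
    p0 <- phantomParams(contrast = 0, seed = 2)
    expect_warning(img <- generatePhantom(p0, "benign", "inv", seed = 2),
                   "invisible")
    expect_equal(nrow(rois(img)), 1L)   # ROI still emitted
    big <- phantomParams(sizeRange = c(100, 120), seed = 1)
    expect_error(generatePhantom(big, "malignant", "big", seed = 1),
                 "cannot fit")
})

test_that("dataset generation writes consistent annotations and manifest", {
    p <- phantomParams(nBenign = 3, nMalignant = 5, seed = 8)
    ds <- generatePhantomDataset(p)
    expect_length(ds$images, 8L)
    expect_equal(nrow(ds$annotations), 8L)
    expect_equal(sum(ds$manifest$diagnosis == "malignant"), 5L)
    # same seed -> byte-identical CSV
    d1 <- tempfile(); d2 <- tempfile()
    generatePhantomDataset(p, dir = d1)
    generatePhantomDataset(p, dir = d2)
    a1 <- readBin(file.path(d1, "annotations.csv"), "raw",
                  file.size(file.path(d1, "annotations.csv")))
    a2 <- readBin(file.path(d2, "annotations.csv"), "raw",
                  file.size(file.path(d2, "annotations.csv")))
    expect_identical(a1, a2)
    # refuses to clobber without overwrite
    expect_error(generatePhantomDataset(p, dir = d1), "overwrite")
    expect_silent(generatePhantomDataset(p, dir = d1, overwrite = TRUE))
    unlink(c(d1, d2), recursive = TRUE)
})

test_that("test split fraction and imbalance are honored", {
    p <- phantomParams(nBenign = 50, nMalignant = 50, seed = 4)
    ds <- generatePhantomDataset(p, testFraction = 0.15)
    expect_equal(sum(ds$manifest$split == "test"), 15L)
    skew <- generatePhantomDataset(p, testFraction = 0.2,
                                   testBenignShare = 0.15)
    testRows <- skew$manifest[skew$manifest$split == "test", ]
    expect_equal(nrow(testRows), 20L)
    expect_equal(sum(testRows$diagnosis == "benign"), 3L)  # round(20 * 0.15)
})
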