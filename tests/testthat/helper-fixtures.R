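# shared fixtures: closed-form rectangle arithmetic (the independent oracle
# for the rasterized overlap metrics) and small deterministic image makers

rectIntersectArea <- function(b1, b2) {
    w <- min(b1$x + b1$width, b2$x + b2$width) - max(b1$x, b2$x)
    h <- min(b1$y + b1$height, b2$y + b2$height) - max(b1$y, b2$y)
    max(0, w) * max(0, h)
}

randomBoxOn <- function(gridW, gridH, label = "benign") {
    w <- sample.int(gridW - 1L, 1L)
    h <- sample.int(gridH - 1L, 1L)
    roiBox(sample.int(gridW - w, 1L) - 1L, sample.int(gridH - h, 1L) - 1L,
           w, h, label)
}

# a flat image with one box, for mosaic plumbing tests
flatImage <- function(id, w, h, box, value = 0.5) {
    annotatedImage(id, matrix(value, nrow = h, ncol = w), box)
}

# four tile-sized single-ROI sources (two per class)
fourSources <- function(tile = 100L) {
    box <- function(lab) roiBox(10, 10, 20, 20, lab)
    list(b = list(flatImage("b1", tile, tile, box("benign")),
                  flatImage("b2", tile, tile, box("benign"))),
         m = list(flatImage("m1", tile, tile, box("malignant")),
                  flatImage("m2", tile, tile, box("malignant"))))
}
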