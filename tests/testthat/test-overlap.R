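shape <- c(20, 20)
Rm <- boxToMask(roiBox(0, 0, 10, 10), shape)

test_that("overlapMetrics matches hand-computed cases", {
    same <- overlapMetrics(Rm, Rm)
    expect_equal(c(same$iou, same$ior, same$iod), c(100, 100, 100))
    disjoint <- overlapMetrics(Rm, boxToMask(roiBox(10, 10, 5, 5), shape))
    expect_equal(c(disjoint$iou, disjoint$ior, disjoint$iod), c(0, 0, 0))
    half <- overlapMetrics(Rm, boxToMask(roiBox(5, 0, 10, 10), shape))
    expect_equal(half$iou, 100 * 50 / 150, tolerance = 1e-12)
    expect_equal(half$ior, 50)
    expect_equal(half$iod, 50)
    expect_equal(half$area_I, 50L)
})

test_that("empty detections yield a flagged zero triple; empty ROI errors", {
    empty <- overlapMetrics(Rm, matrix(0L, 20, 20))
    expect_true(empty$empty_detection)
    expect_equal(c(empty$iou, empty$ior, empty$iod), c(0, 0, 0))
    expect_error(overlapMetrics(matrix(0L, 20, 20), Rm), "reference")
    expect_error(overlapMetrics(Rm, matrix(0L, 10, 10)), "mismatch")
})

test_that("ordering and harmonic identities hold on random mask pairs", {
    set.seed(17)
    for (i in 1:100) {
        g <- sample(10:30, 2)
        r <- randomBoxOn(g[1], g[2])
        d <- randomBoxOn(g[1], g[2])
        tri <- overlapMetrics(boxToMask(r, c(g[2], g[1])),
                              boxToMask(d, c(g[2], g[1])))
        expect_lte(tri$iou, min(tri$ior, tri$iod) + 1e-9)
        expect_gte(tri$iou, 0)
        expect_lte(max(tri$ior, tri$iod), 100)
        if (tri$area_I > 0) {
            expect_equal(100 / tri$iou, 100 / tri$ior + 100 / tri$iod - 1,
                         tolerance = 1e-9)
        }
        # symmetry: iou(R,D) = iou(D,R); ior(R,D) = iod(D,R)
        rev <- overlapMetrics(boxToMask(d, c(g[2], g[1])),
                              boxToMask(r, c(g[2], g[1])))
        if (!rev$empty_detection && !tri$empty_detection) {
            expect_equal(tri$iou, rev$iou)
            expect_equal(tri$ior, rev$iod)
        }
    }
})

test_that("the published attention-map worked example is internally consistent", {
    # reported triple for a multi-focus attention map: IoU 33.80%, IoR 85.82%,
    # IoD 35.80% — must satisfy the ordering bound and the harmonic identity
    iou <- 33.80; ior <- 85.82; iod <- 35.80
    expect_lte(iou, min(ior, iod))
    expect_equal(100 / iou, 100 / ior + 100 / iod - 1, tolerance = 1e-3)
})

test_that("overlapSummary averages per image, unweighted", {
    tri <- function(v) data.frame(iou = v, ior = v, iod = v)
    one <- rbind(tri(0), tri(100))
    expect_equal(overlapSummary(one)$iou, 50)
    expect_equal(overlapSummary(tri(33.333))$iou, 33.33)  # 2-decimal report
    many <- do.call(rbind, replicate(5, tri(42.42), simplify = FALSE))
    expect_equal(overlapSummary(many)$iou, 42.42)
    expect_equal(overlapSummary(many)$n, 5)
    expect_error(overlapSummary(tri(numeric(0))), "no overlap")
})

test_that("localizedFraction counts TP/TN separately with >= threshold", {
    rec <- data.frame(iou = c(10, 30, 90, 100, 20),
                      predicted = c("malignant", "malignant", "malignant",
                                    "benign", "malignant"),
                      gold = c("malignant", "malignant", "malignant",
                               "benign", "benign"))
    out <- localizedFraction(rec, threshold = 30)
    tp <- out[out$class == "TP", ]
    expect_equal(tp$n, 3)
    expect_equal(tp$localized, 2)         # iou 30 counts (>=), iou 10 does not
    expect_equal(tp$fraction, 100 * 2 / 3)
    tn <- out[out$class == "TN", ]
    expect_equal(tn$n, 1)
    expect_equal(tn$fraction, 100)
    # a class with no correct records is undefined, not 0
    onlyTP <- rec[rec$gold == "malignant" & rec$predicted == "malignant", ]
    out2 <- localizedFraction(onlyTP, 30)
    expect_true(is.na(out2$fraction[out2$class == "TN"]))
    expect_error(localizedFraction(rec, 0), "\\(0, 100\\]")
})
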