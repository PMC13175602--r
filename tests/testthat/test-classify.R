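test_that("classificationRates computes the three rates with NA on 0/0", {
    r <- classificationRates(confusionCounts(tp = 466, fn = 73, tn = 76,
                                             fp = 19))
    expect_equal(unname(r), c(0.8549, 0.8646, 0.8000))
    allPos <- classificationRates(confusionCounts(tp = 10))
    expect_equal(unname(allPos[c("accuracy", "sensitivity")]), c(1, 1))
    expect_true(is.na(allPos["specificity"]))
    eq <- classificationRates(confusionCounts(5, 5, 5, 5))
    expect_equal(unname(eq["accuracy"]), 0.5)
    fromLabels <- confusionCounts(
        predicted = c("malignant", "benign", "malignant", "benign"),
        gold = c("malignant", "malignant", "benign", "benign"))
    expect_equal(counts(fromLabels), c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
})

test_that("rates reconstructed from sensitivity/specificity round-trip", {
    set.seed(31)
    for (i in 1:25) {
        nPos <- sample(50:600, 1); nNeg <- sample(20:200, 1)
        sens <- runif(1); spec <- runif(1)
        tp <- round(sens * nPos); tn <- round(spec * nNeg)
        cc <- confusionCounts(tp = tp, fn = nPos - tp, tn = tn,
                              fp = nNeg - tn)
        r <- classificationRates(cc)
        expect_equal(unname(r["sensitivity"]), round(tp / nPos, 4))
        expect_equal(unname(r["specificity"]), round(tn / nNeg, 4))
        # accuracy = prevalence-weighted combination of sens and spec
        expect_equal(unname(r["accuracy"]),
                     round((tp / nPos) * nPos / (nPos + nNeg) +
                           (tn / nNeg) * nNeg / (nPos + nNeg), 4))
    }
})

test_that("anchor-cell aggregation uses the (1,1) region", {
    lay <- mosaicLayout("two_by_two", 100, 100)
    det <- function(boxes) detectionResult("c", boxes)
    b <- function(x, y, lab, conf)
        cbind(roiBox(x, y, 20, 20, lab), confidence = conf)
    # single detection centered in (1,1)
    one <- aggregateAnchorCell(det(b(30, 30, "benign", 0.8)), lay)
    expect_equal(one$label, "benign")
    expect_false(one$fallback)
    # detections in all four cells: only (1,1) matters
    all4 <- det(rbind(b(30, 30, "benign", 0.6), b(130, 30, "malignant", 0.99),
                      b(30, 130, "malignant", 0.99),
                      b(130, 130, "malignant", 0.99)))
    expect_equal(aggregateAnchorCell(all4, lay)$label, "benign")
    # two detections in (1,1): highest confidence wins
    two <- det(rbind(b(10, 10, "malignant", 0.9), b(50, 50, "benign", 0.4)))
    expect_equal(aggregateAnchorCell(two, lay)$label, "malignant")
    # nothing in (1,1): falls back to the vote, flagged
    far <- det(b(130, 130, "benign", 0.7))
    res <- aggregateAnchorCell(far, lay)
    expect_true(res$fallback)
    expect_equal(res$label, "benign")
    # empty detection set abstains
    expect_true(is.na(aggregateAnchorCell(det(emptyDetectionTable()),
                                          lay)$label))
    # center exactly on the cell boundary goes to the lower-index cell
    onEdge <- det(b(90, 90, "benign", 0.9))  # center (100,100)
    expect_equal(aggregateAnchorCell(onEdge, lay)$label, "benign")
    expect_false(aggregateAnchorCell(onEdge, lay)$fallback)
})

test_that("vote aggregation is confidence-weighted with malignant ties", {
    det <- function(boxes) detectionResult("c", boxes)
    b <- function(lab, conf) cbind(roiBox(0, 0, 5, 5, lab),
                                   confidence = conf)
    maj <- det(rbind(b("malignant", 0.5), b("malignant", 0.5),
                     b("malignant", 0.5), b("benign", 0.5)))
    expect_equal(aggregateVote(maj)$label, "malignant")
    expect_equal(aggregateVote(det(b("benign", 0.3)))$label, "benign")
    tie <- det(rbind(b("benign", 0.5), b("malignant", 0.5)))
    expect_equal(aggregateVote(tie)$label, "malignant")
    expect_true(is.na(aggregateVote(det(emptyDetectionTable()))$label))
    # permutation invariance
    boxes <- rbind(b("malignant", 0.9), b("benign", 0.2), b("benign", 0.8),
                   b("malignant", 0.3))
    set.seed(5)
    for (i in 1:5) {
        perm <- boxes[sample.int(nrow(boxes)), ]
        expect_equal(aggregateVote(det(perm))$label,
                     aggregateVote(det(boxes))$label)
    }
})

test_that("epochWindowStats reports mean and sample sd over the window", {
    series <- data.frame(epoch = 1:40, value = rep(0.5, 40))
    series$value[31:40] <- c(0.8, 0.9, rep(0.85, 8))
    flat <- epochWindowStats(data.frame(epoch = 1:10, value = 0.7), 1:10)
    expect_equal(flat$sd, 0)
    two <- epochWindowStats(data.frame(epoch = 1:2, value = c(0.8, 0.9)), 1:2)
    expect_equal(two$mean, 0.85)
    expect_equal(two$sd, 0.0707107, tolerance = 1e-6)
    one <- epochWindowStats(series, 31)
    expect_equal(one$mean, 0.8)
    expect_equal(one$sd, 0)
    expect_true(one$degenerate)
    expect_error(epochWindowStats(series, 35:45), "outside")
    # named metric column
    s2 <- data.frame(epoch = 1:5, accuracy = seq(0.1, 0.5, by = 0.1))
    expect_equal(epochWindowStats(s2, 2:4, metric = "accuracy")$mean, 0.3)
    expect_error(epochWindowStats(s2, 2:4, metric = "auc"), "no column")
})
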