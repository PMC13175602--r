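## Synthetic ultrasound nodule phantoms: speckle-textured grayscale images,
## one hypoechoic nodule each, a tight ROI box, and a benign/malignant label.
## Benign nodules are smooth, wider-than-tall ellipses with sharp margins;
## malignant nodules are taller-than-wide with a sinusoidal radial boundary
## perturbation and a blurred margin — a deliberate caricature of standard
## sonographic risk features, not a clinical model.

#' Phantom generator parameters
#'
#' @param imageWidth,imageHeight raster size in pixels.
#' @param nBenign,nMalignant image counts for [generatePhantomDataset()].
#' @param sizeRange nodule mean-diameter range in pixels (sampled uniformly).
#' @param contrast intensity drop of the nodule relative to background, in
#'   \[0, 1\].
#' @param speckleStrength relative amplitude of the multiplicative speckle
#'   texture (>= 0).
#' @param speckleGrain Gaussian blur sigma (px) setting the speckle
#'   correlation length.
#' @param axisRatioRange range of the ellipse axis ratio (major/minor);
#'   benign nodules put the major axis horizontal, malignant vertical.
#' @param irregularityAmplitude relative amplitude of the sinusoidal radial
#'   boundary perturbation applied to malignant nodules (>= 0).
#' @param marginBlur Gaussian sigma (px) blurring the malignant nodule
#'   margin; benign margins stay sharp.
#' @param seed integer master seed; every output is fully determined by it.
#' @return a list of class `PhantomParams`.
#' @export
phantomParams <- function(imageWidth = 128L, imageHeight = 128L,
                          nBenign = 20L, nMalignant = 20L,
                          sizeRange = c(26, 44), contrast = 0.35,
                          speckleStrength = 0.25, speckleGrain = 1.5,
                          axisRatioRange = c(1.25, 1.5),
                          irregularityAmplitude = 0.15, marginBlur = 1.5,
                          seed = 1L) {
    p <- list(imageWidth = as.integer(imageWidth),
              imageHeight = as.integer(imageHeight),
              nBenign = as.integer(nBenign),
              nMalignant = as.integer(nMalignant),
              sizeRange = sizeRange, contrast = contrast,
              speckleStrength = speckleStrength,
              speckleGrain = speckleGrain,
              axisRatioRange = axisRatioRange,
              irregularityAmplitude = irregularityAmplitude,
              marginBlur = marginBlur, seed = as.integer(seed))
    stopifnot(p$contrast >= 0, p$contrast <= 1, p$speckleStrength >= 0,
              p$irregularityAmplitude >= 0,
              p$sizeRange[1] > 4, p$sizeRange[2] >= p$sizeRange[1])
    class(p) <- c("PhantomParams", "list")
    p
}

#' High-contrast, low-speckle phantom preset
#'
#' The "easy" configuration used for end-to-end pipeline checks: nodules are
#' clearly hypoechoic against mild speckle, so a threshold detector can
#' localize them tightly.
#'
#' @param ... overrides passed to [phantomParams()].
#' @return a `PhantomParams` list.
#' @export
easyPhantomParams <- function(...) {
    defaults <- list(contrast = 0.55, speckleStrength = 0.12)
    args <- utils::modifyList(defaults, list(...))
    do.call(phantomParams, args)
}

.speckleField <- function(h, w, strength, grain) {
    raw <- matrix(stats::rexp(h * w), nrow = h)
    sm <- .ebMatrix(EBImage::gblur(EBImage::Image(raw), sigma = grain))
    sm <- sm / mean(sm)
    bg <- 0.5 * (1 + strength * (sm - 1))
    pmin(pmax(bg, 0.02), 0.98)
}

#' Generate one annotated phantom image
#'
#' Fully deterministic given `seed`: a speckle background with mean intensity
#' near 0.5, one hypoechoic elliptical nodule whose shape encodes the class
#' (see package description), and the tight bounding box of the rendered
#' nodule support as the ROI. The binary support mask and the sampled nodule
#' geometry are attached as attributes `"support"` and `"nodule"`.
#'
#' @param params a `PhantomParams` list.
#' @param diagnosis `"benign"` or `"malignant"`.
#' @param imageId identifier for the image.
#' @param seed seed for this image; defaults to `params$seed`.
#' @return an [AnnotatedImage-class] with exactly one ROI.
#' @export
generatePhantom <- function(params, diagnosis = c("benign", "malignant"),
                            imageId = "phantom", seed = params$seed) {
    diagnosis <- match.arg(diagnosis)
    W <- params$imageWidth; H <- params$imageHeight
    maxDiam <- params$sizeRange[2] *
        (1 + params$irregularityAmplitude) * max(params$axisRatioRange)
    if (maxDiam + 8 > min(W, H))
        stop(sprintf(
            "nodule (up to %.0f px) cannot fit a %d x %d image; shrink sizeRange",
            maxDiam, W, H))
    set.seed(as.integer(seed))
    bg <- .speckleField(H, W, params$speckleStrength, params$speckleGrain)
    diam <- runif(1, params$sizeRange[1], params$sizeRange[2])
    ratio <- runif(1, params$axisRatioRange[1], params$axisRatioRange[2])
    ## equal-area split of the mean diameter into the two semi-axes
    if (diagnosis == "benign") {
        a <- diam / 2 * sqrt(ratio); b <- diam / 2 / sqrt(ratio)
    } else {
        a <- diam / 2 / sqrt(ratio); b <- diam / 2 * sqrt(ratio)
    }
    amp <- if (diagnosis == "malignant") params$irregularityAmplitude else 0
    reach <- (1 + amp) * c(a, b)
    cx <- runif(1, reach[1] + 3, W - reach[1] - 3)
    cy <- runif(1, reach[2] + 3, H - reach[2] - 3)
    lobes <- sample(5:9, 1)
    phase <- runif(1, 0, 2 * pi)
    xs <- matrix(rep(seq_len(W) - 0.5, each = H), nrow = H)
    ys <- matrix(rep(seq_len(H) - 0.5, times = W), nrow = H)
    dx <- (xs - cx) / a; dy <- (ys - cy) / b
    rho <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    support <- (rho <= 1 + amp * sin(lobes * theta + phase)) * 1L
    soft <- support
    if (diagnosis == "malignant" && params$marginBlur > 0)
        soft <- .ebMatrix(EBImage::gblur(EBImage::Image(support * 1),
                                         sigma = params$marginBlur))
    px <- pmin(pmax(bg * (1 - params$contrast * pmin(pmax(soft, 0), 1)),
                    0), 1)
    if (params$contrast == 0)
        warning("contrast is 0: the nodule is invisible; ROI still emitted")
    box <- tightBox(support, label = diagnosis)
    img <- annotatedImage(imageId, px, box, diagnosis)
    attr(img, "support") <- support
    attr(img, "nodule") <- list(cx = cx, cy = cy, a = a, b = b, amp = amp,
                                lobes = lobes, phase = phase)
    img
}

#' Generate a phantom dataset with a train/test split manifest
#'
#' Produces `nBenign + nMalignant` phantoms (per-image seeds derived from the
#' master seed), the flat annotation table, and a manifest assigning each
#' image to the train or test split. By default the test split is stratified
#' proportionally to class; `testBenignShare` can skew it (e.g. 0.15 to mimic
#' a malignant-heavy clinical test split). When `dir` is given, images are
#' written as PNGs alongside `annotations.csv` and `manifest.csv`.
#'
#' @param params a `PhantomParams` list (counts, geometry, seed).
#' @param dir optional output directory.
#' @param testFraction fraction of images assigned to the test split.
#' @param testBenignShare optional benign share of the test split in (0, 1);
#'   `NULL` keeps class-proportional stratification.
#' @param overwrite overwrite existing files in `dir`.
#' @return list with `images` (list of [AnnotatedImage-class]),
#'   `annotations` (data.frame) and `manifest` (data.frame `image_id,
#'   diagnosis, split`).
#' @export
generatePhantomDataset <- function(params, dir = NULL, testFraction = 0.15,
                                   testBenignShare = NULL,
                                   overwrite = FALSE) {
    stopifnot(params$nBenign > 0L, params$nMalignant > 0L,
              testFraction >= 0, testFraction < 1)
    labels <- c(rep("benign", params$nBenign),
                rep("malignant", params$nMalignant))
    images <- vector("list", length(labels))
    for (i in seq_along(labels)) {
        id <- sprintf("phantom_%s_%03d", substr(labels[i], 1, 3), i)
        images[[i]] <- generatePhantom(params, labels[i], id,
                                       seed = params$seed + i)
    }
    ann <- do.call(rbind, lapply(images, function(im)
        .annotationRows(imageId(im), rois(im))))
    ids <- vapply(images, imageId, character(1))
    nTest <- round(testFraction * length(ids))
    nTestB <- if (is.null(testBenignShare)) {
        round(nTest * params$nBenign / length(ids))
    } else round(nTest * testBenignShare)
    nTestB <- min(nTestB, params$nBenign)
    nTestM <- min(nTest - nTestB, params$nMalignant)
    set.seed(params$seed + 100003L)
    testIdx <- c(sample(which(labels == "benign"), nTestB),
                 sample(which(labels == "malignant"), nTestM))
    manifest <- data.frame(image_id = ids, diagnosis = labels,
                           split = ifelse(seq_along(ids) %in% testIdx,
                                          "test", "train"))
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        paths <- c(file.path(dir, paste0(ids, ".png")),
                   file.path(dir, c("annotations.csv", "manifest.csv")))
        if (!overwrite && any(file.exists(paths)))
            stop(sprintf("output exists in '%s'; set overwrite = TRUE", dir))
        for (im in images)
            writeImagePNG(pixels(im),
                          file.path(dir, paste0(imageId(im), ".png")))
        writeAnnotations(ann, file.path(dir, "annotations.csv"))
        write.csv(manifest, file.path(dir, "manifest.csv"),
                  row.names = FALSE, quote = FALSE)
    }
    list(images = images, annotations = ann, manifest = manifest)
}

#' Boundary compactness of a binary shape
#'
#' Polsby-Popper style compactness `perimeter^2 / (4 * pi * area)`; 1 for a
#' disc, larger for irregular boundaries. Used to quantify how the
#' irregularity amplitude roughens the phantom nodule margin and by the
#' reference detector's shape rule.
#'
#' @param mask binary 0/1 matrix with a single foreground shape.
#' @return numeric compactness >= (approximately) 1.
#' @export
shapeCompactness <- function(mask) {
    lab <- EBImage::bwlabel(mask)
    feat <- EBImage::computeFeatures.shape(lab)
    if (is.null(feat) || nrow(feat) == 0L)
        stop("mask has no foreground to measure")
    biggest <- which.max(feat[, "s.area"])
    unname(feat[biggest, "s.perimeter"]^2 /
           (4 * pi * feat[biggest, "s.area"]))
}
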