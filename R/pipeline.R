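## Reproducible runs over the on-disk dialects (PNG images, annotation /
## detection CSVs, YAML run configs). Each run* function takes a config list
## (or the path of a YAML file with the same fields), writes its outputs
## plus a run.yaml manifest recording the config and package version, and is
## idempotent given a fixed seed and inputs. These functions are the
## subcommand surface: the thin wrapper in inst/scripts/mosaicroi maps
## `synth`, `mosaic`, `detect`, `eval-overlap` and `eval-classify` onto them.

.loadConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    config
}

.writeManifest <- function(dir, subcommand, config) {
    manifest <- list(subcommand = subcommand, config = config,
                     package = "MosaicROI",
                     version = as.character(utils::packageVersion("MosaicROI")))
    yaml::write_yaml(manifest, file.path(dir, "run.yaml"))
}

.ensureDir <- function(dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    dir
}

#' Load annotated images from a directory
#'
#' Reads `annotations.csv` (annotation dialect) and one PNG per `image_id`
#' from `dir`. The image-level diagnosis is taken from `manifest.csv` when
#' present, else from the single ROI label. Missing images are reported by
#' id.
#'
#' @param dir directory holding PNGs and `annotations.csv`.
#' @return list of [AnnotatedImage-class].
#' @export
loadAnnotatedImages <- function(dir) {
    ann <- readAnnotations(file.path(dir, "annotations.csv"))
    manifestPath <- file.path(dir, "manifest.csv")
    diagTable <- if (file.exists(manifestPath))
        read.csv(manifestPath, stringsAsFactors = FALSE) else NULL
    ids <- unique(ann$image_id)
    lapply(ids, function(id) {
        path <- file.path(dir, paste0(id, ".png"))
        if (!file.exists(path))
            stop(sprintf("image '%s' listed in annotations but %s is missing",
                         id, path))
        boxes <- ann[ann$image_id == id,
                     c("x", "y", "width", "height", "label")]
        diag <- if (!is.null(diagTable) && id %in% diagTable$image_id)
            diagTable$diagnosis[match(id, diagTable$image_id)]
        else if (nrow(boxes) == 1L) as.character(boxes$label[1L])
        else "malignant"
        annotatedImage(id, readImagePNG(path), boxes, diag)
    })
}

#' Pipeline runs over on-disk datasets
#'
#' `runSynth` generates a phantom dataset; `runMosaic` builds composites from
#' an annotated image directory; `runDetect` runs the reference detector over
#' every annotated image; `runEvalOverlap` scores detections (or top-k
#' thresholded score maps) against the reference ROIs; `runEvalClassify`
#' aggregates detections to image-level labels and reports
#' accuracy/sensitivity/specificity (plus epoch-window statistics when an
#' epoch series is supplied). See the fields of each function's `config`
#' below; every function accepts a YAML path in place of the list.
#'
#' @param config a named list or path to a YAML file.
#' @return the main in-memory result of the step, invisibly (outputs are
#'   written to `config$out`).
#' @name pipeline
NULL

#' @describeIn pipeline fields: `out`, `nBenign`, `nMalignant`, `seed`,
#'   `testFraction`, `easy` (use [easyPhantomParams()]), plus any
#'   [phantomParams()] override.
#' @export
runSynth <- function(config) {
    config <- .loadConfig(config)
    out <- .ensureDir(config$out)
    keep <- intersect(names(config), names(formals(phantomParams)))
    params <- if (isTRUE(config$easy)) do.call(easyPhantomParams, config[keep])
              else do.call(phantomParams, config[keep])
    res <- generatePhantomDataset(
        params, dir = out,
        testFraction = if (is.null(config$testFraction)) 0.15
                       else config$testFraction,
        testBenignShare = config$testBenignShare,
        overwrite = isTRUE(config$overwrite))
    .writeManifest(out, "synth", config)
    invisible(res)
}

#' @describeIn pipeline fields: `in`, `out`, `layout` (`two_by_two` /
#'   `one_by_two`), `tileWidth`, `tileHeight`, `seed`, `rotations`,
#'   `rotationMode`.
#' @export
runMosaic <- function(config) {
    config <- .loadConfig(config)
    out <- .ensureDir(config$out)
    sources <- loadAnnotatedImages(config[["in"]])
    lay <- mosaicLayout(
        if (is.null(config$layout)) "two_by_two" else config$layout,
        tileWidth = if (is.null(config$tileWidth)) 128L else config$tileWidth,
        tileHeight = if (is.null(config$tileHeight)) 128L
                     else config$tileHeight)
    res <- buildMosaicDataset(
        sources, lay,
        seed = if (is.null(config$seed)) 1L else config$seed,
        includeRotations = !isFALSE(config$rotations),
        rotationMode = if (is.null(config$rotationMode)) "tiles"
                       else config$rotationMode)
    for (cp in res$composites)
        writeImagePNG(pixels(cp), file.path(out, paste0(imageId(cp), ".png")))
    writeAnnotations(res$annotations, file.path(out, "annotations.csv"))
    .writeManifest(out, "mosaic", config)
    invisible(res)
}

#' @describeIn pipeline fields: `in`, `out`, plus any [detectorConfig()]
#'   override.
#' @export
runDetect <- function(config) {
    config <- .loadConfig(config)
    out <- .ensureDir(config$out)
    images <- loadAnnotatedImages(config[["in"]])
    keep <- intersect(names(config), names(formals(detectorConfig)))
    cfg <- do.call(detectorConfig, config[keep])
    dets <- lapply(images, detectNodules, config = cfg)
    writeDetections(dets, file.path(out, "detections.csv"))
    .writeManifest(out, "detect", config)
    invisible(dets)
}

#' @describeIn pipeline fields: `in` (annotated images), `out`, and either
#'   `detections` (a detections.csv path) or `scoremaps` (a directory of
#'   `<image_id>.csv` score grids) with `k` (percent list, default
#'   30/50/70). Writes `per_image.csv` and `summary.json`.
#' @export
runEvalOverlap <- function(config) {
    config <- .loadConfig(config)
    out <- .ensureDir(config$out)
    images <- loadAnnotatedImages(config[["in"]])
    records <- NULL
    if (!is.null(config$scoremaps)) {
        ks <- if (is.null(config$k)) c(30, 50, 70) else unlist(config$k)
        if (any(ks <= 0 | ks > 100))
            stop("k values must be percentages in (0, 100]")
        for (img in images) {
            scores <- readScoreMap(file.path(config$scoremaps,
                                             paste0(imageId(img), ".csv")))
            refMask <- detectionsToMask(rois(img), dim(pixels(img)))
            for (k in ks) {
                reg <- topkMask(scores, k)
                tri <- overlapMetrics(refMask, regionMask(reg))
                tri$image_id <- imageId(img)
                tri$k <- k
                tri$k_realized <- kRealized(reg)
                records <- rbind(records, tri)
            }
        }
        summary <- lapply(split(records, records$k), overlapSummary)
        names(summary) <- paste0("top", names(summary))
    } else {
        detTable <- readDetections(config$detections)
        detList <- splitDetections(detTable)
        for (img in images) {
            det <- detList[[imageId(img)]]
            if (is.null(det)) det <- detectionResult(imageId(img))
            records <- rbind(records, overlapPerNodule(img, det))
        }
        summary <- list(overall = overlapSummary(records),
                        localized = localizedFraction(
                            records,
                            threshold = if (is.null(config$iouThreshold)) 30
                                        else config$iouThreshold))
    }
    write.csv(records, file.path(out, "per_image.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    .writeManifest(out, "eval-overlap", config)
    invisible(list(records = records, summary = summary))
}

#' @describeIn pipeline fields: `out`, and either `predictions` (CSV
#'   `image_id,predicted,gold`) or `detections` plus `gold` (annotations or
#'   manifest CSV) with `aggregation` (`"vote"` or `"anchor"`, the latter
#'   needing `tileWidth`/`tileHeight`); optional `epochSeries` CSV
#'   `epoch,accuracy,sensitivity,specificity` with `window` (e.g. `31:40`
#'   as a two-element list). Writes `metrics.json` and `confusion.csv`.
#' @export
runEvalClassify <- function(config) {
    config <- .loadConfig(config)
    out <- .ensureDir(config$out)
    if (!is.null(config$predictions)) {
        preds <- read.csv(config$predictions, stringsAsFactors = FALSE)
    } else {
        detList <- splitDetections(readDetections(config$detections))
        goldTab <- read.csv(config$gold, stringsAsFactors = FALSE)
        goldCol <- if ("diagnosis" %in% names(goldTab)) "diagnosis"
                   else "label"
        lay <- mosaicLayout(
            "two_by_two",
            tileWidth = if (is.null(config$tileWidth)) 128L
                        else config$tileWidth,
            tileHeight = if (is.null(config$tileHeight)) 128L
                         else config$tileHeight)
        preds <- do.call(rbind, lapply(names(detList), function(id) {
            agg <- if (identical(config$aggregation, "anchor"))
                aggregateAnchorCell(detList[[id]], lay)
            else aggregateVote(detList[[id]])
            data.frame(image_id = id, predicted = agg$label,
                       gold = goldTab[[goldCol]][
                           match(id, goldTab$image_id)])
        }))
    }
    kept <- preds[!is.na(preds$predicted) & !is.na(preds$gold), ]
    cc <- confusionCounts(predicted = kept$predicted, gold = kept$gold)
    metrics <- as.list(classificationRates(cc))
    metrics$counts <- as.list(counts(cc))
    metrics$abstained <- sum(is.na(preds$predicted))
    if (!is.null(config$epochSeries)) {
        series <- read.csv(config$epochSeries, stringsAsFactors = FALSE)
        window <- seq(config$window[[1]], config$window[[2]])
        metrics$epoch_window <- lapply(
            setNames(nm = intersect(c("accuracy", "sensitivity",
                                      "specificity"), names(series))),
            function(m) epochWindowStats(series, window, metric = m)[
                c("mean", "sd", "n")])
    }
    write.csv(data.frame(t(counts(cc))), file.path(out, "confusion.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    .writeManifest(out, "eval-classify", config)
    invisible(metrics)
}
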