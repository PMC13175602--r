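# MosaicROI

Radiologist-drawn regions of interest (ROIs) are expensive, and when they are
available it matters whether a model trained with them actually *looks* at
them. MosaicROI is an R toolkit for the input-construction and evaluation
side of that question in grayscale ultrasound nodule imaging. It is aimed at
researchers who train detection/classification networks elsewhere and need,
on this side, exact and reproducible bookkeeping:

- **Mosaic composite inputs.** Fixed-layout 1×2 and 2×2 composites that
  combine benign and malignant nodule images in one raster, with class
  balancing by oversampling, deterministic pairing, tile-permutation
  "rotational" arrangements, and exact transformation of every ROI box into
  composite coordinates (upper-left corner shifted by the tile offset, width
  and height preserved). Full per-tile provenance makes every composite box
  traceable back to its source image.
- **Attention regionization.** Thresholding a non-negative score map (e.g. a
  Grad-CAM heatmap) at its top-*k*% of pixels by rank, with deterministic tie
  handling, producing the binary detected region *D*.
- **Localization metrics.** With *R* the reference ROI and *D* the detected
  region, all ×100:

  IoU = |R∩D| / |R∪D|,  IoR = |R∩D| / |R|,  IoD = |R∩D| / |D|

  plus dataset means, and the fraction of correctly classified images with
  IoU ≥ 30% (the practical "did it look at the nodule" criterion), reported
  separately for true positives and true negatives (malignant = positive).
- **Classification evaluation.** Accuracy / sensitivity / specificity from
  confusion counts; region-to-image aggregation for 2×2 composites by the
  (1,1) anchor-cell rule or by confidence-weighted vote; mean ± sd reporting
  over a late epoch window (e.g. epochs 31–40).
- **Synthetic phantoms and a reference detector.** A deterministic speckle
  phantom generator (one hypoechoic nodule per image, tight ROI, label
  encoded in shape: benign wide and smooth, malignant tall and irregular)
  and a rule-based threshold detector, so the full
  detect → overlap → aggregate → rates pipeline runs without clinical data.

Boxes are 0-based, half-open, x = column / y = row, origin top-left; a
converter handles 1-based inclusive annotations. Images are 8/16-bit
grayscale PNG normalized to [0, 1]; annotations are CSV
(`image_id,x,y,width,height,label`), detections add a `confidence` column.

## Worked example

```r
library(MosaicROI)

params <- easyPhantomParams(nBenign = 4, nMalignant = 4, seed = 2)
ds  <- generatePhantomDataset(params)
mos <- buildMosaicDataset(ds$images, mosaicLayout("two_by_two", 128, 128),
                          seed = 2, includeRotations = TRUE)
cp  <- mos$composites[[1]]
det <- detectNodules(cp)
det
#> DetectionResult 'mosaic_0001': 4 box(es)
#>     x   y width height     label confidence
#> 1  18 158    37     46 malignant     0.6528
#> 2  72   5    50     36    benign     0.6940
#> 3 189  66    35     50 malignant     0.6637
#> 4 203 173    36     29    benign     0.6727

recs <- overlapPerNodule(cp, det)
overlapSummary(recs)
#>     iou   ior   iod n
#> 1 93.63 98.98 94.62 4

aggregateAnchorCell(det, layout(cp))$label
#> [1] "benign"
```

The detector found all four nodules of the composite within a pixel or two
of the reference boxes (mean IoU 93.6%, i.e. detected and reference regions
share ~94% of their union), labeled each correctly, and the (1,1) anchor
cell — benign by the default placement — yields the image-level call.

The same steps run from the shell via the thin wrapper
`inst/scripts/mosaicroi` (subcommands `synth`, `mosaic`, `detect`,
`eval-overlap`, `eval-classify`, each driven by a YAML config and writing a
`run.yaml` manifest).

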