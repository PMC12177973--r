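# stclean

Cleaning of whole-slide H&E images from spot-based spatial
transcriptomics platforms (10x Visium and relatives), in R.

Visium slides print a square frame of small circular **fiducial
markers** around the capture area. On real sections these markers
overlap tissue, get mistaken for cells by segmentation tools, and
mislead tissue detectors and image registration; the blank background
adds stain noise, and tissue-microarray slides carry several
disconnected pieces. `stclean` removes these artifacts with a
four-stage pipeline:

1. **Marker segmentation** — a customised encoder–decoder network
   (channels 3→32→64→128→256 down, 256→128→64→32→16 up, additive skips,
   the input image concatenated onto the final 16 channels to form a
   19-channel pre-head map) predicts a per-pixel marker probability.
   Training minimises
   `L = λ·L_dice + (1−λ)·L_focal` with `λ = 0.9`, Dice smoothing
   `ε = 1`, focal `α = 0.95`, `γ = 3`, using Adam
   (`lr = 1e-4, β₁ = 0.5, β₂ = 0.999`), difficulty-weighted sampling
   (slides with marker–tissue overlap factor > 0.8 visited 3× per
   epoch, 0.3–0.8 visited 2×) and flip/scale/rotation/brightness/blur
   augmentation. The network, backprop and optimiser are implemented
   in RcppArmadillo — no deep-learning framework is required.
2. **Restoration** — masked marker regions are inpainted by a classical
   harmonic fill (pluggable backend registry); pixels outside the mask
   are bit-identical to the input.
3. **Tissue detection** — a light saliency variant of the same network
   separates tissue from background at a 320×320 working size, with an
   automatic 1000×1000 second pass for tissue smaller than 100×100 px.
4. **Segregation** — the tissue probability mask is binarized at 0.8,
   8-connected components are labelled and pieces under 20 px dropped.

The package also ships a seeded **synthetic slide generator** with full
ground truth (marker circles and masks, tissue masks, component
counts), classical baselines (Hough circle transform, Otsu
thresholding, vendor-overlay red-circle extraction), a 12-fold
cross-validation splitter, and the full evaluation suite: IoU,
Hausdorff distance, perimeter ratio, component difference, SSIM,
mutual information, multi-class Dice, adjusted Rand index, and
nine cell-morphology descriptors.

## Worked example

Train the two learned stages on synthetic slides and clean a held-out
slide end to end:

```r
library(stclean)

spec <- synthetic_spec(image_size = 160, markers_per_side = 7,
                       marker_radius = 6, deformation = 3, seed = 100)
corpus <- generate_corpus(8, spec, mix = c(hard = 0.25, moderate = 0.375,
                                           easy = 0.375))
marker_net <- fit_marker_net(corpus,
                             train = train_config(epochs = 5,
                                                  tile_size = 160, seed = 1),
                             augment = augment_config())

tissue_corpus <- lapply(1:10, function(i)
  generate_sample(synthetic_spec(image_size = 160, markers_per_side = 0,
                                 n_tissue_blobs = (i - 1) %% 3 + 1,
                                 overlap_factor = 0, seed = 200 + i)))
tissue_net <- fit_tissue_net(tissue_corpus, working_size = 160, epochs = 8)

slide <- generate_sample(synthetic_spec(image_size = 160,
                                        markers_per_side = 7,
                                        marker_radius = 6,
                                        n_tissue_blobs = 2,
                                        overlap_factor = 0.3, seed = 999))
cfg <- pipeline_config(marker_model = marker_net, tissue_model = tissue_net,
                       tissue = tissue_config(working_size = 160,
                                              small_trigger = 1))
result <- run_pipeline(slide$image, cfg)
evaluate_run(result, list(marker_mask = slide$markers$mask,
                          tissue_mask = slide$tissue_mask))
```

```
<metric_report>
  marker_iou   0.8171
  tissue_iou   0.7985
  tissue_hausdorff 8
  tissue_perim_ratio 0.9548
  comp_diff    0
```

Marker IoU 0.82 means the predicted marker mask covers four fifths of
the union with the gold circles after only five training epochs
(longer training pushes it above 0.9); a perimeter ratio near 1 and a
Hausdorff distance of 8 px say the tissue boundary is neither over-
nor under-segmented; component difference 0 means the pipeline
recovered exactly the two disconnected tissue pieces the generator
rendered. (Numbers printed by this exact script.)

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end to end from scratch against the installed
package: it generates seeded synthetic corpora, trains the marker and
tissue networks, runs the four-stage pipeline on a held-out slide,
prints the metric report, and writes the results JSON to `--out`.

A command-line front end over the same functions is installed at
`inst/cli/stclean.R` (`simulate`, `train`, `detect`, `restore`,
`tissue`, `segregate`, `evaluate`).

See `vignettes/methods.Rmd` for the model, its assumptions, parameter
defaults, the synthetic world the generator emulates, and known
limitations.
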