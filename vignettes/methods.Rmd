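---
title: "Cleaning spot-based spatial transcriptomics histology images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning spot-based spatial transcriptomics histology images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-slide H&E images from spot-based spatial transcriptomics platforms
(10x Visium and relatives) carry three technical artifacts that disturb
downstream image analysis: a printed square frame of small circular
*fiducial markers* used by the vendor for alignment, which overlaps
tissue on badly placed sections and is readily mistaken for cellular
structure; residual stain and noise in the blank *background*; and, on
tissue-microarray-style slides, several *disconnected tissue pieces*
that downstream tools treat as one object. `stclean` removes these
artifacts in four sequential stages:

1. **Marker segmentation** — a customised encoder–decoder convolutional
   network predicts a per-pixel marker probability mask.
2. **Restoration** — the masked marker regions are filled (inpainted)
   from the surrounding context, leaving all other pixels untouched.
3. **Tissue detection** — a light saliency network separates tissue
   from background at a reduced working resolution.
4. **Segregation** — the tissue probability mask is binarized and
   8-connected components are labelled, dropping tiny artifacts.

## The marker segmentation network

The network is a four-stage U-shaped fully convolutional model tailored
to small, globally arranged circular targets. The encoder widens the
channels $3 \to 32 \to 64 \to 128 \to 256$ while halving the resolution
with $4\times4$ stride-2 convolutions. Block 1 adds a $3\times3$
refinement convolution and uses neither normalisation nor dropout, so
fine detail survives; blocks 2–3 use instance normalisation, ReLU and
dropout; block 4 adds another $3\times3$ convolution for global shape
context, and two further $3\times3$ convolutions form the bottleneck.
The decoder mirrors the encoder with $4\times4$ transposed convolutions
($256 \to 128 \to 64 \to 32 \to 16$). Skip connections from encoder
stages 3/2/1 are *additive* (the deepest one through a learned
$1\times1$ projection; the channel counts match elsewhere), while the
final skip *concatenates* the 3 input channels onto the 16 learned
output channels. Additive fusion cannot produce the documented
19-channel pre-head map, so concatenation is the only consistent
reading; the earlier skips stay additive because their widths agree.
A $4\times4$ stride-1 convolution plus sigmoid maps the 19 channels to
the marker probability mask.

Training minimises a convex combination of two losses,

$$L = \lambda\,L_d + (1-\lambda)\,L_f,\qquad \lambda = 0.9,$$

where $L_d$ is the Dice loss with smoothing $\epsilon = 1$ and $L_f$ is
the focal loss with class weight $\alpha = 0.95$ on the (rare) marker
class and focusing exponent $\gamma = 3$. The *reported* Dice loss
binarizes the prediction at 0.5 exactly as defined; because that step
has a zero gradient almost everywhere, *training* uses the standard
soft relaxation in which the probabilities enter the Dice ratio
directly. The backward pass is hand-derived and verified against finite
differences in the test suite.

Slides are stratified by the *marker overlap factor* — the fraction of
markers whose centre lies inside tissue. Slides with factor $> 0.8$ are
hard and visited three times per epoch, factors in $(0.3, 0.8]$ are
moderate and visited twice, factors below 0.3 are easy. A factor of
exactly 0.3 falls into the easy class, reading the moderate interval as
open at its lower end; the choice is documented in
`classify_difficulty()` and only affects a measure-zero boundary.
Augmentation draws uniformly from fixed ranges: left–right and up–down
flips, scaling in $[0.8, 1.0]$, rotation in $[-10^\circ, +10^\circ]$,
brightness in $[0.5, 1.2]$ and Gaussian blur with
$\sigma \in [0, 1]$ px; geometric transforms act identically on image
and mask, photometric ones on the image only. Optimisation is Adam
with learning rate $10^{-4}$, $\beta_1 = 0.5$, $\beta_2 = 0.999$. The
faithful preset trains 800 epochs; the desk-scale default is 200,
which suffices on synthetic corpora.

Whole slides are processed tile-wise (default 256 px tiles, 32 px
overlap at inference — the tile geometry is not fixed by the original
method and is exposed as configuration), the per-tile probabilities are
stitched with arithmetic-mean blending on overlaps, and the mask is
binarized at 0.5. Input intensities are scaled to $[0,1]$; instance
normalisation is used without affine parameters, as none are described.
Dropout defaults to 0.5 (the convention of the pix2pix family the
baseline architecture follows) and is inactive at inference.

## Restoration

The restoration contract is: masked pixels are replaced by synthesised
content, unmasked pixels are bit-identical to the input (enforced by a
final compositing step), and output dimensions are unchanged. The
published pipeline delegates this step to a large pretrained inpainting
network; those externally hosted weights cannot ship with a
self-contained package, so the default backend here is classical:
each masked component is filled with the harmonic interpolant of its
boundary values (onion-peel initialisation followed by successive
over-relaxation), with a `nearest` (onion-peel only) backend as a
cheaper alternative. The backend registry accepts drop-in replacements,
so a learned model can be registered without touching the module
surface. The mask is dilated by 2 px before filling; the anti-aliased
rim of a marker otherwise leaks a dark halo into the fill. Because the
fill of one masked component never depends on pixels beyond its own
boundary, patch-based processing (`inpaint_patched()`, default halo
64 px) is exactly equivalent to whole-image processing — the property
the tests assert on distant disc pairs.

## Tissue detection

Tissue-versus-background separation is a salient-object problem. The
published pipeline calls a pretrained U²-Net through an external tool;
here a light variant of the in-package encoder–decoder (widths
8/16/32/64, compact variant 4/8/16/32 — mirroring the tool's full and
portable model modes) is trained on synthetic slides instead, keeping
the package free of external weights. Slides are resized to a
320×320 working resolution, the saliency map is computed there and
bilinearly upsampled to the original grid. If the first pass finds only
a small tissue region — bounding box of probability > 0.5 under
100×100 px at original scale; the measurement is necessarily two-pass
since tissue extent is unknown before segmentation — the slide is
rerun at 1000×1000 with the compact variant. No CRF or morphological
post-processing is applied. The blended RGBA view copies the RGB
channels and sets alpha to `round(255 * prob)`.

## Segregation

The tissue probability mask is binarized at threshold 0.8 (comparison
`>=`; strictness is not specified and the choice only matters on exact
ties), components are labelled under 8-connectivity in first-encounter
raster-scan order, components smaller than 20 px are removed, and the
surviving labels are compacted to `1..K`. Filtering before compaction
versus after is unobservable in the output; this implementation filters
then compacts.

## The synthetic slide generator

`generate_sample()` renders a stated world, not a tuned one: a square
frame of dark anti-aliased rings (4 × `markers_per_side` circles) with
per-marker centre and radius jitter, globally displaced by a smooth
elastic field (a coarse Gaussian displacement grid, bilinearly
upsampled; the amplitude in px is the knob); one or more textured
tissue blobs built from thresholded band-limited noise, tinted to mimic
H&E pink with sparse darker nuclei-like specks; and faint background
stain speckles. The marker–tissue overlap factor is controlled by
extending the tissue over a contiguous stretch of the frame; a marker
is `in_tissue` iff its centre pixel lies in the tissue mask — a single
unambiguous rule matching the per-marker granularity of the overlap
ratio. All ground truths (circle annotations, marker mask, tissue mask,
component count) are emitted with the image, and the component count
stored is always the realised 8-connected count of the rendered mask.

Generator defaults (256 px slides, 13 markers per side, radius 5 px,
deformation 2 px, one tissue blob, overlap 0.1, speckle density 0.02)
are one-time choices of plausible thumbnail-scale values — the real
corpus the published method was trained on averages some hundreds of
markers per slide, which at thumbnail resolution corresponds to tens of
visible rings per border. What a green test on this world establishes
is that the implementation recovers *its own* stated world; it does not
establish accuracy on real H&E imagery, photorealistic stain texture,
nuclei-level morphology, or vendor-specific marker layouts.

## Evaluation metrics

All eight statistics are implemented from their definitions and checked
against brute-force oracles: IoU (defined 1 when both masks are empty —
two methods that found nothing agree); the symmetric sup–inf Hausdorff
distance between boundary pixel sets (boundary = foreground pixel with
a background 4-neighbour, image border counting as background; the
literal supremum form, not the 95th-percentile variant); the perimeter
ratio under the same boundary convention; the connected-component count
difference; dense-window SSIM (11×11 Gaussian window, $\sigma = 1.5$,
$c_1 = (0.01 \cdot 255)^2$, $c_2 = (0.03 \cdot 255)^2$ — the window and
constants are the de-facto standard since none are prescribed —
averaged per channel then across the three channels); mutual
information on 64-bin grayscale joint histograms in nats (binning and
log base are unstated; these are common defaults); multi-class Dice
with classes absent from both labelings skipped rather than scored 1;
and the adjusted Rand index from the contingency table. Morphology
descriptors use a Cauchy–Crofton perimeter estimate (raw boundary-pixel
counting overestimates curved boundaries by up to $4/\pi$, pushing the
circularity of a disc far from 1), ellipse moments with the standard
$1/12$ pixel-variance correction, and a convex hull over pixel corners
so solidity cannot exceed 1.

## Numerical choices and degenerate inputs

* Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ inside the focal
  loss; the clipped region is treated as flat in the gradient.
* Inputs whose sides are not multiples of 16 are padded reflectively
  and the output cropped back (reported once per session).
* Hausdorff distance and perimeter ratio are undefined for empty masks
  and return `NA` with a warning rather than a sentinel number.
* An all-covering inpainting mask, an empty training corpus, a corpus
  without marker annotations, and an overlap target with no tissue are
  configuration errors, not silent degradations.
* All randomness (initialisation, sampling order, dropout,
  augmentation, generator rendering) flows from explicit integer seeds
  through R's RNG; fits restore the caller's RNG state.

## Scaled-down verification

The acceptance-style tests train the full-width architecture but on
smaller problems than the published experiments (160 px slides; 20
training and 8 held-out slides for marker recovery; one 96 px slide,
200 epochs, for the bit-reproducibility check; tissue training and
detection at a 160 px working size), keeping every stated threshold —
median marker IoU ≥ 0.7 and above the Hough baseline, tissue IoU ≥ 0.8,
component agreement on ≥ 9/10 slides, strict loss decrease, bit-exact
reproducibility — unchanged. This keeps the whole suite within a
CPU-only budget while exercising the same code paths end to end.

## Known limitations

* The classical diffusion fill produces smooth (harmonic) content; it
  removes markers cleanly on background and mildly textured tissue but
  does not hallucinate high-frequency texture the way a learned
  inpainter does.
* The saliency backend is trained per corpus; no pretrained weights are
  bundled, so detection quality on real slides depends on the training
  data supplied by the user.
* The Hough baseline uses gradient-directed voting with a perimeter-
  support score; it is a fair classical reference, not a tuned
  competitor.
* Pyramidal whole-slide formats and colour deconvolution are out of
  scope; inputs are plain PNG/TIFF/JPEG rasters.
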