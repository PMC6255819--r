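---
title: "Deep texture synthesis and psychophysical evaluation of mammogram-like images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep texture synthesis and psychophysical evaluation of mammogram-like images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammetamer)
```

## The problem

Clinical image sets of a given diagnostic description are scarce, which
limits training of both human experts and machine systems. One proposed
remedy is *deep synthesis*: pass a real image through a convolutional
feature hierarchy, summarise each layer's activations by a Gram matrix (the
channel-by-channel co-activation matrix), and then optimise a fresh image —
starting from white noise — until its Gram matrices match the original's.
The result preserves the high-level texture statistics of the input while
scrambling its pixel layout: a candidate *metamer*, an image that experts
should find perceptually interchangeable with the original despite being
physically different.

`mammetamer` implements this whole loop at desk scale, plus the
psychophysical machinery needed to evaluate it with simulated observers:
signal-detection (d′) analysis of "original or synthesized?" judgements,
representational dissimilarity matrices (RDMs) from pairwise similarity
ratings, RDM congruity by permutation test, hierarchical clustering, and a
paired rating comparison. Because real screening mammograms cannot be
redistributed, the package includes a seeded generator of mammogram-like
*phantoms* so every stage is testable end to end from code alone.

## The phantom generator: what it emulates, and what it does not

`generate_phantom()` renders a power-law Gaussian random field — white
Gaussian noise shaped in the Fourier domain to a power spectrum
$\propto 1/f^{\beta}$ with $\beta = 3$ by default, rescaled to
$[0.2, 0.8]$ — which is the standard "lumpy background" stand-in for
mammographic tissue texture. On top of this background the four diagnostic
classes add:

* **normal** — nothing (and an all-zero ROI mask);
* **benign_no_callback** — one smooth disc, radius 8–12 px, contrast +0.10;
* **benign** — one fuzzy-edged Gaussian mass, $\sigma$ 6–10 px, contrast
  +0.18, mask radius $2\sigma$;
* **cancer** — 5–15 small bright Gaussian blobs ($\sigma$ 1–2 px, contrast
  +0.35) scattered in a 12 px disc, mimicking a microcalcification cluster;
  the disc is the mask.

All lesion geometry is an invented stand-in — no quantitative lesion model
was available to copy — chosen so that the classes are separable at the
texture-statistics level (the test suite verifies that cancer and normal
phantoms are farther apart in Gram distance than phantoms within a class).
Lesion extents are capped at `floor(min(h, w)/2) - 2` pixels so the ROI
always fits images as small as 32 px; at the default sizes (64 px and up)
the stated ranges apply unchanged. Passing the package's tests therefore
shows that the *pipeline machinery* is correct on images with this
category structure; it says nothing about radiological realism, scanner
physics, or how the method behaves on real tissue.

Reproducibility runs through one scheme: `derive_seed()` fans a master seed
into child seeds by an exact fixed-modulus linear hash (all arithmetic below
$2^{53}$, so it is platform-stable), and every stochastic operation takes an
explicit seed.

## The feature hierarchy

The default "desk" network (`desk_net_config()`) is three 3×3 convolutions
of 8, 16 and 32 channels with relu activations, separated by 2×2 average
pools; Gram statistics are taken from all three post-activation conv
outputs. Weights are drawn once, deterministically, from a zero-mean
Gaussian with sd $1/\sqrt{\text{fan-in}}$ — random multi-scale filters are
sufficient for texture matching, and the whole synthesis loop runs in
seconds on one CPU. Average pooling (rather than max) is the default
because it gives smoother pixel gradients for the optimiser; both are
available. Convolutions use same-size zero padding (a circular option
exists for shift-invariance experiments), and pooling floor-divides the
spatial dimensions.

A reference VGG-19-style configuration ships under `configs/vgg19.yaml` for
layer-count parity with the full-scale network used in the original
setting (16 conv + 3 dense = 19 weight-bearing layers). It is parsed and
counted in tests but never required for computation: reproducing a
pretrained network's behaviour is out of scope, so the reference file is a
structural document, not a model.

`finetune_features()` is a miniature stand-in for supervised adaptation: a
linear softmax head on the global-average-pooled final feature layer,
trained jointly with the conv weights by full-batch gradient descent on
4-way class cross-entropy. The objective, labels and schedule of the
original fine-tuning were not specified anywhere, so this 4-way head is a
documented invention; what the tests check is the contract — determinism,
monotone non-increasing training loss (each epoch backtracks its step until
the loss does not increase), and above-chance held-out accuracy on fresh
phantoms.

## The synthesis objective and optimiser

For layer $l$ with $N_l$ channels observed at $M_l$ positions and feature
matrix $F^l$, the Gram matrix is $G^l = F^l (F^l)^\top$ (raw sums, not
correlations — spatial layout is discarded, scale is kept). The objective
against target Grams $A^l$ is

$$L = \sum_l \frac{w_l}{4 N_l^2 M_l^2} \sum_{ij} (G^l_{ij} - A^l_{ij})^2 ,$$

an elementwise L2 norm with the conventional $1/(4N^2M^2)$ normalisation so
layers of different size contribute on comparable scales; the layer weights
default to uniform $w_l = 1/|\text{layers}|$, the neutral choice in the
absence of any stated weighting. The pixel gradient is hand-derived
backpropagation: at each Gram layer the feature-space gradient is
$\frac{w_l}{N_l^2 M_l^2}(G^l - A^l) F^l$, injected into a reverse pass
through the conv/pool/relu stack. The test suite validates it against
central finite differences ($h = 10^{-3}$) to a relative error of
$10^{-4}$, restricting the comparison to pixels whose perturbation does not
flip any relu unit — the difference quotient is simply not a derivative
oracle across a kink.

`synthesize()` starts from seeded uniform white noise on $[0,1]$ (matching
the pixel range; no distribution was prescribed) and runs projected
steepest descent: Armijo backtracking (sufficient-decrease constant
$10^{-4}$, shrink 0.5) evaluated on the *post-projection* iterate, pixels
clamped to $[0,1]$ after every step, and the accepted step doubled as the
next trial step so the line search adapts in both directions. Accepting
only decreasing steps makes the recorded loss trajectory non-increasing by
construction; if no decreasing step exists within 40 halvings the run
stops. Default stopping is 500 iterations or an absolute loss of
$10^{-6}$; analyses that measure the *relative* loss ratio pass a tighter
`tol` explicitly, since a 32×32 phantom's initial loss is itself only
$\sim 10^{-4}$ and the absolute default would stop at a ratio near 1%.

At the study conditions used in the tests (32×32 phantoms, desk net, 300
iterations) the final loss falls below 1% of the initial loss while the
synthesized image differs from its original by more than 0.05 mean absolute
intensity — the metamer property restated at the statistics level: matched
Gram statistics, different pixels. `gram_distance()` (the uniform-weight
loss) additionally shows synthesized images are closer to their own
original than to an opposite-class reference.

## Patch extraction

`extract_pvm_roi()` implements the partial-view patch rules: centre a
$w \times w$ square ($w = 600$ at full scale; tests use desk sizes) on the
ROI and skip — with a machine-readable reason — when the mask has more than
one 8-connected component, when the square would leave the image, or when
any ROI pixel falls outside the square. Three choices were genuinely open
and are fixed as follows: the ROI "centre" is the rounded (half-up) mass
centroid, unique and orientation-free; a square exceeding the image bounds
is a skip for ROI crops (padding would fabricate tissue) but a clamp-shift
for saliency crops, because normal-class images must always yield a patch
to keep class balance; reasons are checked in the order `multiple_rois`,
`out_of_bounds`, `roi_outside_square`, which makes them mutually exclusive.
Indices are 1-based, as everywhere in R.

For unannotated (normal) images, `saliency_map()` is a deliberately minimal
single-channel centre–surround conspicuity map:
$S = \mathrm{smooth}\big(\sum_{\sigma \in \{1,2,4\}}
\mathrm{maxnorm}\,|G_\sigma * I - G_{4\sigma} * I|\big)$, each scale
max-normalised before summing, final Gaussian smoothing $\sigma = 2$, and
the result normalised to peak 1 unless flat. Colour and orientation
channels of the classical conspicuity model are meaningless for grayscale
mammograms and are deliberately omitted; the exact parameters of the
original toolbox are not public, so this channel is a declared
simplification. The "most salient region" is the 8-connected component of
pixels at $\ge 0.9 \times$ the peak that contains the global argmax, with
ties broken by smallest row-major index.

## Simulated observers and analyses

There are no deposited human data, so the package evaluates its analysis
code on generative observer models whose ground truth is known:

* **SDT observer** (Experiment 1): evidence $x \sim N(\delta \cdot
  \mathbb{1}[\text{synthesized}], 1)$, respond "synthesized" iff $x > c$.
  The chance observer is $\delta = 0, c = 0$. This is exactly the model
  under which d′ is defined, so parameter recovery is a meaningful check:
  with 200 trials per class, mean estimated d′ tracks
  $\delta \in \{0, 0.5, 1, 2\}$ within ±0.15.
* **Rater** (Experiment 2): rating $= \mathrm{clamp}(D + N(0, \sigma^2),
  0, 100)$ with latent dissimilarities $D = 0$ (identical images),
  `d_pair` = 10 (original/synthesized twins), `d_class` = 40 (same class),
  `d_diff` = 70 (different class). The defaults encode the qualitative
  structure the human panels reported — twins nearly interchangeable,
  class structure dominant — not any measured values.

Schedules are exact: every Experiment-1 image appears exactly the requested
number of times, so the synthesized/original truth split is exactly 50–50
by construction; Experiment-2 enumerates every unordered pair *including*
identical-image pairs (so "both original" and "neither original" trial
types exist), each the requested number of times, unordered because the
side-by-side display carries no order semantics. Trial order is a seeded
uniform shuffle.

`dprime()` applies the log-linear correction $H^* = (h + 0.5)/(n_s + 1)$,
$F^* = (f + 0.5)/(n_o + 1)$ before taking normal quantiles — the standard
way to keep d′ finite at ceiling or floor performance, a case the source
analyses do not say how they handled. The complementary `tn_vs_miss`
variant applies the same formula to corrected true-negative and miss
rates; with complementary counts it yields the identical value, which the
tests assert rather than hide. `rdm_congruity()` uses Spearman rank
correlation of the RDM upper triangles against a joint row/column label
permutation null with the $+1$ correction ($p$ can never be exactly zero);
1000 permutations by default. `hca()` wraps average-linkage agglomerative
clustering (`stats::hclust`), cross-checked in the tests against a
brute-force average-linkage enumeration with lowest-index tie-breaking.
`paired_rating_test()` aggregates per subject (mean rating of pairs
involving originals minus pairs involving synthesized images, twins and
identical pairs excluded from both sides — the pairing unit was otherwise
undefined) and refuses to report an infinite $t$ when the differences are
constant and nonzero.

## Numerical and degenerate-input choices

* Images are matrices in $[0,1]$; writers refuse out-of-range values
  rather than clipping silently. 16-bit output goes to binary PGM so
  quantisation cannot mask Gram differences.
* Flat saliency maps (peak below $10^{-12}$) are defined as identically
  zero rather than normalised floating-point noise.
* Connected components use 8-connectivity everywhere, labelled in
  raster-scan order.
* Gram matrices are symmetric positive semidefinite by construction; tests
  tolerate eigenvalues down to $-10^{-8} \times \mathrm{trace}$ for
  floating-point slack.
* All tie-breaks (saliency argmax, clustering) are deterministic and
  documented at the function that owns them.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by design:
8×8 images for gradient checks, 32×32 phantoms and the 3-conv desk net for
synthesis (300 iterations), 64×64 phantoms for patch extraction, 200
simulated observers per sensitivity level for d′ recovery, and 100–200
replicates for the permutation-test calibrations. These sizes were chosen
so a full verification pass completes in a few minutes on a single CPU
while every statistical check retains enough replication to be
discriminating.

## Known limitations

* Phantoms are texture stand-ins; nothing here validates against real
  mammograms or a pretrained full-scale network.
* The optimiser is first-order; quasi-Newton methods would converge in
  fewer iterations but would not preserve the simple monotonicity
  guarantee.
* Reaction times are carried in the trial schema but never modelled or
  analysed.
* No post-processing (e.g. histogram matching) is applied to synthesized
  images; none was specified.
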