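---
title: "Auditing radiograph classifiers for shortcut learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing radiograph classifiers for shortcut learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(shortcutaudit)
```

## The problem this package addresses

When a disease classifier is trained on images pooled from different
hospitals — say, all COVID-positive radiographs from one repository and all
negatives from another — the *source* of an image predicts its label
perfectly. Any feature that identifies the source (the style and position of
the radiopaque laterality marker, radiopacity at the image borders from
cropping or processing, how high the shoulders sit in the frame from patient
positioning) then works as well as genuine pathology for minimising training
loss. Models that exploit such *shortcuts* look accurate on held-out data
from the same sources and fail on data from new hospitals; worse, a shortcut
that is rendered the same way everywhere survives external validation.

`shortcutaudit` packages the full audit loop at desk scale: a synthetic
two-source generator with planted confounds and a genuine disease signal,
classifier training that mirrors the reference scheme, generalization-gap
measurement, Expected-Gradients saliency, cycle-consistent counterfactual
translation, and behavioral patch tests with Monte-Carlo p-values. Because
the generator plants the confounds, every audit has a ground truth to be
scored against.

## The synthetic generator

Each image is a schematic 64×64 (configurable, ≥ 32) grayscale "radiograph":
a body silhouette, two dark elliptical lung fields, diaphragm and cardiac
shading, a bright shoulder band, a per-source laterality glyph, optional
border radiopacity, optional annotation stamps, and Gaussian pixel noise
(sd 0.05). Genuine disease is a bilateral increase in lung-field radiopacity
rendered as smooth Gaussian blobs (`pathology_spec()`, default amplitude
0.25 over ~0.2 background, four blobs of radius 4 px) confined to the lung
masks. Anatomy is deliberately schematic: the audits only need region
*semantics* — lung field, border, marker, shoulder — not anatomical realism,
and nothing in the pipeline exploits texture beyond those regions. Passing
audits on this generator therefore demonstrates that the machinery detects
planted confounds with known ground truth; it does not certify performance
on real radiographs, whose confounds are subtler (scanner physics,
windowing, demographic mix are all absent here).

The confound structure is controlled by one number. With correlation
strength $\rho \in [0,1]$, a record from the positive-leaning source B is
truly positive with probability $(1+\rho)/2$ and one from source A with
probability $(1-\rho)/2$:

* $\rho = 1$ — worst-case confounding: source B exclusively positive,
  source A exclusively negative (each source still contributes exactly
  `n_per_source` records);
* $\rho = 0$ — label independent of source, so every per-source feature is
  uninformative.

`pathology_penetrance` < 1 lets truly positive cases lack visible signal;
combined with `labeling_rule = "radiographic_evidence"` (label = rendered
evidence) versus `"latent_status"` (label = true status) this reproduces
concept shift between figure-derived and PCR-derived labels.

Two canonical source pairs are exported. `marker_only_profiles()` differ
*only* in glyph ("L" top-left vs "R" top-right) — the cleanest planted
shortcut, used by most audits. `default_profiles()` add opposed border bands
(+0.12 / −0.08), a 6 px shoulder offset and 10% annotation stamps for
source B, emulating the full between-repository signature. The annotation
rate has no empirical anchor; it is exposed as configuration with no
fidelity claim. Projection (PA/AP mix per source) and a two-level sex
analogue are drawn per source; AP projection is rendered either as extra
border radiopacity (shared across sources) or as a source-specific
interior tag, which is what makes the confound-transfer audit
expressible. The
auxiliary 14-label vector is independent low-rate (5%) Bernoulli noise: the
audit never scores those nodes, they exist to keep the multi-task head
honest.

All randomness flows from one master seed; each record renders from a
derived substream, so datasets are byte-reproducible.

## Classifier family and training

No deep-learning framework is assumed: the package carries a small,
finite-difference-verified conv-net engine (3×3 stride-1 convolutions, 2×2
average pooling, ReLU/tanh, dense heads) that exposes parameter *and* input
gradients — the latter are what the attribution and counterfactual modules
need. Three architectures are provided:

* `dense-cnn` — three conv stages (8/16/16 channels) with pooling and a
  dense head on the flattened 8× downsampled map; the higher-capacity
  member.
* `simple-cnn` — one conv stage, two poolings, and a dense head on the
  flattened map; the shallow, location-aware capacity control.
* `logistic-embedding` — a logistic head trained by the same SGD on
  features from a frozen randomly initialised conv stack; the "fixed
  embedding + logistic regression" control. The reference used a pretrained embedding;
  shipping or downloading pretrained weights is out of scope, so the frozen
  embedding here is random, which preserves the capacity argument.

Classification heads are initialised at zero in every architecture — the
fit starts from the no-information model, as logistic fits conventionally
do. Beyond being a clean starting point, this matters for the attribution
audits: with a zero-initialised head, weights grow only along
label-relevant feature directions, so the trained model's input gradients
reflect learned structure rather than leftover random initialisation, and
saliency maps localise to what the model actually uses.

Optimisation follows the reference scheme exactly (`train_hyperparams()`):
mini-batch SGD, batch 16, momentum 0.9, weight decay $10^{-4}$, learning
rate 0.01 divided by 10 every 5 epochs, per-node binary cross entropy, and
the deployed weights are those of the epoch with the highest COVID-node
validation AUROC. No augmentation is used (none is specified by the
reference scheme). At the study scale used throughout (64×64, 400 images
per source, patient-grouped 80/10/10 splits), the marker task saturates
within 3 epochs, so `max_epochs = 3` is the package's default study
condition for the audits; the multilabel-vs-single-label comparison uses 5
epochs on a 300-image evaluation set, where both heads are within
sampling error of each other.

AUROC is computed by the rank (Mann–Whitney) formula with half-weight ties
and cross-checked in the tests against both a pairwise-counting oracle and
`pROC`.

## Dataset assembly

`filter_views()` keeps PA and upright-AP records only. `assign_folds()`
treats patients as atomic: patients are shuffled under the seed and
accumulated into the test fold until its record quota is met, then the
validation fold, with the remainder training. Fractions are interpreted over
records ("5% of the radiographs"), so achieved fractions deviate from the
target by at most (largest patient)/N; with one record per patient they are
exact. A `fixed_test_ids` set is pinned to the test fold first and aborts if
honouring it would split a patient.

## Generalization audit

`evaluate_generalization()` reports internal and external AUROC and their
difference. Because AUROC has a chance floor of 0.5, "performance lost" is
measured on the above-chance scale:
$(\mathrm{AUROC}_{ext} - 0.5) / (\mathrm{AUROC}_{int} - 0.5)$
(`above_chance_retention()`); raw ratios of AUROCs would understate the
collapse. `confound_transfer_audit()` trains fresh single-label classifiers
(default 5 replicates, seeds `seed + 0:4`) to predict projection or the sex
analogue and scores them internally and externally — a cue rendered
identically across domains yields high external AUROC *without* a gap,
which is exactly why external validation alone cannot rule out shortcuts.

## Expected Gradients

For input $x$, node output $f$ (the *pre-sigmoid* log-odds — chosen so that
attribution sums are additive with the behavioral tests, which also work in
log-odds), background distribution $D$:

$$\phi_i(x) = \mathbb{E}_{x' \sim D,\ \alpha \sim U(0,1)}
  \left[(x_i - x'_i)\,
  \frac{\partial f(x' + \alpha(x - x'))}{\partial x_i}\right]$$

estimated by single-gradient samples with a joint $(x', \alpha)$ draw
(default 200 per image; the localization audits use 150 over 10 images,
which bounds the Monte-Carlo error well below the 0.5 mass threshold they
test). The background defaults to training negatives. Integrated Gradients
is the singleton-background special case on a deterministic midpoint
$\alpha$ grid; midpoint quadrature makes completeness exact for quadratic
models and accurate to $O(n^{-2})$ on smooth ones. Every map records its
completeness gap $|\sum_i \phi_i - (f(x) - \overline{f(x')})|$.
`percentile_saliency()` displays $|\phi|$ (or signed $\phi$) as ranks
scaled to $[0, 100]$; an all-equal map returns the 50th percentile by
convention. `background_sensitivity()` reports the Spearman correlation of
maps under two backgrounds.

## Counterfactual translation

Two residual generators $G: X \to Y$, $F: Y \to X$ and two patch
discriminators are trained with the adversarial log losses

$$L_{GAN}(G, D_Y) = \mathbb{E}_y[\log D_Y(y)] +
  \mathbb{E}_x[\log(1 - D_Y(G(x)))]$$

(and symmetrically for $F, D_X$), plus the L1 cycle loss
$\mathbb{E}_x\|F(G(x)) - x\|_1 + \mathbb{E}_y\|G(F(y)) - y\|_1$; the total
is their plain unweighted sum, with no identity-mapping term. Loss *values*
are always reported in this printed form; the generators' training gradient
uses the standard non-saturating surrogate $-\log D(G(x))$ (the saturating
form vanishes exactly where a fresh generator starts), and a least-squares
switch is available.

Desk-scale design choices that mattered, found during development and kept
as defaults:

* **Coordinate channels for both players.** A purely convolutional
  generator is translation-invariant and cannot *place* a glyph on
  featureless background; a translation-invariant patch critic cannot
  punish a glyph painted at the wrong position. Both nets therefore read
  two normalised coordinate channels alongside the image.
* **Zero-initialised residual head.** $G(x) = x + \tanh(c(x))$ with the
  last conv layer zeroed, so the untrained map is exactly the identity and
  all early cycle pressure is spent on real domain differences, not on
  undoing random initialisation. The tanh range (±1) is wide enough to
  paint or erase a radiopaque glyph over background.
* **Adam (β₁ = 0.5) for both players.** With per-patch loss averaging, the
  gradient of a marker-sized domain difference is diluted by two orders of
  magnitude; Adam's per-parameter rescaling restores it. Discriminators
  take two steps per generator step and a matched learning rate (2e-3).

At the study scale (64×64, 40 images per domain, 30 epochs, ≈ 5 minutes on
one CPU) the difference map $|G(x) - x|$ concentrates about two thirds of
its mass in the dilated planted-marker regions; longer runs sharpen this
further. `classifier_flip_rate()` scores translated images with the audited
classifier; a flip is a zero crossing of the COVID log-odds toward the
target class.

## Behavioral tests

`run_swap_test()` exchanges the two images' marker configurations: the
content at both marker sites (each source's canonical glyph footprint) is
swapped between the images in place, so each image ends up carrying the
other's marker. Since different sources print their markers at different
positions, exchanging only one site would relocate a glyph to a position
the model never associates with either class; the both-site exchange is
what "giving the negative image the positive source's marker" means here.
Each induced log-odds change is compared against `n` (default 1000) null
modifications that exchange two uniformly placed random sites of the same
dimensions; `run_reposition_test()`
copies the shoulder band to the top corners against a null of random
same-size source patches copied to the same corners (duplication, not
cut-paste — the source region keeps its content). The empirical p-value is
$(r+1)/(n+1)$ with $r$ the number of null effects *strictly* exceeding the
observed one in the stated direction; ties do not count, so $p$ is bounded
in $[1/(n+1), 1]$ and a fully tied null sits at the floor, not at 1. Null
patches are placed uniformly with full containment and may overlap the true
marker region — excluding them would bias the null toward smaller effects;
the cost is a slightly conservative test when the region is informative.

## Numerical and degenerate-input conventions

* Discriminator probabilities are clamped to $(10^{-7}, 1-10^{-7})$ before
  logs, with a warning if clamping fired.
* Glyph jitter that would push a marker off-image is clamped to the border
  rather than resampled, keeping dataset sizes exact.
* An all-equal attribution map has no rank order; the percentile display
  returns 50 everywhere.
* A validation fold with one class aborts training (epoch selection would
  be undefined), and one-class test sets abort AUROC.
* Constant attribution maps make the background-sensitivity correlation
  undefined; it is returned as `NA` with a warning.

## Problem sizes used by the test-suite and acceptance script

Chosen as the package's study conditions: worst-case marker-only data at
64×64 with 400 images per source (dense-cnn, 3 epochs); a signal-only
dataset of 400 images with opacity 0.3 against noise 0.05; the translator
on 40 images per domain for 30 epochs; behavioral nulls of 1000 draws for
the targeted test and 24 replications of 60 draws for calibration.

## Known limitations

* The generator's confounds are high-contrast and geometrically simple;
  real inter-hospital signatures are subtler and higher-dimensional.
* The frozen embedding of `logistic-embedding` is random rather than
  pretrained, so its absolute AUROC is not comparable to a pretrained
  embedding's — only its qualitative behaviour (shortcut gap persists at
  low capacity) is.
* The translator is a shallow residual map, adequate for planted local
  features; it will not model global intensity remappings or anatomy.
* Backend determinism: everything is plain single-threaded R arithmetic,
  so fixed seeds reproduce results exactly on one platform; across BLAS
  builds the usual last-ulp caveats apply.
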