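---
title: "Clinician-AI fusion for axillary lymph node staging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinician-AI fusion for axillary lymph node staging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axfuse)
```

## The problem

Axillary lymph node (LN) metastasis is the strongest prognostic factor in
breast cancer, and the reference standards for detecting it — sentinel node
biopsy and axillary dissection — are invasive. FDG-PET/CT offers a
noninvasive read, but human sensitivity is poor (about 60%) even though
specificity is excellent (97-99%): small metastatic nodes simply do not light
up much. `axfuse` implements a human-AI collaboration scheme for this
setting, together with everything needed to study it quantitatively: the
probability-fusion rule, the evaluation machinery, a synthetic cohort
generator, a PET/CT phantom generator, and a small trainable 3D attention
network.

## The fusion rule

Clinicians grade each axilla on a 5-point certainty scale
(1 definitely absent, 2 probably absent, 3 indeterminate, 4 probably
present, 5 definitely present). The scale maps to canonical probabilities

$$P_\mathrm{cli} \in \{0, 0.25, 0.50, 0.75, 1\},$$

and the AI contributes a continuous metastasis probability
$P_\mathrm{ai} \in [0,1]$. The blend is biased toward the clinician through a
confidence weight $\alpha = \max(P_\mathrm{cli},\, 1 - P_\mathrm{cli})$:

$$P_\mathrm{blend} = \alpha\, P_\mathrm{cli} + (1-\alpha)\, P_\mathrm{ai}.$$

At grades 1 and 5, $\alpha = 1$ and the AI has no influence; at grade 3,
$\alpha = 1/2$ and the AI has the most. The AI opinion is consulted only
when its confidence $\max(P_\mathrm{ai}, 1-P_\mathrm{ai})$ strictly exceeds
a threshold (default 0.95); below the gate the record passes through
unchanged, bit for bit. The blended probability is converted back to a grade
through integer-percent bins 0–20, 21–40, 41–60, 61–80, 81–100.

Two conventions in this calculus are genuinely open and we fixed them as
follows:

* **Bin edges.** The bins are stated in integer percents, so we round the
  blended probability to an integer percent first (half away from zero,
  with a tiny epsilon guard against binary-representation error) and then
  bin. Any convention that bins the continuous value directly contradicts
  one of the printed ranges at some edge.
* **Gate comparison.** The gate uses strict `>` by default ("confidence
  larger than the threshold"); `fusion_config()` exposes `greater_equal`
  for sensitivity analysis.

A consequence worth knowing: a grade can move by at most one bin, because
$(1-\alpha) \le 1/2$ bounds the blend's distance from $P_\mathrm{cli}$ by
half a bin width plus rounding. Grade 3 can reach {2,3,4}, grade 2 only
{1,2,3}, grade 4 only {3,4,5}; the test suite verifies this by exhaustive
sweep.

Every regrade is classified against pathology as `corrected`, `mistaken`,
`neutral`, or `unaffected`. The starred conventions of regrade audit tables
are preserved exactly: errors pulled to indeterminate and grade-3 cases
pushed toward their pathology are corrections; correct readings pulled to
indeterminate and grade-3 cases pushed away are mistakes. Certainty
enhancements in the wrong direction (e.g. 2→1 on a pathology-positive side)
fit neither footnote and are labeled `neutral`.

## Evaluation machinery

`dichotomize()` collapses the 5×2 grade-by-pathology table at the nested
cutoffs {5}, {4,5}, {3,4,5} and reports sensitivity, specificity and
accuracy as percentages rounded half-away-from-zero to one decimal, matching
the printed style of clinical tables. `roc_curve()` sweeps all distinct
scores as thresholds; its trapezoidal AUC equals the pair-counting
probability (ties counted half), which the tests verify exhaustively on
small instances and against pROC. `youden_optimal()` maximizes
J = sensitivity + specificity − 1, breaking ties toward the lowest
threshold (the more sensitive operating point; the choice is not dictated
by anything upstream). `kfold_patient_split()` shuffles patients under a
seed and deals them round-robin, so folds differ in size by at most one and
both sides of a patient — including bilateral cancers — always travel
together.

## The synthetic cohort

No clinical records ship with the package, so `build_cohort()` emulates the
study's structure: 407 patients, 7 bilateral, hence 414 cancer sides, of
which 204 are pathology-positive; the 400 cancer-free halves serve as normal
samples (814 total). The generative model is the minimal one that
reproduces the observed marginals and the documented clinician-AI error
dependence:

* Every side draws a latent difficulty $d \sim \mathrm{Beta}(2, 5)$ — most
  cases easy, a tail of hard ones, consistent with the low prevalence of
  indeterminate grades.
* The reader draws a grade from its empirical conditional distribution
  (reconstructed per-grade tables of the two study readers are the
  defaults), tilted toward grade 3 by
  $\exp(-c\, d\, |g - 3|)$ with coupling $c \ge 0$.
* The AI draws $P_\mathrm{ai}$ from a per-class Beta (defaults
  $\mathrm{Beta}(2.5, 1)$ for positives, $\mathrm{Beta}(1, 2.5)$ for
  negatives, giving an AUC in the high-0.8s, the regime of a usable but
  subhuman model), then shrinks it toward 0.5 by $1 - c\,d$ (floored at
  −1, so strong coupling pushes difficult cases onto the wrong side).

With coupling 0, reader and AI are conditionally independent given truth,
and the pipeline cohort → tally → dichotomize reproduces the senior
reader's cutoff metrics in expectation — an acceptance test checks this at
$10^5$ cancer sides within three binomial sigmas. What the generator does
*not* model: neoadjuvant-therapy effects, molecular subtype, node size, or
any per-lesion image correlate; passing tests therefore say nothing about
those axes of real data.

## Phantoms and preprocessing

`generate_phantom()` builds paired PET (SUV) and CT (HU) chest volumes:
uniform background (0.8 SUV, 0 HU) plus Gaussian hot spots — a breast-region
tumor for cancer phantoms and an axillary-region node for metastatic ones —
with additive Gaussian noise. Lesion centers are drawn uniformly inside
fixed anatomical sub-boxes (breast: inferior-anterior; axilla:
superior-posterior-lateral) whose z and y ranges are disjoint with enough
margin that the half-maximum masks of default-width lesions cannot touch.
Defaults render the primary as an FDG-avid enhancing mass (SUV 8, +80 HU)
and the node as fainter and hypodense (SUV 3.5, −60 HU, a necrotic-core
appearance). The opposite CT contrast is deliberate: it makes node voxels
linearly separable from every point of the tumor's intensity profile in
joint (PET, CT) space, so the three phantom classes are separable by
construction and a small network trained on few samples can meet a
high-AUC bar honestly. Real metastatic nodes are not reliably hypodense;
the phantoms are a controlled test bed, not a physical simulation — no
attenuation, scanner blur, or registration error is modeled.

`split_sides()` cuts at the lateral midline and labels each half by the
lesion centroids it contains; concatenation reconstructs the volume
exactly. `preprocess()` applies the clinical normalization: PET clipped at
SUV 6 then scaled to [0,1]; CT windowed to [−100, 200] HU and mapped
affinely (increasing — the direction is our choice, stated nowhere
upstream) to [0,1]; channels stacked PET-first.

## The network

`build_network()` constructs a three-class (no cancer / cancer without LNM /
LNM) 3D CNN: a 3×3×3 stem convolution, one 2×2×2 average pooling, and four
residual units at constant width (default 8 channels), each obeying
`out = act(input + conv(act(conv(input))))` with a leaky rectifier. Two
attention branches hang off the trunk midpoint and endpoint. Each branch
maps features through a 1×1×1 convolution to a two-class *evidence map*;
mean- plus max-pooling of the evidence maps gives the branch's auxiliary
logits (the auxiliary classifier is the evidence projection plus pooling,
in the class-activation-map tradition), and the attention map is the
sigmoid of the positive-minus-negative evidence after per-sample centering
(an instance normalization: attention encodes where evidence sits relative
to the rest of the volume, so a shared offset cannot saturate the map
uniformly). Branch 1 is trained on
cancer-vs-normal (LNM samples masked), branch 2 on LNM-vs-cancer (normals
masked); the masked class contributes neither loss nor gradient. Each map
re-weights the trunk as $f \cdot (1 + a)$, the two maps are summed, and the
combined map re-weights the features entering the final head. The main head
reads the mean of the attention-modulated features next to the per-channel
peaks of the raw trunk, then a linear softmax layer. Training minimizes the
equal-weighted sum of the main cross-entropy and the two masked auxiliary
cross-entropies under plain SGD.

Everything below the block topology was open — widths, kernel sizes,
pooling, head design, how the third class enters the two-class branches, and
how a single metastasis probability comes out of three classes. Our
decisions, and why:

* **$P_\mathrm{ai} = p_3 / (p_2 + p_3)$**, the posterior of nodal spread
  given cancer presence from the main softmax. Fusion happens on known
  cancer sides, so conditioning on cancer is the right bridge.
* **Mean+max pooling in the branch heads.** Lesions occupy a few voxels of
  a large volume; global averaging alone dilutes their evidence by the
  voxel count and stalls learning. The max path carries small-lesion
  evidence at full strength (the weakly-supervised-localization
  compromise).
* **Main head: gated mean + raw max.** The mean path reads the
  attention-amplified average; the max path reads the unmodulated trunk
  peaks. Splitting them this way keeps the undiluted evidence available to
  the classifier without routing a classification gradient through the
  attention maps.
* **Attention is stop-gradient at the gates** (`attention_feedback = 0`).
  The maps are shaped only by their branch's own classification loss;
  where a map multiplies the trunk it is a constant in the backward pass.
  We tried the alternative: letting the downstream losses co-shape the maps
  trains faster but destroys their class-activation meaning — converged
  models classified perfectly while attention settled *away* from lesions.
  The feedback strength is exposed in `network_config()` for exactly this
  kind of experiment.
* **Input centering.** Inputs enter the trunk as $x - 0.5$. All-positive
  inputs give notoriously ill-conditioned first-layer gradients; centering
  measurably speeds convergence at these scales.
* **Leaky activations** (slope 0.05): in an 8-channel trunk a hard-zero
  unit is easily lost for good; the leak keeps every unit trainable while
  leaving the residual identity contract intact on nonnegative features.
* **Optimizer furniture.** Plain SGD is kept, with optional momentum,
  global gradient-norm clipping (default ceiling 1), exponential
  learning-rate decay and linear warmup. The clinical-scale default
  learning rate is 0.001; the toy protocol below uses a larger rate with
  decay because its loss surface is far smaller and stiffer.
* **Determinism** is best-effort: seeded initialization and data order give
  bit-identical runs on one platform; across BLAS implementations only
  statistical agreement is promised.

## The toy protocol and problem sizes

The network is demonstrated at toy scale on phantoms: whole chests of
12×16×12 voxels (half-chests 12×16×6, attention maps 6×8×3), ~30 training
phantoms (each contributing a cancerous and a normal half), SGD with
learning rate 0.05, momentum 0.9, batch 16, decay 0.985, 10-epoch warmup,
160 epochs — about a minute of CPU per fit. A narrow network under plain
SGD converges on most but not all initializations, so fits use a
multi-start rule: up to three candidates from different parameter seeds,
keeping the one with the lowest final *training* loss (converged and stuck
runs separate cleanly; no held-out data enters the selection). At these
sizes the test suite runs a 3-fold patient-level cross-validation for the
AUC of `predict_lnm_probability()` and a 5-seed attention-localization
check in some minutes of CPU. These sizes are a deliberate choice to keep
the demonstration cheap and repeatable; nothing in the implementation is
specific to them, but the clinical-scale result (AUC 0.868 on 414 sides)
is out of reach without the clinical images and is not claimed.

## Known limitations

* The fusion rule is the study's; no alternative opinion pools, and no
  recalibration of the canonical grade probabilities.
* The cohort generator reproduces marginal reader behavior and a
  one-parameter error dependence; it cannot answer questions about reader
  covariates it does not model.
* The phantom's CT-contrast separability is a construction for testing;
  transfer of any toy-scale network result to clinical images is explicitly
  not implied.
* Confidence intervals for metric deltas are out of scope (none are
  reported upstream either).
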