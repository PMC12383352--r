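---
title: "Staging cognitive decline from structural connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging cognitive decline from structural connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connstage)
```

## The problem

Clinical cognitive decline progresses along a continuum — from subjective
complaints (here `G0`, SCI-like), through mild measurable impairment (`G1`,
MCI-like), to dementia (`G2`, ADD-like). The hypothesis behind this package
is that structural brain connectomes encode this continuum in a compact,
interpretable form: although a connectome over ~148 cortical parcels has
~11,000 edges, the changes that track decline should be confined to a
low-dimensional manifold.

`connstage` tests that hypothesis end to end: a graph neural network encoder
is trained to discriminate the two clinical endpoints (`G2` vs `G0`), its
graph-level embeddings are projected onto a principal-component manifold,
and the held-out intermediate group is staged on the first manifold axis.
Because clinical connectome data cannot be redistributed, the package ships
a seeded synthetic-cohort generator with a planted progression axis, so that
every downstream stage is exercised and tested without the original data.

## The encoder

Connectomes enter the encoder binarized ("is there any fiber between these
two parcels?", threshold 0 by default) with one-hot node features, so the
model sees topology only. The baseline architecture is:

1. **Graph isomorphism (GIN) layer**, 128-d output. Node update
   $x_v' = \phi\!\big((1+\epsilon)x_v + \sum_{u \in N(v)} x_u\big)$ with
   $\phi$ a two-layer perceptron (hidden 128, rectifier) and a rectifier
   after the layer. Sum aggregation retains fine topological distinctions
   (it matches the Weisfeiler–Lehman test in discriminative power), which
   matters because the downstream attention layer can only redistribute
   information the first layer preserved. $\epsilon$ defaults to 0 and is
   not trained; no value is prescribed by the architecture, and 0 makes the
   layer's test-mode algebra exact (`gin_layer` with identity $\phi$ equals
   $(A + I)X$).
2. **Graph attention (GAT) layer**, single head, 64-d output. Attention
   logits $\mathrm{LeakyReLU}_{0.2}(a^\top (z_u \,\|\, z_v))$ are softmax-
   normalized over $N(v) \cup \{v\}$; the self node is included in both the
   normalization set and the aggregation sum (the standard convention; the
   aggregation formula is sometimes written over $N(v)$ only, which we read
   as notational shorthand).
3. **Attention readout**: $x_G = \sum_v \mathrm{softmax}_v(\phi_{gate}(x_v))
   \odot x_v$ with an affine scalar gate. This weights informative parcels
   rather than averaging them away; 64-d graph embeddings result.

For training, a two-layer softmax head (hidden 32, rectifier) is attached
and the whole pipeline minimizes cross-entropy on a binary staging task with
full-batch Adam (learning rate and weight decay both 0.001, 100 epochs —
full batch because cohorts of this size fit in one batch and no batch size
is otherwise prescribed). After training the head is discarded.

Ablation variants replace the readout with sum pooling (`sum_pool`), drop
the GAT (`gin_only`), replace the GIN with a symmetric-normalized graph
convolution (`gcn_variant` — the convolution's averaging smooths node
features early, which is why it underperforms), or drop the GIN
(`gat_only`).

Parameter initialization is uniform with fan-in scaling,
$U(-1/\sqrt{f_{in}}, 1/\sqrt{f_{in}})$, drawn from R's seeded RNG; training
is full-batch and therefore deterministic given the seed. The compiled
training path runs in single precision (the standard for this model class);
the exported layer functions are double-precision reference implementations
and the test suite asserts the two paths agree.

## The manifold and staging

Embeddings of the two endpoint groups (from the model trained on all their
samples — deliberately separate from the cross-validation protocol) are
centered and decomposed by PCA (covariance with $1/(n-1)$; `fit_pca`).
The fitted projection is then reused, without refitting, to overlay the
held-out intermediate group. Component signs are fixed deterministically —
PC1 so that the late-stage group's mean projection is positive (progression
runs left to right), later components by making the largest-magnitude
loading positive — so repeated runs produce identical coordinates.

Per-group univariate Gaussians on PC1 define one-standard-deviation cohort
bands $[\mu - \sigma, \mu + \sigma]$; a subject may fall in several bands or
none, and membership is reported as-is. The held-out group is staged by a
Naive Bayes rule: assign each PC1 value to the group with the highest
Gaussian density under **equal priors** (the held-out group's size should
not influence staging; no priors are otherwise prescribed), ties broken
toward the earlier stage. `intrinsic_dim` reports the smallest number of
components reaching a cumulative explained-variance threshold (0.99 by
default, read as ratio ≥ 0.99; the threshold is configurable).

Separability of the three groups on the 2-D manifold is assessed by a
permutation test: the observed statistic is the macro one-vs-rest ROC-AUC of
a multinomial logistic model fit and evaluated in-sample on the coordinates
(no split is prescribed; the identical procedure is applied to every label
permutation, so exchangeability holds and the test is valid). The p-value
uses the plus-one estimator and never returns exactly 0. The multinomial fit
is a ridge-stabilized Newton solver (ridge $10^{-4}$, ≤ 50 iterations): on
linearly separable permutations the unpenalized likelihood diverges while
the AUC saturates, and the small ridge keeps the optimum finite without
affecting the ranking.

## Evaluation protocol

Discriminative performance is estimated by pooled leave-one-out
cross-validation: per run, every sample is held out once, the model is
retrained from scratch on the remainder, and one ROC-AUC is computed from
the pooled held-out scores (a per-fold AUC is undefined with one test
sample). Runs differ by initialization seed (base + 0, 1, ...); the
reported mean ± SD is across runs.

Two properties of this protocol are worth knowing. First, pooled LOOCV is
*pessimistically biased under the null*: each held-out sample is the
minority of its training fold, so on tasks with little or no signal the
held-out scores are anti-ranked and the AUC falls to or below 0.5 — on the
synthetic cohort the near-chance `G1`/`G0` task lands near 0 rather than
0.5. The test suite therefore asserts "no positive skill" for permuted
labels rather than a symmetric null at 0.5. Second, retraining n models per
run is expensive; the acceptance tests run the LOOCV orderings at a
reduced-compute protocol (learning rate 0.005, 30 epochs instead of
0.001/100) chosen so that training reaches the same converged loss regime on
the endpoint task at ~30% of the compute. Package defaults keep the full
protocol.

## The synthetic cohort

`generate_cohort` emulates a three-group cohort of 24/46/18 subjects over
148 parcels. One population skeleton (edge probability 0.30) carries
log-normal base weights; the first 12 nodes form a *vulnerable set*
(echoing the handful of parietal/posterior hub regions implicated in early
decline, without claiming anatomical fidelity). Each subject draws a
progression score $t \sim N(\text{group mean}, 0.15)$ clipped to $[0,1]$
(group means 0, 0.5, 1 — drawn per subject so the intermediate group
straddles the axis, emulating its clinical heterogeneity). Edges incident
to the vulnerable set are attenuated by $1 - 0.6\,t$, multiplicative noise
with CV 0.2 is applied, and weights below 5% of the mean base weight are
set to exactly 0 — removal, not just attenuation, because the encoder
consumes binary topology and would otherwise have no signal.

The base-weight spread matters here: with a narrow log-normal
(sdlog ≈ 0.5) essentially no attenuated weight crosses the 5% cutoff
(the probability is $\Phi(-3.9)$), so the binarized topology would be
identical across groups and the stated progression would be invisible to
the encoder. We therefore use sdlog 1.5 — streamline counts span orders of
magnitude, so the heavy tail is also the more realistic choice — which
yields ~10% baseline edge dropout rising to ~26% on vulnerable edges at
$t = 1$.

What a green test does and does not establish: the generator plants a
*single monotone axis* of attenuation on a *fixed* vulnerable set, with
homogeneous noise. Real cohorts add acquisition variability, subject-level
topology differences, region-size effects and heterogeneous pathology; the
synthetic results validate the machinery (the pipeline recovers a planted
low-dimensional progression), not the clinical effect sizes.

Sparsity-matched random controls (`generate_random_networks`) draw each
graph's edge probability from the cohort's empirical densities and carry no
group structure. The intended control contrast is that embeddings of random
networks should need ≥ 4 principal components to reach the variance that
two components capture on structured cohorts. In this implementation that
contrast does **not** materialize, and the corresponding acceptance check
is deliberately left failing rather than weakened. The mechanism is
supervised representation collapse: an untrained encoder spreads random
networks over tens of effective dimensions, but well before the end of the
prescribed 100-epoch protocol the learned features vary almost exclusively
along the classification discriminant, so *any* input — structured or
random, seen or held out — embeds into an essentially 1–2-dimensional
affine subspace (a few dozen arbitrary-labeled random graphs are fully
memorizable with one-hot node features; the training loss goes to ~0).
The test suite verifies both halves of this mechanism: untrained
embeddings of random networks are high-dimensional, trained ones are not.
The control therefore cannot distinguish
structured from random inputs by intrinsic dimensionality here; a
higher-dimensional random-network manifold would require training that
fails to fit the random labels, which this model class at this sample size
does not exhibit.

## Divergence mapping

A normative template is built from the manifold-defined early-stage cohort
(the PC1 band, not the raw diagnostic labels): per-edge mean and SD of the
*weighted* connectomes, with SDs floored at $10^{-6}$ times the global mean
positive weight so zero-variance edges cannot yield infinite scores. For
each later-stage subject, every edge gets a two-sided Gaussian tail
probability $p_e = 2(1 - \Phi(|w_e - \mu_e|/\sigma_e))$, clipped below at
$10^{-12}$ ("how unlikely is this weight under the normative edge
distribution" — no formula is prescribed, and the two-sided tail is the
natural operationalization). Regional scores accumulate evidence
Fisher-style, $S_r = -\sum_{e \ni r} \ln p_e$ over all incident edges
(unfiltered; a degree-normalized mean is available as an option), and
group-level maps report per-region means. Scores are nonnegative, zero only
at the template mean, monotone in single-edge deviations, and invariant to
joint rescaling of weights and template.

## Numerical and design choices

- Binarization threshold defaults to 0 (edge = any positive weight); no
  higher threshold is prescribed and the knob is exposed.
- Node indexing is 0-based in all reports and error messages; files are
  comma-delimited on write, comma/tab auto-detected on read; round-trips
  are lossless to 1e-12.
- Symmetry validation tolerance 1e-8; softmaxes are max-shifted;
  `dropout_cutoff` is interpreted as a fraction of the mean skeleton base
  weight.
- The `G2`/`G1` and `G1`/`G0` synthetic tasks are not symmetric: the
  edge-removal probability is convex in $t$, so the late pair carries about
  twice the topological signal of the early pair — mirroring the clinical
  situation in which the early-stage pair is hardest to separate. A side
  effect of the narrow synthetic `G1` (and its larger sample) is that the
  `G2`/`G1` task can edge out `G2`/`G0`, unlike in clinical data.
- All randomness flows through R's RNG (`set.seed`), including the
  compiled permutation loop; same config + seed ⇒ byte-identical outputs.

## Limitations

- The generator does not reproduce realistic degree distributions,
  region-volume normalization effects, or streamline-count magnitudes.
- Single-head attention and a two-layer stack only; no edge features.
- Staging uses PC1 only; the second manifold axis is reported but not
  modeled.
- Divergence scores carry no multiple-testing correction; they are
  descriptive rankings, not calibrated p-values.
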