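---
title: "Predicting chromatography solvent systems: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting chromatography solvent systems: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Purifying the product of an organic synthesis by normal-phase column
chromatography requires choosing an eluent: one or two solvents and, for a
pair, their mixing ratio. In practice this is scouted manually by thin-layer
chromatography. `eluent` models the choice as a supervised learning problem
over the reaction itself: given the reaction's molecules (reactants and
products, written as one dot-separated SMILES line), predict

1. the solvent system — a multilabel classification over ten common
   solvents, where a system has one or two labels; and
2. for two-solvent systems, the normalized mixing ratio — a regression onto
   a single number in (0, 1).

The two models run in sequence at inference time: the classifier proposes
labels; if exactly two are predicted, the ratio regressor is activated.
This hierarchical decomposition keeps each output simple — a 10-unit
sigmoid layer for the labels, one linear unit for the ratio.

## Label space and orientation conventions

Ten solvents form a closed label space (`solvent_labels()`). Systems are
always written in a fixed canonical priority order — the descending
frequency of the labels in the patent-derived corpus this task originates
from — so that exactly one representation of each pair exists ("ethyl
acetate, hexane", never "hexane, ethyl acetate"). The ratio of a pair is
normalized from its written form `a:b` to `a / (a + b)`, the fraction of
the *first* canonical label; the second solvent's share is the complement,
so the two always sum to one and only one number is predicted. A 9:1
hexane/ethyl-acetate eluent therefore becomes the pair
(ethyl acetate, hexane) with ratio 0.1 — the raw pair is re-oriented
whenever canonical ordering swaps the mentioned labels.

Written ratios with a zero component (`0:1`, `0:0`) are artifacts of
imperfect text extraction and are excluded from the ratio dataset (the
labels are kept for classification). Percentage gradients ("0–10% MeOH")
are likewise rejected: the model covers single isocratic mixtures only.

## Text mining

Solvent labels are mined from raw purification text with a surface-form
lexicon (synonyms, abbreviations, spacing variants), matched
case-insensitively and longest-form-first so "methanol" never double-counts
as "ethanol" and "diethyl ether" never as "ethyl ether". The first `a:b`
integer pattern supplies the raw ratio. Records with no lexicon hit or with
three and more solvents (too rare to model) are filtered out with an
auditable status.

## Datasets

Two datasets are assembled from extracted records: DS1 (reaction → label
set) and DS2 (reaction → normalized ratio; only two-solvent instances, a
subset of DS1). A 10% test split is held out with nearest-integer rounding,
stratified — by label set for DS1 and by ratio decile for DS2 — so the test
set preserves the output distribution. Stratum quotas are reconciled to the
exact overall test size by largest remainder.

Because the molecules of a reaction arrive in one arbitrary concatenation
order, training data are augmented by permuting the molecule order: each
*training* instance with `m` molecules gains `min(5, m! - 1)` distinct
non-identity permutations, sampled uniformly without replacement under the
seed. Augmentation runs after the split and only on the training side —
the corpus itself does not dictate an order, and augmenting before
splitting would leak near-duplicates of test reactions into training. The
permutation cap of 5 is the default of the upstream corpus construction;
caps 2–7 are supported, and for one seed a larger cap extends the smaller
cap's sample (the first draws are shared), which makes cap comparisons
paired rather than resampled.

Two no-model baselines anchor each task. For classification, over the
label-*set* distribution: the random baseline `sum(p_i^2)` (accuracy of
sampling predictions from the empirical distribution) and the majority
baseline `max(p_i)`. For regression, the MSE of the constant mean- and
median-predictors on the test subset. These are the numbers a trained
model has to beat before it is worth anything.

## Vectorization

Three input representations are supported:

* **Learned embedding (LE).** The reaction line is tokenized per character
  (a SMILES corpus uses a few dozen distinct symbols; on the full patent
  corpus about 56), padded to a fixed 200 symbols, and each symbol is
  embedded as a trainable 12-vector, giving a 200 × 12 input matrix that
  trains jointly with the network. Inputs longer than 200 characters are
  truncated with a warning; at desk scale none are.
* **Extended-connectivity fingerprints (ECFP).** Each molecule is hashed
  into 512 bits from its circular atom neighborhoods; with at most 8
  molecules per reaction this stacks into an 8 × 512 binary matrix (rows
  beyond the molecule count are zero), or a flattened 4096-bit vector for
  feed-forward input. The fingerprint radius defaults to 2 bonds — the
  ECFP4 convention, the common default — and is exposed as a parameter,
  as is the bit width. Bits are binary (presence/absence), not counts.
* **Auto-encoder latents (ECFP+E).** A fingerprint auto-encoder is trained
  to reconstruct reaction fingerprints through a 512-dimensional
  bottleneck (8× compression of the 4096-bit input) under binary
  cross-entropy; its frozen encoder then maps each reaction to a dense
  512-vector consumed by a feed-forward head.

The fingerprint implementation canonicalizes SMILES through OpenBabel
before extracting the molecular graph, so atom renumbering and
aromatic-vs-Kekulé writings of the same molecule produce identical bit
vectors; initial atom codes combine element, heavy-atom degree and total
bond order, and each refinement round hashes the sorted
(bond order, neighbor code) environment. Implicit-hydrogen counts and
formal charges are not part of the atom code — a simplification that
leaves the planted-rule recovery tasks unaffected but means the bits are
not numerically interchangeable with any specific cheminformatics
toolkit's ECFP bits.

## Auto-encoder topologies

Three encoder flavours are provided, all trained with Adam under binary
cross-entropy, latent width 512 by default (grid: 32–512):

* *Feed-forward*: 4096 → 512 → 4096 on the flattened input.
* *1D-CNN*: three convolutions of 256, 128 and 64 filters with kernels
  12, 10, 10 and pooling 2, 2, 2. A kernel of width 12 cannot slide along
  an axis of length 8, so convolution is laid along the 512-bit axis with
  the 8 molecule rows as input channels. The decoder mirrors the encoder
  with a dense layer, nearest-neighbour resizing back to 512 positions
  and four kernel-1 convolutions (256, 128, 64, then 8 sigmoid channels).
* *LSTM*: one LSTM layer of 512 units reads the 8 molecule rows as a
  sequence; the decoder repeats the latent vector 8 times through a
  second LSTM and a per-row sigmoid readout.

After training, the encoder is extracted and frozen: encoding is a pure
function, and downstream head training cannot alter encoder weights (the
package verifies this with a weight digest). Max pooling is used in the
CNN encoder and the auto-encoders default to the same optimizer, batch
size and epoch budget as the predictive models, since nothing in the
task dictates separate values; both choices are exposed.

## Predictive models and training

Model heads: a feed-forward network of three ReLU layers (256 → 128 → 64
by default, from the tested width grid 16–512), a 1D-CNN of three
64-filter convolutions (kernels 12, 12, 5; average pooling 3, 3, 3), or a
single LSTM layer of 512 units. The output layer is task-determined:
10 sigmoid units with binary cross-entropy for the solvents (each label
an independent binary decision), 1 linear unit with MSE for the ratio.
Latent-input (ECFP+E) models always use the feed-forward head; the
encoder flavour is chosen separately. Training uses Adam (learning rate
1e-3), batch size 256, 40 epochs and an internal 90/10
training/validation split, all seeded; the same seed on the same platform
reproduces the same weights (cross-platform bit-identity is not
promised). Divergence to a non-finite loss aborts with a diagnostic.

The networks themselves run on a small neural-network engine written in
the package (dense, embedding, 1D-convolution, average/max pooling, LSTM
and reshaping layers, with Adam). Every layer's backward pass is verified
against central finite differences in the test suite; this is the
load-bearing correctness argument for the whole training stack.

The multilabel decision rule is: predict every label scoring at least
0.5, clipped to the top two by score (systems never have more than two
solvents); if no label passes, predict the single argmax; break ties by
canonical priority. Ratio predictions are clipped into (0, 1) with a
warning when the linear output strays outside.

## Synthetic data: what it emulates and what it does not

The generator (`generate_synthetic()`) produces desk-scale corpora with
planted, recoverable structure, built on the same premise as the real
task: functional groups determine the solvent system. A pool of ~200
molecules (20 scaffolds × 10 decorating groups) is partitioned by SMARTS
triggers — carboxylic acid, primary amine, hydroxyl, nitrile — and each
reaction of 2–8 molecules is assembled around a sampled rule so that the
highest-priority triggered rule determines its labels. Two-solvent ratios
follow `base + increment × (trigger count)` plus Gaussian noise
(sd 0.02, clipped inside (0.02, 0.98)), the trigger count being an exact
function of the molecules' substructures. Rule weights are skewed (one
dominant pair system at ~50%) so the majority baseline is meaningfully
high, as in the real corpus. Each record also renders a purification
sentence from patent-style templates, with either solvent order and a
written integer ratio on a 1/20 grid, so the extraction module round-trips
end to end: on generated corpora the extraction recovers 100% of systems
and written ratios.

What passing on this generator shows: the vectorizations expose
functional-group structure, the networks can learn label rules and count
based ratio laws well above the baselines, and every pipeline stage
composes correctly. What it does not show: performance on real patent
text (far messier than the templates), chemistry beyond decorated
scaffolds, label noise (2–4% in the real corpus), or the scale of the
real task — the published patent-scale scores require the full
454k-instance corpus and are out of reach of a desk-scale run by design.

## Evaluation

Classification reports pool every (instance, label) decision into
TP/TN/FP/FN: label accuracy `(TP+TN)/total`, micro precision, recall and
F1, plus subset accuracy (exact set match) — both accuracies are
reported side by side because "accuracy" of a multilabel model is
quotable either way, and the per-class table covers the imbalance.
Regression reports R² (against the truth mean), Pearson correlation and
MSE. Repeated runs are summarized as mean ± Student-t 95% half-width
(n−1 degrees of freedom; only the confidence level is inherited from
common practice, the t form is this package's choice).

## Numerical choices and degenerate inputs

* Sigmoid outputs are clamped to [1e-7, 1-1e-7] inside the
  cross-entropy; gradients flow through the clamp unmodified.
* Weight initialization is Glorot-uniform, seeded; LSTM forget-gate
  biases start at 1.
* Stratified splitting refuses datasets under 10 instances; DS2 file
  parsing rejects rows without exactly two labels and a ratio in (0, 1).
* Constant-truth regression leaves the correlation undefined (`NA` with
  a warning) rather than inventing a value.
* Pearson's formula with population standard deviations and a 1/n sum is
  algebraically the sample correlation, so `cor()` computes it exactly.
* The desk scales used by the shipped checks — 5,000 synthetic reactions,
  40 epochs for the recovery study; 1,000 texts for the extraction
  round-trip — were chosen once as the smallest sizes at which the
  planted structure is comfortably learnable and the checks are stable
  under reseeding.

## Known limitations

* ECFP bits are package-internal hashes; Tanimoto comparisons across
  toolkits are not meaningful.
* The LSTM and CNN paths are exercised at reduced width in the shipped
  checks; at full 512-unit width they train correctly but slowly on a
  single CPU.
* Extraction handles isocratic `a:b` ratios only; gradients, percentages
  and three-solvent systems are rejected by design.
* The products-only input variant collapses product fingerprints by OR,
  losing per-molecule identity when a reaction has several products.
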