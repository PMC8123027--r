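# eluent

Predicting normal-phase column chromatography purification conditions —
the eluent — from reaction SMILES.

After an organic synthesis, the crude product is typically purified on a
silica column, and someone has to choose the mobile phase: one or two
solvents and, for a pair, their mixing ratio. That choice is usually
scouted by thin-layer chromatography. `eluent` treats it as a supervised
learning problem over the reaction itself, for chemists and
cheminformaticians who want a data-driven starting point instead of a
blank TLC plate:

1. **Solvent system** — multilabel classification over a closed set of ten
   solvents; a system is one or two labels, canonically ordered (ethyl
   acetate before hexane, etc.).
2. **Ratio** — for two-solvent systems, regression of the normalized ratio
   γ = a/(a+b) ∈ (0, 1), the fraction of the first solvent; the second is
   its complement 1 − γ (a written 9:1 becomes 0.9).

The two models run hierarchically: classify, and if exactly two solvents
are predicted, activate the regressor.

The package contains the full experimental apparatus around that core:
mining solvent labels and raw ratios from purification text; assembling
the label dataset (DS1) and ratio dataset (DS2) with a stratified 10%
hold-out; molecule-permutation augmentation of training reactions
(min(5, m!−1) extra orderings per instance); three vectorizations —
learned character embeddings (200 × 12), multi-molecule
extended-connectivity fingerprint matrices (8 × 512, flattened 4096), and
512-dimensional fingerprint auto-encoder latents (feed-forward, 1D-CNN or
LSTM encoders, 8× compression); the neural models themselves (FFNN /
1D-CNN / LSTM heads; Adam, batch 256, 40 epochs, BCE or MSE) on a small
fully-tested network engine; random/majority and mean/median-MSE
baselines; multilabel and regression metrics with t-based confidence
intervals over runs; and a synthetic reaction generator whose planted
functional-group rules make every stage testable offline.

## Worked example

Generate a synthetic corpus with planted functional-group rules, build
and split both datasets, augment, train the two models, and predict a
purification system for a new reaction:

```r
library(eluent)

syn <- generate_synthetic(synthetic_config(n_reactions = 2000, seed = 7))
ds1 <- split_dataset(syn$ds1, test_fraction = 0.10, seed = 7)
ds2 <- split_dataset(syn$ds2, test_fraction = 0.10, seed = 7)

classifier <- train_model(
  model_config("solvents", "ecfp", "ffnn", epochs = 15, seed = 7),
  augment_dataset(ds1, cap = 5, seed = 7)
)
regressor <- train_model(
  model_config("ratio", "ecfp", "ffnn", epochs = 15, seed = 7),
  augment_dataset(ds2, cap = 5, seed = 7)
)

test <- ds1[ds1$split == "test", ]
classification_metrics(test$labels, decide_labels(predict(classifier, test)))
#> Multilabel classification over 200 instances:
#>   subset accuracy : 0.9950
#>   label accuracy  : 0.9995
#>   precision       : 1.0000
#>   recall          : 0.9973
#>   F1              : 0.9986

test2 <- ds2[ds2$split == "test", ]
regression_metrics(test2$ratio, as.vector(predict(regressor, test2)))
#> Ratio regression over 170 instances:
#>   R-squared : 0.8265
#>   Pearson R : 0.9099
#>   MSE       : 0.00190

baselines(ds1)
#> Solvent-system baselines (label sets):
#>   random baseline   : 0.3329
#>   majority baseline : 0.5150
#>   most common set   : ethyl acetate + hexane

predict_system(classifier, regressor, "Oc1ccccc1.OCc1ccccc1.CCCC.Oc1ccc2ccccc2c1")
#> # A tibble: 1 x 5
#>   reaction_smiles                           labels    scores     ratio complement
#>   <chr>                                     <list>    <list>     <dbl>      <dbl>
#> 1 Oc1ccccc1.OCc1ccccc1.CCCC.Oc1ccc2ccccc2c1 <chr [2]> <dbl [10]> 0.569      0.431
```

The example reads: the classifier recovers almost every planted solvent
system on held-out reactions (subset accuracy 0.995, far above the 0.515
majority baseline), the ratio regressor explains ~83% of the held-out
ratio variance at this quick 15-epoch scale (MSE 0.0019 against a
mean-MSE baseline of ~0.011; the full 5,000-reaction, 40-epoch study in
the test suite reaches R² ≈ 0.92), and the hierarchical predictor
proposes an ethyl acetate/hexane system near 57:43 for a hydroxyl-rich
reaction — the planted rule for its three hydroxyl-bearing molecules is
0.3 + 0.1·3 = 0.6.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and plot
with `autoplot()` (training curves, per-class metrics, label-set
distributions). A thin command-line wrapper with the same stages
(`synth`, `extract`, `build-dataset`, `augment`, `train`, `predict`,
`evaluate`, `baselines`, `run-all`) ships in `inst/cli/eluent-cli.R`.

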