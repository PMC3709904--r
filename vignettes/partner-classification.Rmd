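---
title: "Classifying TF binding partners from sequence composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying TF binding partners from sequence composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfpartner)
```

## The model

`tfpartner` predicts the functional class of a protein known to bind a
transcription factor (TF): is the partner itself a TF, a transcription
co-factor (TcoF), or some other nuclear protein? The only inputs are the
two amino-acid sequences and the fact that they interact.

The representation is deliberately simple. For an amino-acid index $w$
(one physico-chemical property value per standard residue, AAindex1
format) and a protein sequence $s = s_1 \dots s_n$, the feature is the
composition average

$$ f_w(s) = \frac{1}{n} \sum_{i=1}^{n} w(s_i), $$

which depends only on residue frequencies, not on residue order. A pair
(anchor TF $a$, partner $b$) is the concatenation
$[f(a) \,\|\, f(b)] \in \mathbb{R}^{2k}$ for $k$ indices.

Classification is a cascade of two binary tasks rather than one
three-class model:

* **Model 1**: partner is *TF or TcoF* (positive) vs *other nuclear
  protein* (negative), trained on all labeled pairs;
* **Model 2**: partner is *TcoF* (positive) vs *TF* (negative), trained
  only on TF–TF and TF–TcoF pairs;
* the cascade calls `OTHER` when Model 1 scores below the threshold and
  otherwise lets Model 2 decide `TCOF` vs `TF`.

Each model is a *dual* Random Forest: a forward sub-model trained on rows
ordered (anchor, partner) and a reverse sub-model trained on the same rows
with the two halves of every TF–TF row swapped. Only TF–TF rows swap
because only there is the ordering arbitrary — in TF–TcoF and TF–other
pairs the anchor side is structurally distinct. A pair's confidence score
averages the two sub-models' positive-class probabilities; each forest's
probability is itself the average of per-tree class probabilities
(`ranger` probability forests).

### Assumptions

* Composition sufficiency: the signal that separates the classes is
  assumed to live in average residue composition. Any information in
  residue order, domains, motifs or structure is invisible to the model.
* The anchor column of the pair table really is a TF; the method never
  checks this.
* Training labels are trusted; conflicting labels for the same pair are
  rejected rather than voted on.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_trees` | 100 | trees per forest; doubling it mainly tightens probability estimates |
| `mtry` | $\lfloor\sqrt{2k}\rfloor$ | features tried per split, the standard Random Forest default |
| `max_depth` | unlimited | tree depth cap (0 = none) |
| `seeds` | (1, 2) | independent seeds for the forward and reverse sub-models, so the two forests are not tree-for-tree coupled while runs stay reproducible |
| `threshold` | 0.5 | decision threshold on the averaged score; a score exactly at the threshold is called positive so the rule is deterministic |
| `missing_policy` | `drop` | AAindex entries with undefined residue values are removed; `impute_mean` substitutes the index's mean instead. Averaging over undefined values has no meaning, so dropping is the conservative default |
| `ambiguity_policy` | `skip` | nonstandard residues (B, Z, X, U, O, J) are excluded from the feature mean; `error` aborts instead. UniProt sequences do contain X/U, so skipping is the practical default |
| `scoring_mode` | `paper` | feed the pair as given (TF first) to both sub-models and average; `strict` additionally averages over both orderings, making score(a,b) = score(b,a) an exact identity |

No feature scaling is applied anywhere: Random Forests are invariant to
monotone per-feature transformations, so standardisation would only add a
source of irreproducibility.

## The synthetic generator

Real training data for this problem comes from curated interaction
databases and UniProt sequences, which the package deliberately does not
fetch. Instead, `generate_dataset()` builds datasets with *planted*
compositional signal:

* one base residue-frequency profile (perturbed uniform), tilted per role
  by $\mathrm{softmax}(\log p_{\text{base}} + \delta z_{\text{role}})$
  with fixed Gaussian directions $z$ — at $\delta = 0$ all three role
  profiles coincide, and their pairwise total-variation distance grows
  with $\delta$;
* per-protein compositions drawn Dirichlet($c \cdot p_{\text{role}}$)
  around the role profile (default concentration $c = 200$);
* i.i.d. residues, lengths uniform on 80–500 (a plausible span for
  nuclear proteins);
* a fresh anchor TF and a fresh partner per pair, so instances are
  exchangeable under cross-validation;
* a fully defined synthetic AAindex fixture (values uniform on $[-5, 5]$)
  rather than redistributed database content.

The default preset (200 pairs per class, $\delta = 0.5$, 40 indices,
seed 42) is the package's reference condition: separated enough that the
pipeline should recover the classes at high accuracy, small enough to run
in seconds. The test suite checks recovery at $\ge 0.90$ 10-fold CV
accuracy there, the fallback to the majority-class rate at $\delta = 0$,
and that mean accuracy is monotone in $\delta$ over $\{0, 0.1, 0.3,
0.5\}$ across three generator seeds (240-pair datasets, 5-fold CV, to
keep the sweep fast).

What passing these tests does **not** show: real TF/TcoF/other classes
need not differ in composition the way planted profiles do, real
interaction data has hub TFs (the generator has none, by design, to keep
CV instances exchangeable), shared proteins across pairs, label noise and
length/composition confounds. The generator validates the machinery, not
the biological claim.

## Numerical choices

* **Signatures.** An index set is identified by a 32-bit FNV-1a hash of
  its ordered accession list. The signature changes exactly when the
  ordered accession list changes; models refuse features carrying a
  different signature. Mean-imputation alters values but not accessions,
  so the policy is recorded in the feature manifest instead.
* **Exact score arithmetic.** The reported score is always the exact
  floating-point mean of the two recorded sub-scores. In strict mode each
  sub-score is first averaged over both orderings; swapping the input
  pair permutes the same two addends, so symmetry holds exactly, not
  approximately.
* **Metrics.** Confusion counts are integers; each rate is one integer
  division. Zero-denominator rates (no positives, or no negatives, in a
  test set) are reported as `NA`, never coerced to 0. Cross-validation
  pools counts over folds (micro-average) before computing rates —
  deterministic and safe when small folds would have undefined per-fold
  rates.
* **Fold assignment.** Pairs are put in a canonical (label, id) order
  before stratified fold assignment, so the result depends on the seed
  and the data, never on file row order. Every class must have at least
  $k$ members, except `k = n`, which is accepted as explicit
  leave-one-out (with fewer than $k$ members per class, stratified
  $k$-fold is not defined, but leave-one-out is).
* **Splits.** The stratified hold-out takes `round((1 - f) * n_class)`
  per class, matching proportion-preserving hold-outs such as 90/10 on a
  60/40 class balance exactly.
* **Degenerate inputs.** Sequences with no scorable residues,
  single-class training sets, NaNs in the design matrix, width or
  signature mismatches, truncated model artifacts and Model 2 without
  both TF–TF and TF–TcoF instances all fail loudly with specific errors.
  Model artifacts embed a 20-row probe with its expected sub-model
  scores; `load_model()` re-scores the probe and refuses the artifact
  unless predictions are bit-identical.

## Design decisions that were genuinely open

* **Positive class of Model 2** is TcoF. Some convention is needed for
  sensitivity/specificity to be well defined; TcoF annotation is the
  rarer and more interesting call, making it the natural "detection"
  target. It is a convention, not a claim — swap the interpretation of
  the two rates if the opposite convention is preferred.
* **Prediction-time orientation** in the default scoring mode feeds the
  pair as given to both sub-models, mirroring a user who enters (known
  TF, partner) once. Exact symmetry, when wanted, is an explicit mode
  rather than a silent change to the score's meaning.
* **Duplicate handling**: exact duplicate pair rows collapse with a
  warning (interaction sets are defined on unique instances);
  direction-swapped TF–TF rows are distinct instances unless identical.
* **Missing AAindex values** are dropped before featurization by
  default; whether a curated reduced feature set should be filtered
  before or after selection is left to the caller, who controls the
  selection list.

## Problem sizes

The test suite trains on datasets of 30–120 pairs with 25–50 trees per
forest; the end-to-end checks use the 600-pair reference preset with the
default 100 trees, and the acceptance script repeats the 10-fold
cross-validation of both models on that preset plus its null counterpart.
These sizes were chosen so that a full run stays in the tens of seconds
while keeping every fold's training set large enough for stable forests.

## Limitations

* Composition averaging discards all positional information; two
  sequences with the same residue counts are indistinguishable.
* Scores are raw averaged tree-class probabilities; no calibration is
  applied, so thresholds other than 0.5 should be chosen on held-out
  data.
* The cascade propagates Model 1 errors: a TcoF pair rejected by Model 1
  is lost to Model 2 regardless of how confident Model 2 would have been.
* Only the 20-value AAindex1 dialect is supported; residue-pair matrices
  (AAindex2/3) and domain- or motif-based features are out of scope.
* No redundancy reduction: homologous proteins appearing in many pairs
  will inflate cross-validation estimates on real data.
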