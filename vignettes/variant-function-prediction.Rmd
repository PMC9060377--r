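---
title: "Predicting the functional impact of KCNQ1 variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the functional impact of KCNQ1 variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(kvarann)
```

## The problem

Missense variants of the cardiac potassium channel KCNQ1 (K~V~7.1) cause
long QT syndrome type 1, but most of the >1000 known variants lack the
electrophysiological characterization needed to call them benign or
pathogenic. `kvarann` implements a channel-specific predictor: given a
single amino-acid substitution, it scores four functional parameters of
the channel — peak current density (I~Ks~), voltage of half-maximal
activation (V~1/2~), and the activation and deactivation time constants
(τ~act~, τ~deact~) — each as *normal* (0) or *dysfunctional* (1).

Three ingredients feed the model:

1. **A labeled functional dataset.** Per-variant patch-clamp
   measurements normalized to wild type (%WT) are converted to binary
   labels with fixed criteria (see below).
2. **Residue microenvironment descriptors** computed from a
   membrane-oriented 3-D structure of the channel.
3. **Evolutionary substitution scores** taken from PSI-BLAST
   position-specific scoring matrices (PSSMs).

A multitask feed-forward network with four outputs is trained on these
features under 25-fold cross-validation, and an input-sensitivity
analysis relates features to functional parameters.

## Labeling criteria

A parameter is dysfunctional when it crosses a loss-of-function (LOF)
or gain-of-function (GOF) bound, in %WT:

| parameter | LOF    | GOF    |
|-----------|--------|--------|
| I~Ks~     | < 55   | > 115  |
| V~1/2~    | > 130  | < 80   |
| τ~act~    | > 170  | < 70   |
| τ~deact~  | < 75   | > 125  |

Two special rules complete the scheme: a parameter that could not be
measured (a blank, `NA` or `ND` cell) is dysfunctional, and a severe
loss of peak current (I~Ks~ ≤ 17 %WT) makes **all four** parameters
dysfunctional, since a channel passing almost no current has no
meaningful kinetics. Inequalities are strict: a value exactly at a
bound is normal. The τ~act~ normal band defaults to 70–170 %WT — the
wider band motivated by otherwise wild-type-like slow activators —
while `criteria_table(tau_act_band = c(80, 120))` restores the narrow
band for ablation experiments.

```{r}
classify_record(list(iks = 10, vhalf = 100, tau_act = 100, tau_deact = 100))
classify_direction(list(iks = 120, vhalf = NA, tau_act = 100, tau_deact = 100))
```

Because measured variants cluster in a few channel regions, the dataset
is augmented with one *non-perturbing* variant per structurally
resolved position — the residue "substituted" by itself, all four
parameters at 100 %WT, all labels normal. These records expose the
network to every structural neighborhood and anchor the all-zero
substitution signature to the benign class.

## Biophysical features

All geometric features use one representative point per residue: the
side-chain heavy-atom centroid, with the α-carbon as fallback for
glycine and unresolved side chains. A sub-residue point is needed
because the smallest functional-density radius is 1 Å; `read_structure`
can be switched to Cβ or Cα points. The coordinate frame must already
be membrane-oriented (z = membrane normal, z = 0 the mid-plane), as in
OPM-style depositions.

* **Pore-axis distance** separates pore-domain from voltage-sensor
  variants. The default axis runs along z through the x–y centroid of
  the representative points; it can be overridden explicitly or by a
  list of pore-lining residues.
* **Membrane burial** is a depth weight from a three-layer slab model:
  1 inside a 30 Å hydrophobic core, half-cosine decay across each 5 Å
  interface, 0 in bulk solvent. The form was chosen as the simplest
  smooth, bounded function matching a three-layer model; both
  thicknesses are parameters of `membrane_model()`.
* **Functional density** of a property (polarizability, hydrophobicity)
  is the inverse-distance-weighted average over residues within a
  radius (1, 6.5 or 12 Å), site excluded, distances floored at 1 Å so
  weights stay bounded. An empty neighborhood returns the site's
  (mutant) property, so the 1 Å feature degrades to a point property.
* **Neighbor vector** measures solvent exposure as the norm of the
  weighted mean of unit vectors to neighbors, with a cosine-smooth
  weight from 1 at ≤ 3.3 Å to 0 at ≥ 11.4 Å: near 0 = buried
  symmetrically, 1 = fully exposed (or no neighbors).
* **Substitution deltas** (H-bond donor and acceptor counts, van der
  Waals volume) and the **mutant residue properties** (hydrophobicity,
  polarizability, steric parameter) come from a per-residue table
  shipped as a documented, user-replaceable TSV
  (`load_property_table()`). The shipped scales are the
  Fauchère–Pliska octanol/water hydrophobicity (positive =
  hydrophobic), a normalized side-chain polarizability, a graph-shape
  steric index, residue vdW volumes in Å³, and side-chain H-bond site
  counts at pH 7; the file header states each convention. Any scale
  with the same layout can be substituted without code changes.

The evolutionary features are ΔPSSM values — the log-odds score of the
mutant minus the wild-type residue at the position — from matrices
computed against the NCBI non-redundant and UniRef50 databases. PSSM
generation itself is out of process: the package parses the PSI-BLAST
ASCII format (`parse_pssm`) and treats the matrices as inputs, keeping
results independent of database versions.

Three published feature sets exist (`feature_names()`): `BIOPHYS14`
(all 14 biophysical descriptors), `EVO2` (both ΔPSSM scores), and
`COMBINED12` — the eleven biophysical descriptors that survive
combination (neighbor vector and the two steric parameters are
dropped) plus ΔPSSM(NR).

## Network and training

The multitask network is fully connected:
input → 32 leaky-ReLU units (33% dropout) → second hidden layer →
4 sigmoid outputs. The second hidden layer has 12 units with 33%
dropout for `EVO2`/`COMBINED12` and 8 units without dropout for
`BIOPHYS14`; input dropout is 5% (20% for `BIOPHYS14`). Hidden neurons
use the leaky rectifier `f(x) = x` for `x > 0`, `0.05x` otherwise. The
paper-stated output range [0, 1] forces a bounded output activation, so
the four output neurons are logistic; this is the only bounded choice
consistent with thresholding scores at 0.5.

Training is classical momentum SGD (learning rate 0.001, momentum 0.5)
for 1200 full-batch iterations. Design choices where the protocol was
open:

* **Surrogate loss.** "Accuracy at 0.5" is not differentiable, so it
  serves as the monitoring/selection criterion while gradients come
  from binary cross-entropy (squared error available via
  `network_config(loss = "mse")`). The loss is summed over the batch
  and averaged over the four outputs; normalizing by outputs only keeps
  the gradient scale independent of batch size, which is what makes a
  learning rate of 0.001 effective within 1200 full-batch iterations.
* **Iteration** means one full-batch update — natural and exactly
  reproducible at a dataset scale of ~470 records.
* **Dropout** uses inverted scaling (activations divided by the keep
  probability during training), so inference needs no rescaling; at
  rate 0 the training pass reduces exactly to the inference pass.
* **Snapshot selection.** Monitor accuracy at threshold 0.5 is
  evaluated every 10 iterations and the best snapshot is returned, ties
  resolved toward the later snapshot. (Whether the original models kept
  the best or the final snapshot is unstated; best-snapshot is the
  conservative reading of an "objective function" used for selection.)
* **Initialization** is seeded Glorot-uniform,
  ±sqrt(6/(fan_in+fan_out)). With all seeds fixed, the full
  train→predict path is bit-for-bit reproducible.

## Cross-validation and evaluation

`make_cv_plan` shuffles the records and partitions them round-robin
into 25 subsets (sizes differ by ≤ 1; for 470 records the typical
split is 432 training / 19 monitoring / 19 test). Each rotation trains
one network; the 25 models form the prediction ensemble (`run_cv`),
whose output is the member average.

Within each training fold, experimental records are oversampled 3:1 —
each replicated three times, non-perturbing records once — which
roughly balances the two populations and keeps the network from
overtraining on non-perturbing records. The feature scaler (per-feature
z-scoring) is fitted on the training fold only.

Decision thresholds are tuned per output by scanning 0 to 1 in steps of
0.01 for the best MCC. Tuning uses the pooled *monitoring*-fold
predictions and is applied to the pooled *test*-fold predictions, so
the headline metrics remain honest to unseen data (the alternative —
tuning on test predictions — is the optimistic reading of the
protocol; the monitoring choice is deliberate). MCC handles the
imbalanced classes; a zero denominator is defined as 0. ROC curves
sweep all thresholds and the AUC equals the pair-counting rank
statistic, ties counting one half. Headline metrics are computed on the
experimental records, matching the published protocol; the report also
carries pooled all-record MCCs, the non-perturbing benign accuracy, and
the entropy separation.

**Entropy separation** quantifies how well predictions at a 0.05
boundary separate non-perturbing from experimentally benign records:
the weighted average of the binary entropies of the class composition
on each side (0 = perfect separation, 1 = both sides maximally mixed).
The exact entropy formula of the original analysis is not published;
split entropy is the package's stand-in, exact at both endpoints.

## Input sensitivity

`input_sensitivity` perturbs each standardized feature by +0.1 (in
scaled-feature standard deviations, applied after scaling — both the
perturbation size and its placement are package choices; the original
protocol says only "a small amount") and records the sign of each
output's movement for every record and member model. The net
consistency of a feature–output pair is
`(n_up − n_down) / n_total`, pooled over records, the 25 member models
and replicate ensembles; responses below 1e-12 in magnitude count to
neither side. Only signs are reported: movement magnitudes depend on
feature rescaling and are deliberately not comparable.

## The synthetic fixture generator

The package is testable end to end without external downloads:

* `synthetic_structure()` builds an idealized α-helical bundle (1.5 Å
  rise, 100°/residue) around the z axis spanning the membrane slab. The
  default — 15 helices × 23 residues at ring radius 16 Å — resolves 345
  positions, the size of the real channel's structural model.
* `synthetic_pssm()` writes valid PSI-BLAST ASCII matrices with
  tunable conservation.
* `synthetic_variant_dataset()` samples 125 missense variants, computes
  their **real** features through the package's own pipeline, and draws
  labels from a planted rule: dysfunctional when `β·z + ε > 0` with
  `ε ~ N(0, σ²)`, features standardized over the experimental subset.
  The defaults plant two features of |β| = 4 per output with σ = 0.5,
  and the manifest records the full truth so recovery experiments are
  falsifiable. With σ = 0 and a single planted feature the labels are
  exactly the feature's sign. 345 non-perturbing records (labels all
  normal) complete the 470-record composition.
* `synthetic_functional_table()` generates a measurement table in the
  layout of the study's deposited dataset, with %WT values drawn inside
  the criteria regions to realize the published peak-current
  composition (71 LOF / 15 GOF / 39 WT-like, including severe-loss and
  unmeasurable cases). It is a synthetic stand-in — the real deposit is
  external — but classifying it from raw values must recover the
  composition, which is what the dataset tests assert.

What the synthetic data does *not* emulate: real side-chain packing and
atom-level contacts (residues are representative points on ideal
helices), realistic sequence evolution in the PSSMs, correlations
between the four functional parameters beyond shared planted features,
and measurement noise structure of patch-clamp data. Tests passing on
these fixtures therefore demonstrate that the machinery — features,
training, evaluation, sensitivity — is correct and recovers known
ground truth at the study's scale; they do not certify accuracy on real
channel data, which additionally depends on the user's structure,
PSSMs and measurements.

## Numerical conventions and degenerate inputs

* Functional-density distances are floored at 1 Å; empty neighborhoods
  fall back to the site's own (mutant) property.
* A residue with no neighbors inside 11.4 Å has neighbor-vector
  exposure 1.
* Constant features z-score to 0 rather than NaN.
* MCC with a degenerate margin is 0; ROC requires both classes and
  fails loudly otherwise; threshold scanning breaks ties toward the
  smaller threshold; the decision rule calls scores ≥ threshold
  dysfunctional.
* Training raises an error (with the iteration number) if weights or
  outputs become non-finite.
* All randomness — bundle sampling, PSSM noise, label noise, CV
  shuffles, dropout, initialization — is governed by explicit seeds.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the full pipeline at
the study's own scale: 470 records, 25-fold cross-validation, 1200
training iterations per member, with three replicate ensembles for the
sensitivity analysis. Geometry and metric oracles run on hundreds of
randomized small cases. These sizes keep a complete run in the
single-digit minutes on one CPU while exercising every code path at
full fidelity.

## Known limitations

* Predictions are only possible for residues resolved in the supplied
  structural model, and the tool does not orient structures in the
  membrane itself.
* Exact ΔPSSM values depend on the user's database versions and
  PSI-BLAST settings; they are treated as inputs, not reproduced.
* The polarizability normalization of the original feature extraction
  is not fully specified; the shipped scale is documented and
  replaceable, and the single published calibration point (functional
  density of polarizability 0.19 at R195, 6.5 Å) is exposed as an
  integration check that requires the real structure.
* Heterozygous/dominant-negative effects, multi-conformation or
  dynamics-derived features, and clinical pathogenicity interpretation
  are out of scope.
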