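---
title: "Modelling nitrogenase activity with feature-group selection and stacking"
author: "nifstack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nitrogenase activity with feature-group selection and stacking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nifstack)
```

## The modelling problem

Nitrogenase activity — the rate at which a diazotrophic strain reduces
acetylene, in nmol C₂H₄/mg protein/hour — varies over several orders of
magnitude across strains, and measuring it is slow. `nifstack` predicts it
from genomic information alone: the three structural proteins of molybdenum
nitrogenase (nifH, nifD, nifK), the coding sequences of eight nif-operon
genes, the operon's genomic organisation, and the copy numbers of 34
fixation-related genes.

Two targets are derived from the measured activity $x$:

* a binary label, positive iff $x$ **strictly exceeds** 50 nmol C₂H₄/mg
  protein/hour. The strict inequality is a convention (a measurement exactly
  at the threshold is "not more than 50", hence negative); the threshold is a
  configurable argument of `binarize_activity()`.
* a regression target $y = \log_{10}(x + 2)$. The offset keeps $x = 0$
  finite and compresses the heavy right tail; `inverse_transform_activity()`
  is its exact inverse.

## Feature groups

Nine named groups encode a strain. All protein-level and codon-level vectors
are averaged element-wise over the three structural proteins, so one strain
contributes one row per group.

**Conjoint triad (CT, 343).** The 20 amino acids are grouped into 7 classes
by side-chain dipole moment and volume ({A,G,V}, {I,L,F,P}, {Y,M,T,S},
{H,N,Q,W}, {R,K}, {D,E}, {C}); entry $(a,b,c)$ is the count of consecutive
residue triplets with class signature $(a,b,c)$ divided by $L-2$. The class
map is an argument, so alternative clusterings can be swapped in. Relative
frequencies are the default; the original min–max rescaling of triad counts
is available via `rescale = TRUE` but is off because plain frequencies keep
the simplex normalisation that the tests assert.

**Dipeptide composition (DPC, 400).** Count of each ordered residue pair
divided by $L-1$, row-major over the alphabetical residue order.

**Pseudo-amino-acid composition (PAAC, 50).** Composition (20) plus
$\lambda = 30$ sequence-order correlation tiers. Tier $j$ is the mean over
positions of $\Theta(R_i, R_{i+j})$, the mean squared difference of three
standardised physicochemical properties (hydrophobicity, hydrophilicity,
side-chain mass; classical tables, standardised to mean 0 and population sd 1
over the 20 residues). Components are weighted by $w = 0.05$ — the classical
default, chosen because only the output dimension (20 + 30) is externally
fixed — and normalised so all 50 sum to 1. On a homopolymer every $\Theta$
vanishes and PAAC reduces exactly to the composition, which the tests use as
an oracle. Note PAAC is invariant to sequence reversal (the lag correlations
are symmetric); it is sensitive to permutations that change the lag
structure.

**RSCU (61).** For codon $c$ in a synonymous family of size $n_f$ with
family count $N_f$: $\mathrm{RSCU}_c = \text{count}_c \cdot n_f / N_f$, over
the 61 sense codons of the standard genetic code in lexicographic order
(A < C < G < T). Codons of families unobserved in a gene take fill value 0 by
default; a neutral fill of 1 is available. The zero fill follows the literal
reading that all 61 codons enter downstream statistics; the choice matters
only for the distance feature below.

**Euclidean codon distance (1).** $\mathrm{ECD} = \sqrt{\sum_{i=1}^{61}
(x_i - 1)^2}$ against the neutral reference where every codon has RSCU 1.
All 61 entries enter the sum, including fills.

**Expression (24).** For each of nifA, nifB, nifD, nifE, nifH, nifK, nifN,
nifX (fixed order), the triple (CAI, E, Fop). CAI is the geometric mean of
relative-adaptiveness weights over the gene's codons, excluding the
single-codon families Met and Trp, with weights floored at $10^{-4}$; Fop is
the fraction of codons equal to their family's preferred codon. The weights
come from a reference gene set: the bundled default
(`inst/extdata/reference_usage.tsv`) is **synthetic**, derived once and
deterministically from the package's own simulated highly-expressed gene
set, because no canonical reference applies across the diverse source
organisms; users supply their own table via `read_reference_usage()` when an
organism-specific set exists. The bias statistic E is defined in this
package as the family-share-weighted mean absolute deviation of within-family
codon frequencies from uniform — zero iff every used multi-codon family is
used uniformly, invariant to gene length at fixed proportions. External
packages compute related statistics under the same name with unspecified
conventions; numerical agreement with them is not claimed.

**Gene distance (1).** The genomic span `max(end) − min(start)` of the three
structural genes (1-based inclusive coordinates, GenBank convention),
invariant to gene order and strand. A pairwise midpoint-distance sum is an
alternative mode. Genes on different replicons are an error by default
(sentinel configurable); circular replicons are treated as linear — a
documented limitation.

**Copy number (34).** Counts of the canonical 34 genes (nifD, nifH, nifK,
amtB, fix/gln/nif/rnf accessory genes) in a fixed order.

**Embedding (D).** Protein language-model inference is out of scope;
per-residue or per-protein matrices computed elsewhere are ingested from TSV
(`load_embedding_table()`), mean-pooled along the sequence axis over residue
rows only (no special tokens), and averaged over the three proteins. Widths
of known sources are validated (ProtT5 1024, ProteinBERT 512, Ankh 1536,
ESM C 960/1152/2560). A deterministic pseudo-embedding backend with the same
interface (seeded hash of residue identity and ±1 context window) supports
tests and simulation.

## Selection procedures

**Incremental feature-group selection (IFS).** Round 1 scores every single
group by $k$-fold cross-validation (stratified folds for classification,
shuffled for regression; $k = 5$); each later round scores the retained set
plus each unused group and keeps the best extension. The search always runs
to exhaustion (all groups included), evaluating $G + (G-1) + \dots + 1$ sets;
the final selection is the global maximum over everything evaluated, ties
broken by fewer groups, then by evaluation order. The default evaluator is
gradient-boosted trees (the evaluator is injectable, and the tests use a
logistic evaluator for speed). The objective is F1 on predicted labels
(classification) or R² (regression); an F1 undefined on a fold counts as 0.
Optionally the whole CV is repeated under consecutive seeds and averaged
(`repeats`).

**Incremental mutual-information learner selection (IMI).** Candidates are
fitted on the first 60% of the training data (the same 60/40 protocol as the
stacking layer) and produce outputs on the held-out 40%. The objective is
the mutual information, in nats, between the joint outputs of the current
learner set and the truth. For classification the outputs are predicted
labels and the MI is the plug-in estimate on the joint empirical
distribution — predicted labels rather than probabilities, a deliberate
choice since only the label-level decision enters the final ensemble's
confusion counts. For regression the outputs are stacked as a multivariate
variable and MI is estimated by the Kraskov k-nearest-neighbour estimator
(first variant, $k = 3$, max-norm neighbourhoods); negative estimates are
clamped to 0, and constant outputs receive a deterministic seeded jitter of
$10^{-10}$ so the neighbour counts stay defined. Candidates that fail to fit
are skipped with a warning. Greedy growth and tie-breaking follow IFS.

## The stacking ensemble

Training samples are split 60/40 (stratified on the label for
classification). Base learners fit on Training-60; their outputs on
Training-40 — one positive-class probability per base learner for
classification (the complementary probability is redundant for a binary
task), one prediction per learner for regression — form the BLP vector. The
meta learner fits on the Training-40 features augmented with the BLP
columns, so its input width is the feature width plus the number of base
learners. At prediction time base outputs are recomputed for the new samples
and the meta learner produces the final probability or value. Base learners
stay fitted on Training-60 (no refit on the full training set before test
prediction).

Default configurations are the tuned values: classification — KNN base
(5 neighbours, uniform weights) and random-forest meta (200 trees, unlimited
depth, min split 5, log2 feature subsampling, bootstrap) with decision
threshold 0.55; regression — decision-tree (depth 5, min split 10) and
gradient-boosted (depth 5, learning rate 0.01, 200 rounds, gamma 0) bases
with an RBF support-vector meta (C = 1, ε = 0.01, scale kernel width). The
tuned SVR kernel is recorded ambiguously in its source configuration; the
radial basis kernel is assumed here. The classification threshold comparison
is inclusive (probability ≥ threshold → positive). Grid search
(`grid_search()`, grids in `tuning_grid()`) enumerates cells in grid order,
keeps the best mean CV score, breaks ties toward the first cell, and scores
failed cells as worst.

Implementation notes on the learner registry: KNN (classification and
regression) is implemented in-package as exact brute-force search with
uniform or inverse-distance weights, so the `algorithm`/`leaf_size` grid
axes — which only affect neighbour-search internals in approximate
implementations — are accepted and recorded but do not change results.
Decision trees use `rpart`, which has no random-splitter or
feature-subsampling option; `splitter` and `max_features` are likewise
accepted but inert for trees, and `min_samples_split`/`min_samples_leaf` map
to `minsplit`/`minbucket`. Random forests map `max_features` to `mtry`
(sqrt/log2/all) and `min_samples_leaf` to `nodesize`.

## Metrics

SN, SP, ACC, BACC = (SN+SP)/2, PREC, F1 = 2TP/(2TP+FP+FN) and MCC are
computed from confusion counts, with explicit zero-denominator conventions:
SN/SP/PREC/F1 are 0 when undefined, MCC is 0 when any marginal is zero. AUC
is the rank-based Mann–Whitney statistic (ties 1/2) — exact for finite
samples and equal to the area under the empirical ROC curve, verified
against a brute-force pairwise oracle. Regression reports R², MSE,
RMSE = √MSE and MAE.

## The synthetic-data generator

`generate_dataset()` emulates the structure of the real training data: per
strain, three structural proteins of 250–550 residues, coding sequences for
the eight expression genes, coordinates on a single replicon, 34 copy
counts, and a continuous activity. The latent score is

$$s = \beta_{cn}\, z(\text{nifH copies}) + \beta_{emb}\, z(\text{embedding
projection}) + \beta_{cb}\, z(\text{CAI of nifH}) + \varepsilon,\quad
\varepsilon \sim N(0, \sigma^2),$$

with activity $= 50 \cdot 10^{s}$ after the score is centred so the
configured class balance (default 0.5) holds at the 50-unit threshold.
Exponentiating makes the log-scale regression target near-linear in $s$, so
parameter-recovery assertions are clean. Coding sequences are produced by
back-translating the proteins with a per-sample codon-bias parameter (the
probability of choosing each family's preferred codon), which is what gives
the codon-usage features tunable signal; the embedding effect enters through
a per-sample residue-composition tilt picked up by a fixed projection of the
pseudo-embedding. Defaults ($n = 100$, $\sigma = 0.3$, unit effect weights,
balance 0.5) represent a moderately noisy cohort in which each planted
effect is individually recoverable.

What the generator does **not** emulate: phylogenetic structure, homology to
real nif sequences, correlated gene loss, replicon rearrangements, or
measurement error in the activity assay. Passing tests therefore demonstrate
that the pipeline recovers signal it is pointed at under controlled
conditions — not that any feature group is informative for real strains.

## Numerical and design choices

* Strict `>` at the label threshold; inclusive `≥` at the classification
  decision threshold. Both documented at their call sites.
* Stratified splits allocate `floor(fraction × class size)` per class to the
  first partition, remainder to the second — this exactly reproduces the
  published 167/154 + 42/39 partition of a 209/193 cohort at 80%.
* Ambiguous protein letters (B, Z, X, U, O, J) are rejected by default; a
  drop-residue mode with a warning exists for survey data.
* Terminal stop codons are stripped before codon counting; internal stops
  are errors. Standard genetic code only; GTG/TTG starts count as Val/Leu.
* All randomness flows through explicit integer seeds; fits of stochastic
  learners re-seed locally so results are bit-reproducible. In the
  config-driven pipeline every stage derives its seed deterministically from
  the single top-level seed.
* Model archives are a directory of JSON metadata plus serialised learner
  state, with a format version checked on load.
* Problem sizes used by the test-suite and acceptance script — cohorts of
  60–150 synthetic strains, 20-seed recovery loops, pseudo-embedding widths
  8–32 — were chosen as the smallest sizes at which the planted effects are
  comfortably recoverable, keeping the full suite under two minutes.

## Known limitations

* The E statistic and the bundled reference usage are artifact-specific
  definitions (documented above); CAI/Fop values are comparable within a run,
  not across tools.
* Gene distance treats circular replicons as linear and requires the three
  structural genes on one replicon.
* The KSG mutual-information estimator is $O(n^2)$ per evaluation — fine for
  the hold-out sizes used here, slow beyond a few thousand samples.
* No probability calibration and no multi-meta-learner stacking; single
  replicon assumption for gene distance; no operon prediction.
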