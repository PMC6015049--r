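---
title: "Predicting RNA-protein interactions from sequence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RNA-protein interactions from sequence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpiboost)
```

## The problem

Most RNA function is executed through physical association with proteins, but
experimentally mapping RNA-protein interactions (RPIs) is slow and biased
toward well-studied systems. `rpiboost` predicts, from sequence alone,
whether a given RNA chain and protein chain interact. The knowledge that
powers the predictor is extracted from RNA-protein complex crystal
structures: which amino acids prefer to sit at RNA-binding interfaces, and
how long a typical contiguous binding patch is.

## From structures to parameters

**Interfaces by distance.** Two chains in a complex are *interacting* when
any pair of their atoms lies strictly closer than 8 Å; an individual residue
belongs to the *binding interface* when one of its atoms is strictly within
5 Å of the partner chain. The tighter interface cutoff avoids counting
water-bridged contacts as direct ones. Both rules are implemented over all
atoms (hydrogens included when present); waters and free ions are removed at
parse time, and only the first alternate-location conformer is kept.

**Interface extent and the minimum structural unit.** Interacting residues
are merged into interface segments: two interacting positions join the same
segment when at most three non-interacting residues intervene, and segment
extent counts those admitted residues (interacting positions 5 and 9 alone
give one segment of extent 5). Across curated structures the typical extent
is five residues — one central residue plus two neighbors on each side, which
also matches the smallest autonomous structural units of proteins
(beta-turns) and RNA (hairpin loops). That five-residue *minimum structural
unit* (MSU) becomes the k-mer window of the encoder.

**Interaction propensities and the reduced alphabet.** For each amino acid
*j*, the propensity is

$$P_j = \frac{I_j / I_n}{N_j / N_n}$$

where $I_j$ counts interacting residues of type *j* at interfaces, $N_j$
counts non-interacting residues of type *j* lying inside interface segments,
and $I_n$, $N_n$ are the corresponding totals. $N_j$ is restricted to
residues *inside* segments because the gap rule explicitly admits them into
the interface; residues far from any contact say nothing about interface
preference. Propensities computed this way separate the 20 amino acids into
four groups, which the package hard-codes as its reduced alphabet:

| class | members | character |
|---|---|---|
| 0 | R, K, H | positively charged, highest propensity |
| 1 | D, P, M, F, A, V, L, I | aspartate + non-polar hydrophobics |
| 2 | C, E | lowest propensity |
| 3 | N, W, S, Q, Y, G, T | remaining polar/small residues |

`compute_propensities()` lets users recompute $P_j$ on their own structure
corpora; regrouping is deliberately a manual step (the grouping that ships
is a fixed, documented convention, and no clustering algorithm is implied).
Nucleotides show near-uniform propensities, so RNA keeps its four-letter
alphabet; chemically modified residues are mapped to their parents
(pseudouridine to U, queuosine to G, selenomethionine to M, ...) instead of
being discarded as `X`, so modified positions retain sequence information.

## Sequence encoding

Each molecule is scanned with a window of 5 and stride 1; each window maps
to a base-4 index (leftmost residue most significant) over its class
symbols, yielding a histogram of $4^5 = 1024$ window counts per molecule.
Windows containing residues with no known parent are skipped rather than
imputed. Each histogram is scaled as $v' = (v - \min v)/\max v$, clamping
into $[0,1]$ so that long chains do not dominate by raw frequency;
all-zero histograms pass through unchanged. The normalized protein block is
concatenated before the RNA block into the final 2048-entry pair vector.

Two normalization readings were possible from the verbal description
(per-molecule-vector scaling vs a corpus statistic per feature); the
per-molecule reading is adopted because it is the only one computable for a
single query pair in isolation, which is what a sequence-only predictor must
handle. Normalization happens per block, before concatenation, for the same
reason. The base-4 packing convention is arbitrary but fixed; any consistent
bijection yields an equivalent feature space.

## Training data construction

Positives are all interacting (8 Å) RNA-protein chain pairs from validated
complexes — X-ray structures at ≤ 3.0 Å resolution with protein chains of
≥ 25 and RNA chains of ≥ 15 residues (all bounds inclusive; structures with
no resolution record, e.g. NMR ensembles, are rejected) — with exact
duplicate sequence pairs collapsed. Negative candidates come from two
combinatorial sources: RNAs of single-RNA/single-protein ("monomeric")
complexes paired with proteins of every *other* monomeric complex, and
within multimeric complexes each RNA paired with the proteins it does not
touch. A candidate survives only if (1) it is not an exact positive pair,
(2) its protein is < 30% identical to every protein positively paired with
its RNA (and symmetrically for the RNA), and (3) surviving negatives sharing
a partner are mutually < 30% identical, scanned in deterministic order with
first-kept-wins. Identity is global-alignment percent identity (match +1,
mismatch 0, gap open −10, gap extend −1, matches divided by alignment
columns including gaps) — the conventional reading of "sequence similarity"
where none is specified. Finally `balance_subset()` draws exactly as many
negatives as positives by a seeded greedy pass that keeps the negative
set's unique-protein:unique-RNA ratio close to the positive set's.

One caveat worth stating: rule 3 makes the *filtered set* slightly
order-dependent by construction, so survival is not strictly monotone in the
similarity threshold — at a higher (more permissive) threshold, extra rule-1/2
survivors enter the greedy scan and can displace a candidate kept at a lower
one. The per-pair rules 1-2 are monotone and are tested as such.

## Classifier and evaluation

The classifier is an XGBoost gradient-boosted tree ensemble with the
published configuration: 200 trees, learning rate 0.25, maximum depth 8,
L1 = 1.12, L2 = 18.51, row subsample 0.9, binary-logistic loss, decision
threshold 0.5 with the ≥ convention. Evaluation is nested cross-validation:
a stratified 10-fold outer loop measures generalization while, inside each
outer training set, a stratified inner grid search over the L1/L2 penalties
picks the best mean inner accuracy before retraining on the full outer
training set. Stratification keeps class balance within ±1 example per fold;
all shuffling and subsampling flows from one recorded seed. Reported
metrics are accuracy, precision, recall, F-score (their standard
confusion-matrix forms) and rank-based AUROC, each as mean and standard
deviation over the outer folds.

The default inner search is 3-fold over a 2×2 grid
({0, 1.12} × {1, 18.51}); `wide_penalty_grid()` supplies a 4×4 grid for
larger studies. The compact default keeps a full nested evaluation of a
1000-pair corpus to roughly 130 model fits — a few minutes on one CPU —
while still containing the published penalty pair, so the published
configuration is always recoverable by the search. Exact tree-level
reproducibility across boosting-library versions is not promised; fold
assignments and all sampling are exactly reproducible.

## What the synthetic generators emulate

`generate_toy_complex()` builds two straight-line chains ~20 Å apart, one
backbone plus one side-chain pseudo-atom per residue, with chosen protein
positions displaced to 4-5 Å of the matching RNA residue and everything else
beyond 8 Å. This gives exact ground truth for the distance rules (planted
positions are provably the only interface residues) but no physical realism:
no packing, no chemistry, no crystallographic noise. `generate_motif_corpus()`
plants a class-level protein 5-mer and an RNA 5-mer in positive pairs
(defaults: 500 positives, 500 negatives, two copies of each motif, protein
lengths 30-80, RNA lengths 20-60, uniform background) and rejection-samples
negatives to be motif-free. Lengths respect the chain-validity minima so
nothing is silently filtered downstream.

Passing tests on these fixtures demonstrates that the machinery is correct —
distance rules match brute-force scans, the encoder matches a naive
histogram, the learner recovers a signal that an independent
nearest-centroid classifier confirms is present, and chance-level data stays
at chance. They do not demonstrate real-world accuracy: real interfaces are
not single motifs, real negatives are not motif-free background, and real
corpora carry homology structure that the similarity filters only
approximate. Benchmarking on curated structure-derived corpora is the
user's step, with `build_training_corpus()` as the entry point.

## Numerical conventions and degenerate inputs

- Both distance cutoffs are strict (`<`); the length and resolution bounds
  are inclusive. Ties in the inner grid search go to the first grid row.
- Sequences shorter than the window encode as all-zero vectors with a
  warning; windows containing unknown residues are skipped.
- Propensities with $I_j = 0$ are 0; $N_j = 0$ with $I_j > 0$ yields an
  +Inf sentinel with a warning; $I_n = 0$ or $N_n = 0$ is an error.
- Undefined precision/recall (empty denominator) is reported as 0 with a
  warning; AUROC uses midranks for tied scores.
- Residue order follows author-deposited numbering with insertion codes
  after their base number; chain kind is decided by residue chemistry
  (majority vote), never by chain labels.
- Pyroglutamate (PCA) is mapped to E; component-dictionary parentage is
  ambiguous here, and the mapping table accepts user overrides.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run entirely on generated
fixtures: 50 toy complexes for the contact-rule cross-check, 200 random
sequences for the encoder cross-check, a 12-complex corpus for the
negative-set audit, and a 500+500-pair motif corpus (with a label-permuted
copy) for the nested-CV signal-recovery check. These sizes give stable
pass/fail behavior at desk scale; all generators accept larger sizes.
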