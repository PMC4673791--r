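---
title: "Rule-based genome classification from k-mer composition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based genome classification from k-mer composition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`kmerules` classifies whole genomes to taxa using nothing but substring
composition. A genome `S` of length `n` over `{A, C, G, T, N}` is mapped to
the vector of relative frequencies of all `4^k` words of length `k`:
`f_i = c_i / w`, where `c_i` is the sliding-window count of word `i` and
`w` the number of *valid* windows — windows containing `N` are skipped, so
`w = n − k + 1` only for unambiguous sequences. Counting covers the forward
strand and, by default, the reverse complement as an independent second
scan (counts summed, never spanning a junction between the two). This
makes vectors strand-symmetric, `f(W) = f(revcomp(W))`, at the cost of a
factor-two redundancy in the feature space; we keep all `4^k` features
rather than collapsing to canonical words so that learned and published
rules can reference either orientation.

The classifier is an ordered decision list: rules of the form
`if f(W1) ∈ [a1, b1) and f(W2) ∈ [a2, b2) then taxon T`, evaluated top to
bottom, with a default class when nothing matches. Intervals are half-open
`[lo, hi)`; a value equal to the upper bound does *not* match. This is the
convention used by published rule tables of this kind, and it makes the
interval arithmetic of discretization and prediction consistent.

The taxonomy is handled one rank at a time: species, genus, order, class,
phylum each define an independent classification task over the same
feature matrix. Classes with fewer than `min_specimens = 9` genomes are
dropped before training — below that, fold-wise training sets become too
small to support grow/prune splits.

## Significance transforms

Raw frequencies can be replaced by a relative-deviation score
`z(W) = (p(W) − p̃(W)) / p̃(W)` against one of three null models:

* **Markov (order k−2):** `p̃(W) = p(W[1..k−1]) p(W[2..k]) / p(W[2..k−1])`.
* **Boundary independence:**
  `p̃(W) = (f(W[1]) f(W[2..k]) + f(W[1..k−1]) f(W[k])) / 2`.
* **i.i.d.:** the product of single-nucleotide frequencies.

Sub-word probabilities are computed on the same sequence with the same
strand mode, so the null model is internally consistent and the scores
inherit strand symmetry. On megabase genomes a zero expectation never
occurs, but short sequences can produce one; the `zero_expectation_policy`
either scores such words 0 (default) or drops the feature from the matrix.
Only the expectation-based score is implemented; variance-normalised
variants are deliberately out of scope. On the synthetic benchmark the
transform leaves cross-validated accuracy essentially unchanged (the
acceptance suite bounds the gap at five percentage points), consistent
with the view that rule learners dampen compositional noise on their own.

A DUST-style low-complexity mask is available as preprocessing: every
window of length 64 (shorter at the sequence tail, minimum 4) is scored by
triplet over-representation, `Σ c_t(c_t − 1)/2 / (m − 1)` over its
`m = L − 2` triplets, and windows scoring above 2.0 are set to `N`. Scores
are computed on the input and masks applied afterwards, which makes the
operation idempotent. The parameters are the conventional ones; exact
parity with any particular DUST binary is not promised, and masking is off
by default because the simulator produces no low-complexity sequence.

## Discretization

Rule thresholds come from supervised minimum-description-length
discretization (recursive entropy partitioning): candidate cuts are
midpoints between consecutive distinct sorted values at class boundaries,
and the entropy-minimising cut is accepted only when its information gain
exceeds `log2(N−1)/N + Δ/N`, with
`Δ = log2(3^c − 2) − [cE − c1E1 − c2E2]`. Features with no accepted cut
are retained as single-interval features (the learners simply cannot split
on them) so that feature indices stay stable. An equal-frequency binner is
provided for experiments on interval granularity.

Discretization is always fitted inside training folds, never on test data.
Whether the original pipeline discretized once globally or per fold is not
something we could determine; the leakage-free choice is the defensible
one and is asserted structurally by the cross-validation harness (cut
points are computed from the training partition object only).

## Rule learners

**Sequential covering (RIPPER-style).** Classes are processed in ascending
prevalence, each against all remaining samples; the most prevalent class
becomes the default. Per rule, a stratified 2/3 grow split adds literals
maximising FOIL information gain until no negatives are covered; the
held-out 1/3 prunes trailing literals to maximise `(p − n)/(p + n)`. Rule
addition stops when a rule errs on more than half its prune cover or when
the description length of the ruleset exceeds the best seen by 64 bits.
Two optimization passes then consider a freshly grown replacement and a
revision of each rule, keeping the variant with the smallest total
description length. The description-length bookkeeping follows the
standard sequential-covering formulation (theory bits per rule plus
exception bits); only relative comparisons matter, and parity with any
specific implementation is not promised.

**Partial trees (PART-style).** Repeatedly build a pruned C4.5-like tree
on the samples not yet covered — binary splits at candidate thresholds
chosen by gain ratio, pessimistic error pruning with the classical
confidence factor 0.25, minimum leaf size 2 — extract the leaf covering
the most samples as a rule, remove its cover, and repeat. When the tree
collapses to a single leaf the residual majority becomes the default.

Candidate thresholds for both learners are the MDL cut points when
discretization is enabled (the default), else midpoints between
consecutive sorted values. Determinism demanded explicit tie-breaking, and
two of the choices matter scientifically:

* Exact ties in FOIL gain (and in gain ratio) are broken by fewer covered
  negatives, then by preferring over-representation (`>=`) literals over
  under-representation (`<`) ones, then by the widest separation margin at
  the threshold, then lexicographically. Insertion-based signature
  planting necessarily enriches the words overlapping a planted copy's
  flanks (at roughly `copies/4` extra occurrences each), so several
  features can separate the same classes perfectly and tie exactly; the
  margin criterion resolves such ties toward the strongest marginal
  signal, and the direction preference describes a taxon by its own
  enriched words rather than by the absence of a sibling's. Both are
  deviations from a plain "lexicographic ties" convention, made so that
  the learned literal set is scientifically meaningful rather than an
  artefact of alphabet order.
* The same direction preference applies when choosing which pure leaf of a
  partial tree becomes a rule.

A literal may in principle hold a union of disjoint intervals on one word.
The learners never produce such literals, but published rule tables
occasionally contain a within-rule disjunction on a single word, and
representing it as one union literal keeps the printed rule count of such
tables intact when they are parsed.

## Cross-validation and reporting

Folds are stratified by class with sizes differing by at most one;
aggregate accuracy is pooled, `A = c/t` over the union of test folds,
which coincides with the fold-size-weighted mean of per-fold accuracies.
Ten folds are the default; when the smallest class has fewer members the
fold count shrinks to that size with a warning, and singleton classes are
excluded with a warning rather than an error (mirroring what happens on
real collections where many species have one or two genomes). Reports
print percentages rounded to two decimals; internal values keep full
precision.

## The synthetic benchmark

The simulator emulates the statistical structure the method assumes:
taxon-specific biases in word frequencies, nested across ranks, on an
i.i.d. background. Each taxon at each rank receives signature words
(2 by default) sampled so that no signature — nor its reverse complement —
is assigned twice anywhere in the taxonomy; under strand-symmetric
counting a word and its reverse complement are aliases, so this keeps the
ground truth unambiguous. Every genome of a taxon carries each signature
at a target frequency of `bias` times its background expectation (default
bias 5, capped at frequency 0.05). Copies are planted by overwriting
non-overlapping slots on a `k`-aligned grid at uniformly sampled
positions; the planted count is the target minus the expected background
count, so the measured frequency lands on the target up to sampling noise.
A guard rejects specifications whose summed per-genome target frequency
mass exceeds 30%, which would leave too little background for the
i.i.d. assumption to mean anything.

Defaults define the study conditions: 2 phyla × 1 class × 1 order ×
1 genus × 2 species (4 species), 10 genomes per species, 50 kb genomes,
`k = 4`. At those settings each lineage carries 10 signature words whose
combined target mass is 19.5% of windows. The benchmark is deliberately
easy — planted enrichment dwarfs binomial noise — because its role is
parameter recovery: cross-validated accuracy should be essentially perfect
at every rank, learned rules should be one or two literals long, and the
literals should point at planted signatures (or their reverse
complements). What passing these tests does *not* show: performance on
real genomes, where signal strength, phylogenetic correlation, GC skew,
repeats, and horizontal transfer are all outside the simulator's
vocabulary. The simulator also plants identical copy counts in every
genome of a taxon (only flank composition varies), so within-class
variance is lower than in any real collection.

Null calibrations use a flat taxonomy of 5 species × 10 genomes: with
permuted labels, and with bias 0, cross-validated accuracy must sit within
three binomial standard errors of the 20% chance level. In both cases the
MDL criterion typically finds no cut points, the learners return
default-only models, and accuracy lands at the majority rate — the
designed behaviour, since a rule learner that invents structure from noise
would be worse than useless here.

## Numerical choices and degenerate inputs

* Word order is lexicographic over `A < C < G < T` everywhere; matrices
  serialize deterministically.
* `k` is capped at 12 (the dense `4^k` vector is the representation).
  The CLI restricts `k` to 3–6 unless explicitly overridden.
* A sequence shorter than `k`, or fully masked, yields a zero vector plus
  a warning rather than an error.
* All stochastic steps (grow/prune splits, fold assignment, simulation)
  run under a caller-supplied seed via `withr::with_seed`; per-genome
  simulation seeds are derived arithmetically and kept within 32-bit
  range. Identical seeds give byte-identical FASTA, models, and CV
  serializations.
* Entropy computations define `0 log 0 = 0`; gain comparisons use a
  `1e-12` tolerance so that floating-point noise cannot flip a tie-break.

## Problem sizes

The test and acceptance runs use the default benchmark (40 genomes of
50 kb; ten-fold CV for both learners at five ranks), a 50-genome flat
taxonomy for the null calibrations, and 20 kb genomes for unit-level
checks — sizes chosen so the whole suite exercises every pipeline stage at
full fidelity while remaining comfortable to run on a laptop. Counting
scales linearly in total sequence length; learner cost is dominated by the
number of candidate thresholds, which MDL discretization keeps to a few
per informative feature.

## Known limitations

* No hierarchical (parent/child) rule structure: each rank is learned
  independently, so the per-rank models need not be mutually consistent.
* No fragment-level classification; the contract is whole genomes.
* The RIPPER-style optimizer is a faithful but compact rendition;
  description-length constants differ from other implementations, so rule
  sets — though similar in spirit and size — are not expected to match
  another tool's output rule for rule.
* Baseline classifiers (support-vector machines, nearest neighbour) are
  not part of the package; the evaluation layer exposes enough structure
  to wire them in externally if a comparison is wanted.
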