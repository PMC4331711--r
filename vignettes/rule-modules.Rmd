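---
title: "Interval-rule discovery and miRNA-mRNA module inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-rule discovery and miRNA-mRNA module inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirulenet)
```

`mirulenet` infers miRNA-mRNA regulatory modules from a paired
two-class expression study by connecting *100%-frequency interval
rules* mined on each side of the pairing. This vignette explains the
statistical machinery, the defaults and why they are set where they
are, what the synthetic generator does and does not emulate, and the
design decisions taken where more than one reading was defensible.

## The rule model

For features $x_i$ (miRNA or mRNA expression values) a rule for class
$c$ is a conjunction of closed intervals

$$\bigcap_{i=1}^{k} a_i \le x_i \le b_i \;\rightarrow\; c\,(100\%),$$

required to cover every training sample of class $c$ and none of the
other class. The model is deliberately stringent: with a 100%-frequency
requirement a rule is a certificate about the training data, not an
estimate, so its discovery is a combinatorial search rather than a fit.
Two consequences shape the package. First, unlabeled or missing values
cannot be tolerated anywhere (coverage of "every sample" would be
undefined), so the I/O layer rejects them at parse time. Second, the
interval bounds carry no uncertainty; reliability is assessed
afterwards by separation (Max-Min distance) and by cross-validated AUC
rather than by the rule itself.

miRNA-side rules are restricted to $k = 2$: pairs are the smallest
conjunctions that capture co-expression changes, remain readable as
diagnostic statements, and keep the committee search exhaustive in
spirit. mRNA-side rules have no $k$ cap — the greedy miner adds
conditions until purity or a plateau.

## Gain-ratio ranking

Continuous features are scored by their best binary split: candidate
thresholds are midpoints between consecutive distinct sorted values;
information gain is measured in bits and divided by the entropy of the
split sizes (the gain ratio, which penalizes lopsided splits that would
otherwise look informative). There is no minimum-description-length
correction — none is needed for ranking, and adding one would change
only the absolute scores, not the order. The default cutoff retains
features with gain ratio strictly above 0.5, i.e. features whose best
split removes more than half of the class uncertainty per bit of split
entropy; a perfectly separating feature scores exactly 1 at any class
balance, because a perfect split partitions along the classes and the
split information then equals the class entropy.

Ranking ties are broken lexicographically on the feature id so results
are reproducible across platforms. The accompanying p-value column uses
the classical pooled-variance two-sided Student t-test; the pooled form
was chosen over Welch's because the two are indistinguishable under the
generator's equal-variance classes and the pooled form is the stricter
reading of "Student's t-test" (`welch = TRUE` switches). The ranking is
driven by gain ratio alone — a feature can rank highly with a
non-significant t-test when its distribution separates non-linearly.

## Committee trees and rule extraction

Rules are extracted from a committee of depth-capped (default 2)
gain-ratio decision trees: the first tree is grown on the full matrix,
the root feature is then removed and the next tree grown, until fewer
than two features remain. Root removal forces diversity: every tree is
anchored on a different feature, so the committee enumerates rule seeds
in ranked order instead of rediscovering the same dominant split.

Every pure root-to-leaf path (all samples of one class inside the
path's region, none of the other) yields a rule, with one deliberate
transformation: the one-sided tree thresholds are **tightened to the
observed class minima and maxima** on the path features. Tightening is
what turns a half-space decision path into the two-sided closed
intervals of the rule model; because all target-class samples lie in
the path region, their per-feature extremes lie inside it too, so the
tightened box is a subset of the region and purity is preserved (the
implementation still verifies every emitted rule exactly and would
abort on a violation). Printed rule bounds are therefore data extremes,
not tree thresholds.

One committee-specific wrinkle: when the class gap is large a single
feature may separate the classes on its own, giving a depth-1 pure path
with only one feature — below the 2-feature rule form. Such paths are
completed by pairing the path feature with the highest-gain-ratio other
feature available to that tree; intersecting the second feature's class
range can only shrink a pure box, so the completed rule is still
100%-frequency. This keeps the rule inventory in the $k=2$ form across
both regimes (jointly-separating pairs and individually-separating
features) without special-casing downstream code.

No pruning and no missing-value machinery are implemented: pruning
exists to fight overfitting in *predictive* trees, while here impure
paths are simply not extracted, and missing values are rejected at I/O.

## Greedy compactness mining on the mRNA side

With tens of thousands of mRNAs, tree committees are poorly suited (the
root-removal loop would be enormous and almost all features
uninformative), so mRNA rules use a direct greedy search. For class $c$
each candidate feature contributes its class expression range
$[\min, \max]$ over the currently active samples; the range's
*compactness* is $p = N_c/N$, the fraction of active samples inside the
range that belong to $c$. The highest-compactness range is accepted
(ties lexicographic), the active set is restricted to it, and the loop
continues until $p = 1$ (a rule) or no candidate strictly increases $p$
(no rule). Three readings were fixed here:

* **Plateaus terminate.** "Cannot be improved" is read as no *strict*
  increase; accepting equal-$p$ conditions could cycle.
* **Ranges are recomputed on active samples.** This is the only reading
  under which accepted conditions interact; it is also a no-op for the
  class-$c$ extremes themselves, since class-$c$ samples are never
  removed (every accepted range spans them), which is precisely why any
  returned rule automatically covers the whole class — its frequency is
  measured against the full class size and equals 1 by construction.
* **A class that fails one round is retried the next.** Harmless, and
  mining only terminates when a full round yields nothing for any
  class.

Rounds exclude every feature used by a previously accepted rule (of
either class), so rule feature sets across rounds are pairwise
disjoint and the round index is a meaningful "strength" tag: earlier
rounds had the pick of the most compact features.

A useful property, exercised heavily in the test suite: whenever *any*
pure box over at most two features exists, the greedy search is
guaranteed to find some rule — at every state each uncovered
other-class sample lies outside at least one of the pure pair's class
ranges, so one of those two candidates always strictly increases $p$.
Greedy composition may differ from the exhaustive search's, but
existence agrees.

## Rule metrics

**Max-Min distance** is the minimum Euclidean distance between
cross-class sample pairs in the rule's own feature subspace, on raw
expression values — the same scale as the printed rule bounds, so a
distance of 5 means the closest opposing samples are 5 expression units
apart along these two miRNAs. It is symmetric in the classes and
invariant to orthogonal transforms of the subspace.

**Cross-validated AUC** re-learns a depth-capped gain-ratio tree on the
rule's features within each of 10 seeded stratified folds and scores
held-out samples by the target-class probability of their leaf. The
choice of *per-rule* features (rather than one tree per committee) ties
the score to the rule being reported; fold assignment is deterministic
given the seed. Folds whose held-out part contains one class have no
defined AUC and are excluded with a warning; if no fold is usable the
pooled held-out AUC is returned instead.

**Pearson correlation** on paired samples signs the module edges.
Correlations are computed only over samples present in both matrices
(paired designs are often incomplete). The default labelling threshold
|r| ≥ 0.1 is deliberately permissive: biologically confirmed positive
regulation can sit near r ≈ 0.2 in noisy clinical material, and the
threshold only affects the `regulation` label, never the stored r.
A constant profile yields `NA`, never a silent 0.

## Modules and the network

Each miRNA rule is joined to its mined mRNA rules through a
predicted-target map (an input file; the package performs no database
retrieval). Only the top mRNA rules enter a module — default two per
class, so up to four — ordered by round, then by parsimony (fewer
conditions), then lexicographically. The ordering criterion is a
package decision: "top" is otherwise undefined, and round order is the
natural proxy for compactness strength given that earlier rounds
consume the best features. Edges require predicted targeting; an mRNA
in a rule but targeted by no module miRNA stays in the rule listing
without an edge, which preserves bipartiteness. Merged networks
deduplicate edges while keeping all source-module ids, and the
many-to-many core (default: mRNAs with ≥ 3 distinct regulators) is
available for the cooperative-regulation analyses where inverse and
positive edges coexist.

## Seed scan and Markov background

The seed is taken as positions 2–8 of the mature miRNA (7 nt); the seed
string itself is user input since mature sequences are not bundled. A
site is a sense-strand window equal to the reverse complement of the
seed at ≤ 1 mismatch (Watson–Crick only by default; G–U wobble pairs
are *not* matches unless `allow_wobble = TRUE`, since complementarity,
not thermodynamic stability, is the criterion being modelled).
Coordinates are 1-based inclusive and always satisfy
`site == substr(sequence, start, end)`.

Significance uses a first-order Markov chain estimated from the scanned
sequence itself: transition probabilities are row-normalized
adjacent-pair counts, and the initial distribution is the sequence's
global base composition, with the base order fixed to A, G, U, C in all
outputs. For a k-mer $c_1 \dots c_k$,

$$P = \frac{n(c_1)}{L} \prod_{i=1}^{k-1} P(c_{i+1} \mid c_i),$$

which sums to 1 over all $4^k$ k-mers — a normalization the tests check
directly for $k = 1..7$. Two labelled quantities are reported per site
and deliberately kept apart: `p_exact`, the probability of the
*observed* genomic window (the defensible choice when a mismatch makes
"the complementary k-mer" ambiguous), and
`p_window` $= 1-(1-p_\text{exact})^{L-k+1}$, the chance that at least
one window of the sequence spells that site. Neither aggregates over
the whole one-mismatch family of k-mers; a family-wise $P$ is a
different quantity and is not claimed.

The package bundles the published dinucleotide count table of the GFRA2
5' UTR (675 nt; 151 A, 182 G, 161 U, 181 C) as a plain-text reference
case for this machinery; `gfra2_transition_matrix()` rebuilds the model
from those counts alone. One caveat a careful reader will notice: the
published counts sum to 675 rather than the 674 adjacent pairs a 675-nt
sequence possesses, and one published 3-decimal cell (G→C, 42/182)
rounds to 0.231 rather than the printed 0.230. `build_transition_matrix`
counts $L-1$ pairs (the terminal base starts no pair), and comparisons
against the printed probabilities are made at one unit in the last
printed digit.

## The synthetic generator

`simulate_dataset()` emulates the structure the method is designed to
recover: two classes (default 24 vs 12 samples, a realistic paired
clinical design), signal miRNAs whose class-conditional Gaussian means
differ by `class_gap` (default 10) with within-class spread `noise_sd`
(default 0.1 — a gap-to-noise ratio of 100, i.e. essentially separable,
the regime in which 100%-frequency rules are meaningful), background
miRNAs with no class signal, target mRNAs linearly coupled to their
regulator (`sign * 0.9 * x` plus noise, signs alternating so both
inverse and positive regulation are planted), decoy target predictions,
background mRNAs, and UTR sequences carrying the reverse complement of
each miRNA's seed at recorded coordinates with one planted mismatch
(positive couplings get 5' UTR sites, negative ones 3' UTR sites,
mirroring the biology that motivates sign-aware module inference).

What it does **not** emulate: microarray technical artifacts, dye bias,
replicate structure, probe-level noise, non-linear regulation,
competition between miRNAs, or realistic UTR base composition. Passing
the planted-recovery tests therefore demonstrates correctness of the
algorithms under their own assumptions — separable classes and linear
coupling — not performance on clinical microarray data.

## Numerical choices and degenerate inputs

* Entropies use log base 2; any fixed base gives identical rankings.
* Gain-ratio and compactness ties break lexicographically on feature
  id; threshold ties break toward the smaller threshold.
* A constant feature has gain ratio 0 with its single value as the
  reported threshold; a zero-variance t-test returns p = 1 (equal
  means) or p = 0 (unequal).
* Interval membership is inclusive on both ends everywhere (a sample
  exactly on a printed bound is covered).
* Strict-improvement comparisons use a 1e-12 tolerance to keep
  floating-point plateaus from looping.
* One global pipeline seed fans out to per-stage seeds by fixed
  offsets, so inserting a stage never perturbs another stage's
  randomness; reruns with the same config and seed are bit-identical.

## Problem sizes used by the test suite

The suite validates the miners against an exhaustive box-enumeration
oracle on 200 random matrices of up to 12 features × 40 samples,
end-to-end planted recovery over 20 generator replicates at the default
study shape, a 100-replicate signal-free null (spurious 100%-frequency
rules arise in far fewer than 5% of replicates), and Markov
normalization over 20 random chains for k up to 7. These sizes were
chosen to make every combinatorial claim checkable by enumeration while
keeping the whole suite comfortably fast on a laptop.

## Known limitations

* The 100%-frequency requirement is brittle by design: one mislabeled
  sample destroys a true rule. The machinery is appropriate for clean,
  strongly separated designs; the frequency threshold would need
  relaxation (not provided) for noisier cohorts.
* The committee explores one tree per removed root; it is not an
  exhaustive pair search, and on adversarial layouts it can miss pure
  pairs the brute-force oracle finds (the tests assert soundness —
  emitted rules are always pure — and existence agreement only for the
  greedy miner, where it is provable).
* Technical-replicate collapsing is left upstream: the matrices accept
  one column per sample.
* The seed scan models complementarity only — no thermodynamics,
  conservation, or context scores.
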