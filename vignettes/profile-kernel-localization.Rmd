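---
title: "Predicting protein subcellular localization with profile-kernel SVM trees and homology transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein subcellular localization with profile-kernel SVM trees and homology transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profloc)
```

## The problem

Most proteins function in one specific subcellular compartment, and
knowing that compartment is often the first usable statement one can
make about an uncharacterized sequence. `profloc` predicts a single
localization class per protein — 18 classes for eukaryotes (10
non-membrane and 8 membrane compartments), 6 for bacteria (cytosol,
plasma membrane, periplasmic space, outer membrane, fimbrium,
extra-cellular) and 3 for archaea — and attaches to every call a
reliability index (RI) on a 0–100 scale, so that users can trade
coverage for accuracy.

Two complementary routes are combined:

1. **Homology transfer.** If a database search has produced a
   significant hit (E-value ≤ 10⁻³, self-hits excluded) to a protein
   with an experimentally annotated localization, the annotation of the
   best hit — best by percentage pairwise sequence identity (PIDE), not
   by E-value — is copied to the query. The RI is a function of PIDE.
2. **De novo prediction.** Otherwise a hierarchical system of binary
   SVMs over a profile k-mer string kernel walks the query from the
   root of a compartment tree to a leaf class, multiplying per-decision
   confidences into the RI.

The combination rule is a single parameter-free switch: *homology when
available, machine learning otherwise*. Annotation transfer is very
accurate when a close homolog exists but degrades to random at low
similarity, while the SVM tree keeps working there; the switch keeps
each route in the regime where it is strong.

## The profile k-mer kernel

Each protein is represented by a per-position residue profile: an
L × 20 matrix of scores on a negative-log-probability scale,
`score = -ln(p)` with `p` clamped to `[0.001, 1]`, so every score lies
in `[0, 6.908]`. Profiles come from one of two sources:

* `read_pssm()` parses the NCBI ASCII PSSM dialect and converts the 20
  *percentage* columns (the weighted observed residue frequencies) to
  this scale. The log-odds columns are ignored: the kernel needs
  per-position probabilities, and the percentage block is the closest
  printed representation of them. This is a design choice — either
  block could in principle feed a kernel — and it is isolated in one
  reader function.
* `fabricate_profile()` builds a deterministic surrogate from the bare
  sequence: the observed residue gets mass `p_self = 0.9`, the other
  19 letters share the remainder, and `X` positions get a uniform
  column. This keeps the de novo route usable when no alignment
  tooling has been run; it is a soft one-hot encoding, not a claim
  about evolutionary profiles.

A k-mer β **hits** position `i` of a profile when its summed score
`sum_j S[i + j, β_j]` is *strictly below* a threshold θ. The feature
vector of a protein counts every hitting k-mer over all positions; the
kernel between two proteins is the cosine of their sparse count
vectors, so `K(u, u) = 1` exactly and all values lie in `[0, 1]`.

`feature_map()` implements this as a depth-first trie traversal: a
prefix whose partial score already reaches θ is pruned together with
all its extensions (scores are non-negative), and children are visited
in ascending score order, which makes one threshold crossing prune all
remaining siblings at that depth. `brute_force_feature_map()` is the
independent enumeration oracle — identical by construction on any
input with `|alphabet|^k ≤ 10⁶` — and the test suite asserts exact
count-level equality on hundreds of random profiles.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 6 eukaryota / 5 bacteria / 3 archaea | k-mer window length |
| `theta` | 6.0 | strict score threshold for a k-mer hit |
| `p_self` | 0.9 | self-residue mass of fabricated profiles |
| `C` | 1.0 | SVM soft-margin cost |
| `evalue_max` | 1e-3 | homology-transfer gate |
| `pide_floor` | 20 | PIDE at and below which the transfer RI is 0 |

The θ default deserves a note. On a *uniform* profile every k-mer has
the identical score `k·ln 20`, so the hit count per position jumps
from 0 to 20^k as θ crosses that value — there is no θ that produces a
moderate hit count on a flat background. The default is therefore
calibrated on the fabricated-profile scale instead: with
`p_self = 0.9` the self letter scores `-ln 0.9 ≈ 0.105` and every
other letter `-ln(0.1/19) ≈ 5.25`, so θ = 6.0 admits at each position
exactly the window's own k-mer and its single-substitution neighbours
(1 + 19k k-mers at k ≤ 11). Feature vectors stay sparse (tens of
thousands of potential k-mers, ~100(1 + 19k) realized counts for a
100-residue protein) yet overlap strongly for sequences sharing
motifs. The hit rule uses strict inequality so θ → 0 gives an empty
map rather than an alphabet-complete one.

## The hierarchical SVM tree

The tree topology is *data*: an editable JSON config whose internal
nodes are binary splits and whose leaves are exactly the domain's
class set (validated on load). The shipped defaults follow the cell's
sorting anatomy — the secretory pathway splits off first, then
membrane/soluble splits — and are a reasonable default, not a
reconstruction of any externally trained tree.

Training (`train_tree()`) gives each internal node the training
proteins whose class lies under it, labeled by child subtree
(left = −1, right = +1), and solves an independent soft-margin SVM on
the shared precomputed kernel (kernlab's SMO). Each node then gets a
sigmoid (Platt) calibration fitted on its training decision values
with Laplace-smoothed targets — no inner cross-validation, which is a
deliberate small-data choice: the synthetic training sets are small
and an inner split would starve the calibration.

Prediction (`predict_de_novo()`) computes one kernel row of the query
against the training examples and descends: the decision-value sign
picks the child (an exact 0 descends to the positive side — a
documented deterministic tie-break), and the step confidence is
`max(p, 1 − p)` of the calibrated sigmoid, hence ≥ 0.5. The RI is
`round(100 × Π confidences)`, so a depth-d path has an RI floor of
`100 × 0.5^d`. Lowering any single step confidence can only lower the
RI.

Numerical details worth stating: the kernel matrix is built by one
sparse cross-product (Matrix package) and normalized as
`G_ij / sqrt(G_ii G_jj)` on the exact integer dot products, which
makes the diagonal exactly 1; training is deterministic (same data,
same parameters → byte-identical serialized model); and if a node's
decision values carry no signal the Platt fit falls back to a nearly
flat sigmoid (`a = −10⁻⁶`) so confidences stay near 0.5 instead of
becoming anti-calibrated.

## Homology transfer and the reliability index

`filter_hits()` keeps hits with `evalue ≤ 1e-3` whose subject is
annotated, drops self-hits, and preserves order; `best_hit()`
maximizes PIDE with ties broken by lower E-value, then input order.
Exactly one hit transfers — no voting among equally good hits.

The transfer RI is a clamped linear map anchored at the two points the
method fixes — saturation at `PIDE ≤ 20` (RI = 0) and full identity
(RI = 100):

```
RI(PIDE) = round(100 · (clamp(PIDE, 20, 100) − 20) / 80)
```

The true deployed curve of the original server is not published beyond
those two constraints; the linear form is the simplest function
satisfying them and is isolated in `ri_from_pide()` for replacement.

`expected_accuracy()` is deliberately *optional* output: it is a step
lookup into an `ri_calibration` that can only be produced by running
`calibrate_ri()` on labeled predictions. A fresh installation has no
benchmark of its own, so predictions carry an empty expected-accuracy
column until the user calibrates — the honest dependency order.

## Evaluation machinery

Per-class accuracy `100·TP/(TP+FP)` and coverage `100·TP/(TP+FN)`
return `NA` (rendered `n/a`) on empty denominators, never 0 or 100.
The overall n-state accuracy Qn is the fraction of proteins whose
(optionally merged) predicted class equals the observed one. Merge
maps — e.g. nucleus membrane → nucleus, chloroplast → plastid for
cross-granularity comparisons — ship as total, validated configs.

Standard errors use a subsampling bootstrap: `n_sets = 1000` draws of
`ceil(0.15·N)` proteins *without replacement*, with the deviation
measured around the **full-set** metric rather than the bootstrap
mean:

```
sigma = sqrt( sum_i (x_i − x_full)² / n ),   SE = sigma / sqrt(n − 1)
```

A subsample on which the metric is undefined is skipped and counted,
never imputed. The draw sequence is a documented contract —
`set.seed(seed)` once, then `n_sets` successive `sample.int(N, m)`
calls — so an independent re-implementation reproduces the result to
machine precision, which the test suite does.

`ri_curve()` sweeps an RI threshold over 0..100 and reports coverage
(fraction of predictions at or above the threshold) and the accuracy
of that subset; coverage is 100% at threshold 0 and non-increasing.

## What the synthetic generator emulates — and what it does not

`make_dataset()` builds, from a seed: an annotated reference set
(default 50 proteins per class), class-specific planted motifs
(default 2 per class, length 6, pairwise Hamming distance ≥ 2),
queries that are either mutated copies of reference proteins at a
controlled identity (default 60%, the `WITH_HIT` split, with a
fabricated hit record) or fresh draws from the class (`WITHOUT_HIT`,
with a decoy hit at background identity), and fabricated profiles for
everything. Defaults were chosen once as a realistic miniature of a
with-hit/without-hit benchmark design: 50 training and 20 test
proteins per class keep every SVM node in the hundreds-of-examples
regime while the whole suite runs in minutes on one CPU.

Two honest constructions matter for interpretation:

* The hit E-value is an explicit monotone proxy,
  `evalue = 10^(−0.2·PIDE)`, not a claim about search statistics. At
  the default target identity of 60% it is 10⁻¹², far inside the
  gate; at background identity (~5%) it is ~0.1, outside it. Decoy
  subjects are redrawn in the rare case background identity would
  pass the gate, so the WITH/WITHOUT split is exactly recoverable
  from the hits plus the default policy — by construction, which is
  what makes the routing test exact.
* Homolog mutation does **not** protect planted motifs: substitutions
  land uniformly, so a 60%-identity homolog keeps any given length-6
  motif intact only with probability 0.6⁶ ≈ 5%. High-divergence
  homologs therefore genuinely degrade the de novo signal, which is
  what makes the "transfer beats de novo on homologs, de novo beats
  indiscriminate transfer on the rest, the combination beats both"
  structure emerge from the data rather than from wiring.

What passing these tests does *not* show: real proteins are not
uniform-background sequences with two planted hexamers, real PSSMs
carry position-specific conservation the fabricated profiles lack,
real alignments have indels, and real class frequencies are far from
balanced. The synthetic results validate the machinery and its
contracts, not biological performance; absolute synthetic accuracies
(typically near 100% on fresh queries) should not be read as expected
accuracy on real data.

## Degenerate inputs and edge policies

* Non-standard residues (B, Z, U, O, J) map to `X`; `X` contributes a
  uniform profile column. No position is dropped.
* A profile shorter than k is a signaled error on the de novo route,
  never a silent empty vector; in batch mode such failures are logged
  per query and reported, not fatal.
* The kernel is undefined (error) for an empty feature vector;
  `theta` small enough to empty the map surfaces immediately.
* A duplicate protein id within one FASTA file, conflicting
  annotations for one protein, and a hit table with the wrong column
  count are all hard errors.
* k > 6 is rejected by default (the enumeration oracle and the k-mer
  space grow as 20^k); an override flag exists.

## Known limitations

* Tree topologies are shipped defaults with the correct leaf sets, not
  learned structures; node order can matter for hard queries.
* The Platt calibration is fitted on training decision values; on
  very small nodes confidences are optimistic, which propagates into
  optimistic de novo RIs. The RI–accuracy relation should always be
  read off `calibrate_ri()` output rather than assumed.
* The transfer route trusts the hit table's PIDE as given (no
  re-alignment) and transfers from exactly one hit.
* The package parses profiles; it does not run the profile search
  itself, and no attempt is made to reproduce the runtime
  characteristics of any deployed service.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely on synthetic
data: kernel-oracle equivalence on 200 random profiles of length
≤ 30 for k ∈ {1, 2, 3}; class recovery on 6 bacterial classes with
50 training + 20 held-out queries per class at k = 5 (three seeds);
the combination analysis on the same scale with half the queries
mutated homologs at 60% identity; and a 1000-set bootstrap on the
combined predictions. These sizes were chosen as the package's
standard desk-scale benchmark; all are configurable upward through
`scenario_config()`.
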