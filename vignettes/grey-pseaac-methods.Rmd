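---
title: "Methods: the grey-model PseAAC and its classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the grey-model PseAAC and its classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greyDBP)
```

## The model

greyDBP treats DNA-binding prediction as binary classification of a
fixed-length summary of the sequence. The summary has two blocks.

**Composition block (components 1–20).** The occurrence frequencies of the
20 standard amino acids, alphabetical by one-letter code. Non-standard
characters (X, B, Z, U, O, J, gaps) are excluded from both the counts and
the denominator, so the block is always a probability distribution over the
20 standard types. This block carries the charge/composition signal — real
DNA binders are enriched in lysine and arginine — but is blind to residue
order.

**Grey-model block (components 21–23).** The sequence is first rendered as
a numeric series: residue `r` becomes `f(s_r) = 1 / (1 + exp(-s_r))`, where
`s_r` is its molecular-volume factor score (Atchley's multivariate factor
analysis of physicochemical properties). The logistic map is used because
the grey model requires a strictly positive series and the map sends any
finite score into (0, 1) while preserving order. A GM(2,1) grey dynamic
model — a second-order, one-variable model from grey-system theory, suited
to oscillating series — is then fitted, and the absolute values of its
three coefficients `(|a1|, |a2|, |b|)` become the last three components.
Unlike the composition block they respond to permutations of the sequence,
so the vector as a whole encodes some order information at a cost of only
three dimensions.

### GM(2,1) discretization and fitting

For the encoded series `x0(1..n)`, the 1-AGO series is the running sum
`x1 = cumsum(x0)`, and the background value is the adjacent mean
`z1(k) = (x1(k) + x1(k-1)) / 2`. We adopt the canonical discrete form

```
x0(k) - x0(k-1) = -a1 * x0(k) - a2 * z1(k) + b ,  k = 2..n
```

i.e. design-matrix rows `[-x0(k), -z1(k), 1]` against the first differences
of `x0`. Among several sign/ordering conventions in the grey-systems
literature this is the most common; any consistent alternative produces the
same unordered feature set, but the convention is fixed and documented so
that models and feature files are interchangeable.

The 3-unknown least-squares problem is solved by singular value
decomposition rather than the normal-equations formula
`(B'B)^-1 B' Y`: homopolymer-like inputs are legal and make `B` (nearly)
rank-deficient, and the normal equations square the condition number. On
rank deficiency the minimum-norm solution is returned and a `degenerate`
flag is set. Two consequences worth knowing:

* a constant series (e.g. a homopolymer) has zero response and yields
  exactly `(0, 0, 0)`;
* a geometric series like `(1, 2, 4, 8)` gives a singular but consistent
  3×3 system; the fit has zero residual and returns the minimum-norm
  representative of the solution line.

The fit requires at least 4 encodable residues (3 equations for 3
unknowns). In practice the dataset screening step already removes
fragments shorter than 50 residues, so this bound only matters for
hand-constructed inputs; shorter records are dropped with a logged reason
rather than an abort when whole files are processed.

### The residue code table

The default table ships as a plain TSV (`residue`, `factor_score`) and can
be replaced by any single-factor physicochemical encoding with the same
shape. Codes are always recomputed from the factor scores at full floating
precision; the 3-decimal reference values serve as test oracles only, so
rounding error never propagates into the grey fit. Two of the twenty
published 3-decimal codes (isoleucine and asparagine) are inconsistent with
the published factor scores under the logistic map — the isoleucine value
is a digit transposition — and the computed values (0.894, 0.786) are used;
the test suite pins both facts.

Sign conventions: nine factor scores are negative (A, C, D, H, L, P, Q, S,
V); these are exactly the residues whose codes fall below 0.5, as the
logistic map forces, which is how the signs were reconstructed and
validated against the printed codes.

## The classifier

A random forest is built in-package (C++): each of `n_trees` trees is grown
on a bootstrap sample of size n, splitting on the best of `mtry` randomly
chosen features by Gini impurity, to purity (minimum node size 1, no
pruning). Defaults are `n_trees = 560`, `mtry = 5`. Prediction is the
unweighted majority vote; an exactly tied vote goes to the first class
level, `binding` — ties are rare at 560 trees but the rule is fixed so runs
are reproducible. No probability cutoff is applied. All forest randomness
comes from a dedicated Mersenne Twister seeded per tree from
`(config seed, tree index)`, independent of R's global RNG, so a fixed seed
gives bit-identical forests.

Feature scaling is deliberately absent: trees are invariant to monotone
per-feature transforms, so the mixed scales of the composition block
([0, 1] frequencies) and grey block (unbounded magnitudes) are harmless.

### Evaluation protocols

`jackknife()` singles out each of the N records in turn and predicts it
with a forest trained on the remaining N − 1 (N training rounds — the most
objective of the standard validation protocols because its outcome is
unique for a given dataset). Each fold's forest seed is derived
deterministically from the master seed (`(seed * 7919 + fold * 104729) mod
(2^31 - 1)`), giving reproducibility without correlating folds.
`evaluate_independent()` scores a fitted model on a held-out labeled set in
one pass. Both produce an `evaluation_report` whose invariants (overall
counts are the sum of per-class counts; every rate is
`100 * correct / n`) are enforced by construction and re-checked in the
test suite.

## Dataset handling

The screening filters mirror standard benchmark construction: drop
sequences shorter than 50 residues (likely fragments; a 50-residue sequence
is kept), and drop sequences with a run of more than 10 consecutive `X`
(a 10-run is kept). Redundancy reduction against a culling service is out
of scope; a documented greedy stand-in is provided: records are visited in
input order and kept only if their global-alignment identity
(matches / alignment length, BLOSUM62, gap opening 10, gap extension 0.5)
to every previously kept record is ≤ 0.25. This is deterministic and
reproducible but order-dependent and not identical to production culling
pipelines; id lists from a real culling run can be applied by ordinary
subsetting instead.

Labels travel either as a trailing `|1` / `|0` header token or as a
two-column sidecar TSV; both dialects are read, and the FASTA writer emits
the header dialect so round trips preserve labels.

## The synthetic world

`generate_synthetic()` draws sequences i.i.d. per position from per-class
residue profiles: the positive class puts 0.15 on each of K and R
(remaining mass uniform), the negative class is uniform at 0.05; lengths
are uniform on [50, 300] (lower bound = the fragment filter; upper bound a
typical single-domain length). These defaults emulate the compositional
charge bias that separates real DNA binders from non-binders at roughly
realistic sequence lengths.

What the generator does **not** emulate: positional motifs, domain
architecture, evolutionary correlation between residues, homology between
records, or class-imbalanced sampling. Consequently a green synthetic test
establishes that the pipeline is wired correctly and that the classifier
recovers a planted compositional signal under the exact published protocol
(leave-one-out, 560 trees, mtry 5); it does not certify accuracy on real
benchmark data, which carry order-level signal the generator cannot plant.
Published-scale benchmark rates can only be reproduced by supplying the
corresponding curated FASTA+label files through the same interfaces.

## Numerical choices and degenerate inputs

* SVD rank tolerance: `max(dim(B)) * eps * d1` (the LINPACK-style default).
* Minimum-norm convention on rank deficiency, with a `degeneracy` flag
  rather than an error.
* Feature TSVs are written with 17 significant digits so read/write round
  trips are bit-exact.
* Empty sequences, label-free records in labeled protocols, single-class
  training sets, and dimension mismatches abort with descriptive errors;
  unknown residues are skipped with a warning by default (`"error"` policy
  available) because no published convention exists for encoding residual
  non-standard characters — sequences with short X runs survive the
  screening filter, and skipping them keeps the composition block a true
  distribution and the encoded series standard-residues-only.

## Known limitations

* The grey block contributes only three order-sensitive components; two
  sequences with equal composition and similar volume dynamics are
  indistinguishable.
* The greedy identity filter is quadratic in the number of records and
  alignment-based; for thousands of records use a dedicated culling tool
  and import its id list.
* The jackknife trains N forests; at the default 560 trees this is minutes
  for N in the hundreds on one CPU.
* Tree growth to purity interpolates the training set; training-set
  accuracy is therefore not an estimate of generalisation (use the
  jackknife or an independent set).
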