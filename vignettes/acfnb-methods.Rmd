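---
title: "Classifying compound activity with atom-center fragments and Laplacian-corrected naive Bayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying compound activity with atom-center fragments and Laplacian-corrected naive Bayes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acfnb)
```

## The problem

Ligand-based binary classification asks: given a library of compounds with
measured potencies (Ki or IC50) against a target — here motivated by
ATP-competitive kinase inhibition — can a model trained on 2D structure
alone separate inhibitors from non-inhibitors, and can it do so for
*scaffolds it has never seen*? `acfnb` implements the standard modelling
stack for this question: physicochemical descriptors, sparse circular
fingerprints, atom-center fragments (ACFs), a Laplacian-corrected naive
Bayesian classifier, depth-bounded recursive partitioning, and the full
confusion-matrix evaluation suite.

## Activity labelling

A compound is an **inhibitor** iff its assay value is *strictly below* the
cutoff (default 10 µM = 10{,}000 nM; 1 µM and 5 µM are the conventional
sensitivity settings). The boundary case — a value exactly at the cutoff —
is a non-inhibitor: "below" is read strictly, and the choice is tested.
Ki and IC50 values are pooled without conversion; the assay type is carried
as metadata only. Duplicate structures are collapsed keeping the lowest
(most potent) value, the conservative reading of an otherwise unspecified
dedup rule.

The *inhibition index* used in descriptor/activity correlation analyses is
$-\log_{10}(\text{value in mol/L}) + 2$, i.e. molar pKi/pIC50 plus a fixed
offset of 2. The offset's origin in the source convention is ambiguous; we
adopt the molar-based reading because it makes the index scale-free and
monotone in potency, and document it here once.

## Featurization

**Descriptor panel.** The 13 descriptors are MW, nHBDon, nHBAcc, N_rot,
nRing, nAR, N plus O (computed natively from the molecular graph: donors
are N/O bearing hydrogen; acceptors are N/O excluding pyrrole-type and
amide nitrogens; rotatable bonds are non-ring single bonds between
non-terminal heavy atoms; rings are SSSR) plus six continuous models
(AlogP, logD, logS, MPSA, MFPSA, MSA) delegated to a pluggable *provider*.
The default provider uses additive approximations — Ertl-style polar
surface contributions, a coarse atom-contribution logP, an ESOL-style
solubility regression, overlap-scaled van der Waals sphere areas — which
are monotone with the quantities they stand in for but are **not**
publication-grade values; swap in a full-toolkit provider for those. A
provider failure degrades the continuous block to `NA` with a warning;
count descriptors always survive.

**Circular fingerprints.** ECFP-style iterative neighborhood hashing:
initial invariant (element, charge, degree, attached H, aromatic flag),
then `diameter/2` rounds hashing the sorted (bond order, neighbor id)
pairs through a fixed 31-bit modular mixing function. Environments
duplicating an already-covered atom set are removed. Identifiers stay
sparse — no folding — because the Bayesian learner consumes sets, not
fixed-width bit vectors.

**Atom-center fragments.** For every heavy atom, the level-*n* ACF is the
induced subgraph of all atoms within *n* bonds, *keeping* bonds between
in-reach atoms (ring closures survive). The canonical key marks the
center, records element/charge/aromatic flag and bond orders, and encodes
severed boundary bonds as attachment stars. Canonicalization uses
Weisfeiler–Lehman partition refinement seeded with distance-from-center,
individualization on ties with a lexicographic-minimum search, and an AHU
rooted-tree fast path for acyclic fragments. The exact encoding of the
original in-house program is unpublished; this scheme is a reconstruction
chosen for reproducibility and order-independence, and its invariance is
enforced by 100-permutation tests. Multilevel featurization (levels
1..`max_level`, default 3) tags keys with their level so identical shapes
at different radii stay distinct.

## The Laplacian-corrected Bayesian classifier

With class prior $P = \#\text{inhibitors}/n$ and correction strength
$K = 1/P$, a feature $F$ contained in $N_F$ training compounds ($A_F$ of
them inhibitors) receives

$$P_\text{corr}(F) = \frac{A_F + PK}{N_F + K} = \frac{A_F + 1}{N_F + 1/P},
\qquad w_F = \ln\frac{P_\text{corr}(F)}{P}.$$

$K = 1/P$ makes a data-free feature return exactly the prior, hence weight
0: a compound whose features were never seen in training scores exactly 0.
Features are counted by presence, not multiplicity (binary-fingerprint
semantics); occurrence counts are retained for reporting. The compound
score is the plain sum of present-feature weights; `score > 0` predicts
inhibitor (strict), and the interval $[-20, 0)$ is the *uncertain zone*
(configuration default taken from the observed score-histogram overlap,
not re-estimated — note a score of exactly 0 therefore lands on the
reliable-inhibitor side of the boundary). Leave-one-out scores are
computed by decrementing the count tables; the fast path is tested to
equal $n$ explicit refits to $10^{-9}$.

Descriptors can join the feature set through equal-frequency binning
(edges learned on training data, frozen for prediction, out-of-range
values clamped): each (descriptor, bin) pair becomes a categorical
feature. Whether the original vendor pipeline used this encoding is
unknown; equal-frequency binning is the declared stand-in. Features
occurring once can be pruned behind a flag (`prune_singletons`); the
default keeps everything, because the vendor's pruning rule is
unpublished.

## Recursive partitioning

`grow_tree` is greedy CART: Gini impurity, binary fragment features split
present→right/absent→left, numeric descriptors at midpoints between sorted
distinct values, stopping on purity, `max_depth`, or `min_leaf` (default
10, tempering the overfitting a deep sweep invites). Ties between equal
gains resolve to the lexicographically smallest feature name, then the
smallest threshold, so the tree is invariant to feature-column
permutation. One deliberate deviation from textbook CART: a zero-gain
split is admitted when depth budget remains below it, because parity-style
interactions (the XOR small case) are otherwise unreachable by any greedy
positive-gain grower; pure nodes and exhausted budgets still terminate.
Missing numeric values route to the child that received more training
examples.

`tune_depth` sweeps depths (default 3–20) under stratified k-fold CV on
the training set and selects the depth maximizing the pooled Matthews
coefficient, smallest depth on ties. Selecting instead on an external test
set — the replication mode exposed via `eval_features` — leaks the test
set into model selection and is off by default. Whether the original
protocol's 5-fold CV selected the depth or merely assessed robustness is
ambiguous; both modes exist for that reason.

## Evaluation

`compute_metrics` implements SE, SP, Q_i, Q_ni, Q and Matthews C with the
standard conventions (C = 0 when a denominator factor vanishes; a metric
whose own denominator is zero is flagged `NA`). The engine reproduces all
26 published benchmark confusion rows (52 training/test halves shipped as
a text fixture) to 3 decimal places with half-up rounding. ROC/AUC uses a
threshold sweep with trapezoidal area; ties contribute half credit, so the
AUC equals the normalized Mann–Whitney pair count, and the equivalence is
property-tested on random score sets. The two-sample test defaults to
Welch (unequal variances) rather than the classical pooled Student test —
the robust modern default — with a `pooled` flag for strict replication.

## The synthetic world

`generate_library` assembles valence-respecting molecules by concatenating
curated SMILES pieces via single bonds. Defaults state the world the
package is tested in: 500 compounds, 80% actives (emulating a ~4:1
composition), MW in 140–700, activity values log-uniform on the correct
side of the 10 µM cutoff (so assay values carry no information beyond the
class), and planted class-defining substructures at fidelity 0.9: actives
carry a nitrogen-in-saturated-ring motif (piperidine), non-actives an
unsaturated-lactam motif, each with probability equal to the fidelity and
*no* planted piece otherwise — so each fragment occurs only in its own
class and its class association equals the fidelity exactly. The planted
pieces are interior-safe: assembly only bonds to their first/last written
atom, so the nitrogen-centered level-1 ACF key is identical wherever the
piece is embedded, and `planted_fragment_keys()` recovers it from the
isolated fragment for recovery checks.

What a green test establishes: the full pipeline — parsing,
featurization, learning, ranking, evaluation — recovers a known planted
signal at realistic library scale. What it does not: medicinal-chemistry
realism (no property matching beyond the MW band and class balance, no
scaffold-series correlation, no assay noise structure), so synthetic
performance numbers say nothing about any real target.

## Numerical choices

Fingerprint hashing is exact 31-bit modular arithmetic in doubles (no
platform dependence). Gini gain ties use a 1e-12 tolerance. Rounding for
published-table comparison is half-up at 3 decimals, matching the tables'
presentation. Model persistence stores integer counts and the prior;
weights are recomputed on load, so loaded models score bit-identically.
All randomness (splits, folds, the generator) flows through explicit
integer seeds, and the CLI echoes a JSON config sufficient to reproduce
any run byte-identically.

## Known limitations

The SMILES dialect omits stereochemistry (read and dropped) and
multi-ring aromatic envelope perception (single-ring Hückel only);
tautomer canonicalization and 3D geometry are out of scope. The default
descriptor provider is approximate by design. Vendor fingerprint dialects
(functional-class and path-based families) are not reimplemented;
externally computed feature sets can be plugged in through the
`featureset` serialization schema.
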