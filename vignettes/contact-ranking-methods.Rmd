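---
title: "Two-stage contact prediction by ranking fusion: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage contact prediction by ranking fusion: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two residues of a folded protein are *in contact* when their C&beta; atoms
(C&alpha; for glycine) lie less than 8 &Aring; apart — the CASP community
definition, with a strict inequality.  Contacts are stratified by sequence
separation $|i-j|$: short range (6–11), medium range (12–23), long range
($\ge 24$); pairs closer than 6 residues along the chain usually share a
secondary-structure element and are excluded.  Predicted contact maps
constrain conformational search in template-free structure prediction, and
predictions are assessed by the precision of the Top 5, $\lfloor L/10
\rfloor$ and $\lfloor L/5 \rfloor$ highest-scored pairs per range class,
macro-averaged over domains with $L > 50$.

`contactrank` implements a two-stage fusion architecture for this task.

## Stage 1: two heterogeneous scorers

**Correlated-mutations (CM) inputs.**  Score matrices from co-variation
tools (sparse inverse covariance, pseudolikelihood Markov random fields,
…) are consumed as files — triplet lists, full $L \times L$ matrices, or
CASP RR lines.  Raw CM scores are not naturally bounded, so each matrix is
min–max normalized per protein to $[0,1]$ at load time; a constant matrix
maps to 0.5 everywhere.  Whether normalization should be per protein or
global is not fixed by the architecture; per-protein scaling is our choice
and makes scores comparable across targets of different alignment depth.

**Windowed sequence-feature forests.**  Every residue is described by
$F = 32$ features: 20 PSSM log-odds columns (used raw, no squashing), the
profile's information-per-position and relative-weight columns (passed
through unscaled), a 3-state secondary-structure one-hot, binary solvent
accessibility (buried/exposed at the usual 25% cutoff), the five published
Atchley factors, and the relative position $p/L$.  A residue pair is an
18-residue window instance: the 9-residue windows centred at $i$ and $j$,
concatenated ($2 \times 9 \times 32 = 576$ values); windows extending past
the termini are zero-padded, keeping the dimension fixed — zero is the
neutral value for log-odds-centred features.

Native contacts are extremely sparse (roughly 2–3% of considered pairs),
so training pools are rebalanced by under-sampling non-contacts to a 4:1
non-contact:contact ratio.  Under-sampling discards information; to
counteract that, the sampling is repeated three times per range class and
one random forest is trained per subset, the ensemble score being the mean
of the three class probabilities.  Negative draws are disjoint across the
three subsets when availability permits, and the pool is put in canonical
order (target id, $i$, $j$) before seeded sampling so results never depend
on input file order.  Forest hyperparameters are not dictated by the
architecture; we fix 500 trees, unlimited depth, minimum node size 5, and
`mtry` $= 2\sqrt{576} = 48$ — wider than the classification default
because the informative columns of a windowed profile are few, and a wider
draw finds them with far fewer trees.  All of this is recorded in the
model metadata.  The environment provides no R tree learner, so the
forests (Gini splits, bootstrap, per-node feature subsets) are implemented
in C++ inside the package; trees serialize as plain numeric matrices.

## Stage 2: per-protein ranking SVM

Each target protein $t$ is a query group and its residue pairs $d$ are the
documents.  The fusion feature vector $\Phi(t,d)$ holds the $k$ normalized
CM scores and the RF ensemble score — all in $[0,1]$.  The model is the
linear ranking function: pair $d_i$ ranks above $d_j$ iff $\omega \cdot
\Phi(t,d_i) > \omega \cdot \Phi(t,d_j)$, and $\omega$ minimizes

$$ V(\omega,\xi) \;=\; \tfrac12\,\omega\cdot\omega \;+\; C \sum \xi_{i,j,k},
\qquad
\omega\cdot\big(\Phi(t,d_i)-\Phi(t,d_j)\big) \ge 1 - \xi_{i,j,k},\;
\xi \ge 0, $$

over within-group difference vectors (constraints never cross proteins).
The slack variables are exactly the hinge losses, so the solver minimizes
$\tfrac12\|\omega\|^2 + C\sum\max(0, 1-\omega\cdot\Delta)$; only the linear
kernel is supported.  We solve the box-constrained dual by coordinate
descent (deterministically re-shuffled sweeps); correctness is defined by
the objective contract, and the test suite checks the final objective
against an independent `quadprog` dual solution to $10^{-6}$ on toy
instances, plus the 1-D closed form $\omega^* = \min(1, Cn)$.  The
stopping test uses `tol * max(1, C)` because dual gradients scale with
$C$.  Failure to converge is an error, never a silent result.

Design points the architecture leaves open, and what we chose:

* **Relevance granularity.**  Ranking by raw distances makes the
  constraint set quadratic in pair count.  Distances are binned into five
  ordinal levels (edges 8, 12, 16, 20 &Aring;; the sub-8 bin is the
  contact bin), preserving "smaller distance, higher rank" while bounding
  constraints.  Bin edges are configuration.
* **Sampling.**  At most `pair_cap` (default 2000) pairs per target per
  range enter training, and difference vectors are drawn under a global
  budget (`diff_cap`, default 20000) split *evenly across relevance-level
  pairs*: with proportional sampling the far-versus-farther constraints —
  two orders of magnitude more numerous — drown the contact-versus-rest
  constraints that the task actually cares about.
* **Cross-fitted stage-1 scores.**  Forests score their own training
  pairs near-perfectly, so training the ranker on in-sample RF scores
  teaches it to trust the RF far beyond its out-of-sample accuracy (we
  measured fused long-range precision collapsing from ~100% to ~30% on an
  oracle-CM world).  Stage-2 training therefore uses out-of-fold RF
  scores (targets split into `rf_folds = 2` folds); the shipped ensemble
  is trained on all targets.
* **$C$ selection.**  Five-fold cross-validation over a logarithmic grid,
  with folds split *by protein*, never by pair, scoring held-out groups by
  the fraction of correctly ordered difference vectors.  A fixed `C` can
  be set in the configuration.
* **One model per range class**, matching the per-class stage-1
  ensembles; $\Phi$ holds the ensemble mean (per-member columns are a
  possible extension, not implemented).

## The synthetic world

The generator exists so that every module is trainable and testable with
no downloads; its defaults state a world and are then left alone.

* **Structures** are self-avoiding random walks: 3.8 &Aring; virtual-bond
  steps, 4 &Aring; exclusion between non-adjacent residues, confined to a
  sphere of radius $4.4\,L^{1/3}$ &Aring; with a mild centre bias (0.1).
  The two confinement constants were tuned once so that contact density
  over considered pairs lands in the 1–5% band with mean near the native
  2–3% sparsity (measured mean 2.8% at $L = 120$), then frozen.  Walks
  that miss the band are retried with deterministic seed offsets.
* **CM matrices** are $\rho \cdot \text{contact} + (1-\rho) \cdot
  \text{noise}$, symmetrized and normalized: $\rho = 1$ is a perfect
  oracle, $\rho = 0$ pure noise.  Signal can be restricted to chosen
  separation classes to emulate the empirical complementarity of the two
  stage-1 families (co-variation strongest at long range, sequence-window
  classifiers at short range).
* **Feature files**: PSSM rows are residue-type conditioned noise; with
  probability `informativeness`, a contact plants a correlated
  perturbation — a shared log-odds bump of amplitude 10 in the column
  indexed by the pair's separation mod 20 at both endpoints, plus a small
  information-content lift.  Indexing the column by separation matters:
  per-residue features can only carry endpoint information, and at native
  density most residues touch *some* contact, so a single "contact flag"
  column saturates and caps held-out AUC near 0.6.  Separation-indexed
  columns make the false-coincidence rate quadratic and small, and the
  forests recover held-out AUC > 0.9 at `informativeness = 1`.
* **What a green test does not establish.**  The walk is not a protein:
  no secondary structure, no hydrophobic core, no beta-pairing; SS/SA
  strings are independent of the geometry; the planted profile signal is
  far cleaner than evolutionary covariance.  Passing the planted-signal
  criteria shows the machinery (features &rarr; under-sampled ensembles
  &rarr; fusion &rarr; ranking &rarr; evaluation) is correct and
  information-efficient, not that any particular precision would be
  reached on CASP targets.
* The unplanted world is *not* exactly chance for the RF: separation and
  chain-end regularities are genuinely weakly predictive in any
  consistent geometry, so the null-AUC test asserts a band around 0.5
  rather than a point.

## Numerical and degenerate-input conventions

* Pairs with any missing residue coordinate have undefined distance; they
  are excluded from training labels and from evaluation denominators
  rather than being fabricated.
* $\lfloor L/10 \rfloor$ and $\lfloor L/5 \rfloor$ use floor with a
  minimum of 1 (rounding mode configurable); prediction ties are broken
  lexicographically by $(i,j)$, so all outputs are deterministic.
* RR output maps per-protein scores to $[0,1]$ by min–max; a constant
  score vector maps to 0.5.  Out-of-range scores on write are an error,
  never clipped silently.
* The paired two-sided Student's t-test compares matched per-target
  precisions; all-zero differences give $p = 1$, zero variance with a
  non-zero mean is reported as degenerate.
* "Oracle input gives 100% top-$L/5$ precision" is asserted on its
  well-posed domain: a range cell with fewer than $\lfloor L/5 \rfloor$
  true contacts cannot reach 100% for any method, so such cells assert
  the equivalent statement that every true contact is ranked on top.

## Known limitations

Only the C&beta; 8 &Aring; contact definition is implemented (no
C&alpha;-only or heavy-atom variants); mmCIF and binary PSI-BLAST
checkpoints are out of scope; MSAs are upstream of the consumed score
matrices and are never parsed.  The per-member-RF feature variant of
$\Phi$ and nonlinear kernels are deliberately absent.
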