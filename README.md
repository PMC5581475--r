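# contactrank

Two-stage protein residue–residue contact prediction by ranking fusion,
for structural bioinformaticians who have per-target correlated-mutations
score matrices and sequence-derived feature files and want a single,
well-calibrated ranked contact list per protein.

## The method

A residue pair (i, j) of a protein with known structure is a **contact**
when the distance between the Cβ atoms (Cα for glycine) is **< 8 Å**
(strict, the CASP definition).  Pairs are stratified by sequence
separation |i−j|: short (6–11), medium (12–23), long (≥ 24); separations
below 6 are not considered.

**Stage 1** scores every pair two ways:

* k externally computed correlated-mutations matrices (PSICOV /
  CCMpred / GREMLIN-style), min–max normalized per protein to [0, 1];
* an ensemble of random forests over windowed sequence features.  Each
  residue contributes F = 32 features (PSSM 20 + its two trailing profile
  columns, SS one-hot 3, solvent accessibility 1, Atchley factors 5,
  relative position p/L 1); a pair instance is the concatenation of the
  two 9-residue windows centred at i and j (2 × 9 × 32 = 576 values,
  zero-padded at the termini).  Because native contacts are only ~2–3% of
  considered pairs, non-contacts are under-sampled at a **4:1** ratio,
  three times per separation class, and one forest is trained per subset;
  the ensemble score is the mean of the three class probabilities.

**Stage 2** fuses those scores with a per-protein pairwise **ranking
SVM**.  Each target t is a query group; pair d has the fusion vector
Φ(t, d) = (k CM scores, RF score).  The linear scorer ω·Φ is trained so
that pairs at smaller true distance rank higher, by minimizing

    V(ω, ξ) = ½ ω·ω + C Σ ξ      s.t.   ω·(Φ(t,dᵢ) − Φ(t,dⱼ)) ≥ 1 − ξᵢⱼ,  ξ ≥ 0

over within-target difference vectors (the slacks are the hinge losses;
linear kernel only; C chosen by grouped 5-fold cross-validation).
Predictions are evaluated CASP-style: precision of the **Top 5, L/10 and
L/5** highest-scored pairs per separation class, macro-averaged over
domains with L > 50, with paired Student's t-tests between methods.

A deterministic synthetic-fixture generator (compact self-avoiding-walk
structures at native ~2–3% contact density, CM matrices with tunable
signal ρ, feature files with tunable planted informativeness) makes the
entire pipeline trainable and testable offline.

## Worked example

Train on five synthetic targets, predict a held-out one, evaluate:

```r
library(contactrank)

rho <- c(psicov = 0.8, ccmpred = 0.5, gremlin = 0.4)
train <- lapply(1:5,    function(s) generate_target(80, seed = s,  rho = rho,
                                                    informativeness = 0.6))
test  <- lapply(201:203, function(s) generate_target(80, seed = s, rho = rho,
                                                     informativeness = 0.6))

cfg    <- run_config(n_trees = 100, pair_cap = 400, diff_cap = 4000, C = 1)
models <- cr_train(train, cfg)
models

report <- cr_evaluate(cr_predict(models, test), test, cfg)
report
```

```
<contact_models> ranges: short, medium, long 
  CM inputs: psicov, ccmpred, gremlin 
  short: C=1, w = (2.198, 0.084, 0.553, 5.360)
  medium: C=1, w = (2.859, 0.071, 0.512, 6.678)
  long: C=1, w = (2.741, -0.008, 0.779, 4.186)
<evaluation_report> 3 targets (macro-averaged precision, %)
  range L10  L5 top5
   long 100 100  100
 medium 100 100  100
  short 100 100  100
```

The per-range weight vectors are the trained ω = (psicov, ccmpred,
gremlin, RF): the strongest CM input and the RF ensemble dominate, the
near-noise CM columns get near-zero weight, and with this much planted
signal the fused ranker retrieves every top-list contact on the held-out
targets.  The precision table is an `evaluation_report`; `cr_compare()`
adds the paired t-test and the x = y scatter counts between two reports.

On-disk workflows (PSI-BLAST ASCII PSSMs, SS/SA strings, triplet /
matrix / RR score files, CASP RR output) go through `read_pssm()`,
`read_cm_scores()`, `read_pdb_record()`, `write_rr()` and friends, or the
`inst/exec/contact-rank` command-line script
(`make-fixtures | train | predict | evaluate | compare`).

## Package layout

| Path | Contents |
| --- | --- |
| `R/geometry.R` | contact maps, separation classes, PDB ATOM reader |
| `R/io_formats.R` | PSSM / CM-matrix / SS / SA readers, CASP RR I/O |
| `R/features.R` | Atchley table, per-residue features, windowed pair vectors |
| `R/rf_stage.R` | under-sampling, C++ random-forest ensembles |
| `R/ranker.R` | rank examples, difference vectors, dual-CD ranking SVM, fusion |
| `R/evaluation.R` | Top5 / L10 / L5 precision, paired t-test, scatter |
| `R/synthetic.R` | deterministic structure / CM / feature generators |
| `R/cli_config.R` | run configuration, train / predict / evaluate / compare |
| `src/` | CART forest and dual coordinate-descent SVM (Rcpp) |
| `vignettes/contact-ranking-methods.Rmd` | models, design choices, limits |
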