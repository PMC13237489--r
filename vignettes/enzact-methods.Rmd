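---
title: "Methods: weak-label curation, transformer activity classification, and variant prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weak-label curation, transformer activity classification, and variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(enzact)
```

# Scope and model

`enzact` implements a family-specialized workflow for prioritizing
single-point mutants of an enzyme when no large measured activity dataset
exists, only weak species-level labels.  The workflow has three stages.

**Curation.**  Homolog sequences are read from UniProt-dialect FASTA
(species parsed from the `OS=` field), annotated by a pluggable,
deterministic annotator that maps species metadata to a putative activity
class (`HIGH`/`LOW`) and a temperature class (thermophilic > 45 C,
mesophilic 15-45 C, psychrophilic <= 15 C), deduplicated on the exact
amino-acid string (first occurrence kept), and restricted to mesophiles.
An artificial `NONE` ("no activity") penalty group is appended: every
annotated active/binding-site residue of selected high-confidence parents
is substituted with each of the 19 alternative residues.  The penalty
group exists to teach the classifier that active-site substitutions are
not candidates for improvement; it is not a model of the full inactive
sequence space.

**Classification.**  Each sequence is represented by a frozen per-residue
embedding matrix (L x D; D = 1152 for the external embedder contract) that
is never fine-tuned.  The classifier is a stack of pre-normalized
transformer encoder blocks — layer norm, multihead self-attention,
dropout, residual; then layer norm, a position-wise feed-forward network
expanded 4x, dropout, residual — followed by mean pooling over residues
and a linear 3-class head.  Training minimizes the focal loss
$-w_c (1-p_c)^\gamma \log p_c$ with $\gamma = 2$ and per-fold class
weights, with Adam or AdamW, a 5-step linear warm-up followed by 0.95
exponential decay per scheduler step, early stopping on validation
Macro-F1 (patience 5, at most 50 epochs), and stratified 5-fold
cross-validation.  The deployed predictor is the ensemble of the five
fold checkpoints; its score is the mean post-softmax probability.
Because the minority `HIGH` class is the class of practical interest, its
decision threshold is a tunable hyperparameter in [0.3, 0.9]; an optional
rejection rule withholds predictions whose maximum probability is below
0.55.

**Prioritization.**  The full 19L single-mutant library of the target
enzyme is scored by ensemble P(HIGH); a conservativeness pre-filter keeps
variants with `delta PSSM >= -7` (mutant minus wild-type PSI-BLAST
log-odds at the mutated position; the default cutoff sits near the
library-wide average, which the ranking reports for any input).  The
model score and the PSSM filter are deliberately not combined into one
weighted composite score.  Residue-level attribution uses integrated
gradients (zero baseline, 50 interpolation steps, logit of the
ensemble-predicted class) and incoming attention (ensemble/block/head
mean attention matrix, zeroed diagonal, column sums).

# Validation machinery

*Label permutation.*  Whether weak labels carry sequence-associated
signal is tested by comparing a reference learner's stratified
cross-validated Macro-F1 on the true labels against B = 500 label
permutations under three schemes: global, length-restricted (10
equal-frequency bins), and dual-restricted (5 length bins x 5 bins of the
first principal component of amino-acid composition, 25 strata).  The
one-sided empirical p-value is (b+1)/(B+1), never zero.  Reference
learners (random forest, 500 trees, mtry = sqrt(p); gradient boosting,
300 rounds, depth 4, learning rate 0.05; a fast multinomial-logistic
learner for small fixtures) are injected through a fit/predict contract,
so the test contains no learner-specific code.

*Pairwise similarity.*  To check that labels are not a proxy for plain
sequence similarity, unordered sequence pairs are sampled without
replacement, their global-alignment identities computed once and cached,
and same-label status is predicted from identity: AUC (same-label pairs
positive), median identity difference, and rank-biserial correlation
(identically 2*AUC - 1).  Percentile bootstrap CIs resample pairs (1,000
replicates); the unit of resampling is the pair, a documented
simplification.  A label permutation over sequence ids (1,000 replicates,
two-sided, add-one corrected, cached identities) provides the null.

*Leakage-aware splits.*  Global identity is Needleman-Wunsch alignment
identity: matches divided by alignment length, gaps included.  Scoring
defaults are match +2, mismatch -1, gap open -5, gap extend -0.5 and are
configurable, since the identity ratio is far less sensitive to them than
the raw score.  Identity-capped folds build single-linkage clusters over
the graph of pairs at or above the cap (0.70 and 0.40 presets) — the
unique clustering that guarantees no cross-fold pair reaches the cap —
and distribute whole clusters greedily by size.  The audit statistic is
nearest-train identity: a 3-mer TF-IDF cosine prefilter proposes
candidate neighbors, the top k are aligned exactly, and the maximum is
reported.  Species/genus holdouts assign whole taxa to folds with a
seeded greedy assignment (seed 42 preset) balancing fold size and class
composition.  Auxiliary `NONE` sequences are excluded before clustering
and before both label-validation analyses.

*Downstream analyses.*  Trajectory post-processing computes hydrophobic
contact occupancies (closest heavy-atom distance <= 0.45 nm; partner set
= hydrophobic residues outside the 124-134 helix within 0.60 nm of helix
heavy atoms in the first frame of each reference replicate, union over
replicates, applied to both systems).  Replicate-level mean occupancies
feed an exact two-group permutation test that enumerates all C(10,5) =
252 relabelings for 5+5 replicates; the two-sided p counts the observed
relabeling, so attainable values are k/252.  Per-pair tests are
Benjamini-Hochberg corrected and reported as secondary.  Kinetics
post-processing converts fluorescence to product concentration through a
standard curve (0-50 uM grid), takes the ordinary least-squares slope in
a fixed linear window (1,620-1,905 s preset) as the initial velocity in
uM/min, fits v = Vmax S/(Km + S) by multi-start nonlinear least squares,
and converts kcat = Vmax / [E] / 60 with [E] = 3 uM total enzyme.

# Synthetic data: what it emulates and what it does not

All tests run on seeded generators, pure functions of their spec.

The family generator emulates the statistical structure the pipeline
assumes, at desk scale: n = 505 natural homologs of length 100 derived
from a common root at 2% per-site divergence (a close homolog family),
~8%/92% high/low imbalance mirroring weak family labels, species drawn
from a 12-genus pool, and 95 penalty knockouts of one parent's five
catalytic-site residues (600 sequences in total).  The label rules are
planted: `pooled_motif` makes `HIGH` a single-motif property;
`contextual_pair` makes it the co-occurrence of two 5-residue motifs,
with decoy `LOW` sequences carrying doubled copies of a single motif.
The decoys are the point of the design: in the pooled representation the
`HIGH` pattern (one copy of each motif) is a strict interior point of the
decoy patterns (two copies of one motif), so no linear function of pooled
features separates the classes, while a residue-level model with
attention can.  This reproduces, as a testable property, the qualitative
ablation ordering (linear-on-pooled < transformer) without claiming any
quantitative correspondence to real protein families.  The 2% divergence
was chosen so that the planted contextual signal is recoverable by the
reference 1-block configuration under these fixture sizes; at much higher
divergence the background drowns the motif signal for any learner at this
n.

The synthetic embedder maps residue i to the scaled sum of seeded random
projections of the residue identities in a +/-2 window, so motif
co-occurrence is representable and a single substitution perturbs exactly
the rows whose window covers it.  It stands in for a frozen protein
language model only in the contract sense (deterministic L x D output);
it carries no evolutionary information, so passing tests demonstrate
correct mechanics and recoverability of planted signal, not biological
accuracy.

Trajectory fixtures plant per-pair contact probabilities on a synthetic
geometric scaffold (stations 2 nm apart, contact placements at 0.30 nm,
partner-only placements at 0.55 nm) that is deliberately not a physical
protein model; a deterministic occupancy mode realizes exactly
round(p * n_frames) contact frames when measured occupancies must equal
planted values.  Kinetics fixtures generate linear early-phase progress
curves at Michaelis-Menten rates with Gaussian signal noise.

# Numerical choices

- Pre-norm block order (Norm-Attention-Dropout-residual,
  Norm-FFN-Dropout-residual), ReLU feed-forward activations, Glorot
  initialization, layer-norm epsilon 1e-5.
- No positional encoding: the contextual embedder already encodes local
  order, and the permutation-invariance test witnesses the choice.
- Class weights default to inverse training-fold class frequency
  normalized to mean 1; the focal clamp is 1e-8; exact probability ties
  decide HIGH > LOW > NONE.
- The LR scheduler is stepped once per epoch: stepping it per optimizer
  update would decay the rate by >90% inside the first epoch and make the
  50-epoch/patience-5 schedule inert, which contradicts the training
  description it implements; the schedule function itself is defined per
  scheduler step (warm-up to the base rate at step 5, times 0.95 each
  later step).
- Hyperparameter search is a seeded random search over the stated space
  (depth 4-10, log-uniform learning rate 1e-5 to 5e-3, dropout 0.1-0.7,
  log-uniform weight decay 1e-6 to 1e-2, heads {4, 8, 16}, Adam/AdamW,
  tau in [0.3, 0.9]); the sampler is not part of the contribution, the
  space and objective (mean CV Macro-F1) are.  Search reuses the same
  folds as evaluation (no nested CV), a documented caveat.
- Integrated gradients use the trapezoidal rule on the straight path.
  For linear models the attribution is exact; for the MLP-on-pooled
  variant the path is smooth and completeness holds to ~1e-3 at 50
  steps.  For the pre-norm transformer, layer norm is scale-invariant,
  so the zero-baseline path is nearly discontinuous at the origin and
  completeness cannot be certified at 50 uniform steps; the per-residue
  maps remain well-defined and are reported, with this caveat, which
  applies equally to any zero-baseline attribution of pre-norm
  architectures.
- Equal-frequency bins use type-7 quantile edges; a value exactly on an
  interior edge goes to the lower bin; duplicated edges collapse.
- Alignment gap costs follow the open + (g-1) * extend convention.
- Deduplication keys on the exact sequence string; temperature filtering
  happens after annotation (both labels come from one annotator call).

# Problem sizes and runtime

The default test and acceptance configuration trains a 1-block, 4-head,
d = 64 model on the 600-sequence fixture with batch size 16 and learning
rate 2e-3.  A full 5-fold cross-validation completes in a few minutes on
one CPU core; the stress test uses the fast multinomial learner for
B = 100 permutations at this scale.  The reference-scale configuration
(5 blocks, 16 heads, d = 1152, B = 500, 20,000 pairs) is exposed through
the same interfaces and defaults where the method definition fixes them.

# Known limitations

- The synthetic embedder cannot certify performance on real protein
  language-model embeddings; only contracts and mechanics transfer.
- Grouped holdout assignment is greedy, not an exact optimizer of fold
  balance; it guarantees the grouping constraint, not optimal balance.
- The pairwise-identity analysis bootstrap resamples pairs, not
  sequences, so its CIs ignore dependence between pairs sharing a
  sequence.
- Rejection (the -1 label) is off by default and enabled explicitly,
  matching its role as an ablation-mode device; whether the deployed
  pipeline should reject is a user decision.
- kcat uses total enzyme concentration, which reproduces the reference
  conversion; active-site normalization would scale it.
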