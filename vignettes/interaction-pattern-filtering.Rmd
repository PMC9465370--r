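---
title: "Interaction-pattern filtering of docked poses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-pattern filtering of docked poses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posefilter)
```

## The problem

Molecular docking proposes binding poses for a small molecule against a
protein, but its scoring functions produce many false positives, which is
especially damaging in reverse docking (target fishing), where one ligand is
docked against many candidate receptors and the ranking itself is the
result. `posefilter` implements a statistical rescoring filter built not on
physical energy terms but on the empirical geometry of atomic contacts
observed in crystallographic protein–ligand complexes.

The unit of observation is the **interaction pair**: one ligand heavy atom
together with one **protein fragment** — three covalently linked protein
heavy atoms — whose first (anchor) atom lies within 5 Å of the ligand atom
(inclusive). Pairs are pooled across training complexes and grouped by
(SYBYL atom type of the ligand atom, fragment type), where the fragment
type is the residue name of the anchor plus the three atom names. Within
each group, the spatial distribution of ligand atoms around the fragment is
modelled with a Bayesian–Gaussian mixture; mixture components supported by
at least 20 training ligand atoms are **significant interaction patterns**.

A docked pose is then summarised by two numbers:

* `pattern_num` — how many of its interaction pairs fall on significant
  patterns, and
* `pattern_ratio` — that count divided by all of its interaction pairs
  (defined as 0 for a pose with no contacts).

The screening rules shipped as defaults are the published operating points:
a potential target must satisfy `pattern_num >= 600` **and**
`pattern_ratio >= 0.8` (a strict conjunction); the pose-level Youden-optimal
cutoffs are 285 on the count and 0.679 on the ratio, reported as two
independent flags. A two-feature probability classifier (gradient boosting
by default) fuses the same two numbers into a probability that the pose is
near-native (ligand RMSD ≤ 2.5 Å from the crystal pose).

## Geometry: what exactly is clustered

The training quantity handed to the mixture model is the ligand atom's
position expressed in a local orthonormal frame of its fragment:

* origin at the anchor atom,
* x along anchor → second atom,
* y in the fragment plane, positive toward the third atom,
* z completing a right-handed system.

This 3-vector is rigid-motion invariant (the frame co-moves with the
protein), preserves the contact distance (`|local| = distance` because the
anchor is the origin), and is low-dimensional enough to cluster with modest
data. Collinear fragments fall back to a deterministic axis choice and are
flagged. Because the anchor is defined as "the first atom" of an undirected
three-atom path, a canonical orientation is mandatory for reproducible
grouping: each path is oriented so the (residue name, atom name) label
sequence is lexicographically smallest end-first, ties broken by atom
index. The convention is versioned in library metadata
(`pf-frag-lexmin-1.0`), and scoring refuses a library whose conventions
differ from the running build.

The distance is measured to the anchor only, not to all three fragment
atoms, and a ligand atom contacting k fragments contributes k pairs: the
screening statistics count pairs, not atoms.

## Chemical typing

Bonds are perceived either from a shipped amino-acid connectivity template
(with peptide C–N links between sequence-adjacent residues) or, for
non-template residues and ligands, from interatomic distances (covalent
radii + 0.45 Å). SYBYL atom types are assigned by a self-contained,
versioned rule table (`pf-sybyl-1.0`) keyed on element, heavy-atom degree,
aromatic-ring membership (rings of 5–7 sp2-consistent members planar within
0.1 Å RMS), and neighbour pattern, with double/triple bond orders inferred
from bond lengths. The table emits C.1/C.2/C.3/C.ar, N.1/N.2/N.3/N.4/
N.ar/N.am, O.2/O.3/O.co2, S.2/S.3/S.O/S.O2, P.3, halogens, and Du as the
sink for anything else. Typing operates on hydrogen-free structures
throughout — the pattern method is defined on heavy atoms, so hydrogens are
stripped on input and never re-added. A deliberate consequence: isolated
(degree-0) heavy atoms default to the sp3 type of their element.

## The mixture model

Each group's local coordinates are fitted with a variational Bayesian
Gaussian mixture: full covariances, a symmetric Dirichlet weight prior with
concentration 1/K (K = `max_components`, default 10), and Normal–Wishart
priors on means and precisions. The small concentration gives
Dirichlet-process-style behaviour — surplus components lose responsibility
and empty out — so no per-group model selection is needed. Member counts
come from hard (argmax-responsibility) assignment at convergence, which is
what the "≥ 20 ligand atoms" significance rule needs; groups with fewer
than 20 points are still fitted but can contain no significant component by
construction. Raising `min_members` can therefore never increase the number
of significant patterns.

Three numerical choices matter and are worth stating plainly:

* **The full variational lower bound (ELBO)** is used both as the
  convergence criterion (relative change < 1e-3, at most 500 iterations)
  and to select among restarts. A cheaper log-normaliser surrogate is not a
  substitute: it ignores the Occam penalty and will happily prefer a true
  cluster split into two overlapping halves.
* **Wishart prior scale by empirical-Bayes calibration.** A first pass is
  fitted under a prior scaled to the group's covariance; the prior scale is
  then reset to the member-weighted average of the fitted component
  covariances and the model refitted. A prior at the spread of the whole
  group makes broad merged components cheap (two patterns 8σ apart collapse
  into one); a prior far below the pattern scale makes needle components
  cheap (one pattern splits). Tying the scale to the fitted pattern scale
  avoids both failure modes.
* **Restarts on a granularity ladder, plus merge refinement.** Restart
  initialisations are seeded k-means partitions with k stepping from
  `max_components` down to 1 (default 5 restarts); the ELBO picks the
  winner. Variational updates merge surplus components far more readily
  than they split merged ones, so at least one start must sit at or just
  above the true component count. The winning fit is then refined by
  greedy ELBO-guided merging: restart from a hard assignment in which one
  pair of occupied components is pooled, and accept the result only if the
  lower bound improves. Both devices attack the same characteristic local
  optimum — a true cluster split into overlapping halves — and both are
  deterministic. Measured on planted mixtures of 2–4 clusters (50–80
  points each, 8σ separation), the combination recovers the correct
  significant-component count in 98–100 of 100 seeded fits (and 30/30 on
  single 45-point clusters); with plain k = 10 restarts and no refinement
  the rate was 91/100.

Covariances carry a 1e-4 Å² diagonal ridge, so 200 copies of one point
still yield a proper (single, significant) component. Per-group seeds are
derived from the master seed by a polynomial hash of the group key, and
groups are fitted in sorted key order, so a library rebuild under the same
seed is byte-identical.

Scoring a docked pair evaluates the posterior responsibilities of its local
coordinates under the group's fitted mixture (via the serialised weights,
means and covariances); the pair is significant iff the argmax component is
a significant pattern. A pair whose group key was never seen in training is
not significant. An optional Mahalanobis gate (χ², 3 d.o.f., 0.99) is
available for stringency experiments but off by default: position inside a
known group only changes the verdict when the group holds a mix of
significant and non-significant components.

## Validation harness

The evaluation module reproduces the standard validation computations with
explicit conventions:

* **Ligand RMSD** is in-place (no superposition), atom correspondence by
  input order, no graph-symmetry correction — the docking convention for
  judging a pose against the crystal ligand. Poses at or below 2.5 Å are
  near-native; per docking case the lowest- and highest-RMSD poses can be
  selected (ties to the lexicographically smallest pose id).
* **ROC analysis** evaluates thresholds at the unique score values with the
  rule "score ≥ threshold ⇒ positive"; AUC is the trapezoid area, which
  equals the normalised Mann–Whitney U statistic with half credit for ties.
  The Youden cutoff maximises J = sensitivity + specificity − 1, ties
  (within 1e-12, absorbing floating-point noise between mathematically
  equal J values) resolved to the smallest threshold.
* **Confusion metrics** (accuracy, sensitivity, specificity, PPV, NPV) are
  closed forms on the 2×2 table; zero denominators yield NA, never an
  error. Near-native is the positive class.
* **Splitting** shuffles under a seed and cuts at `round(n * fraction)`;
  1,252 items at 0.7 give the published 876/376 sizes. An optional grouped
  mode keeps all poses of one complex on one side, because the two extreme
  poses of a complex are statistically dependent; the default remains the
  plain random split.
* **The five-model comparison** trains logistic regression, k-nearest
  neighbours (k = 5, standardised features), a decision tree, a random
  forest (500 trees) and gradient boosting (100 rounds, depth 3, eta 0.3,
  single thread) on exactly the two features, and reports test-set AUC plus
  confusion metrics at a probability cutoff of 0.5. The operating point and
  the hyperparameters are configuration, not claims: the source material
  states none.

## What the synthetic generators emulate — and what they do not

All tests and the acceptance script run on synthetic structures built by
the package itself:

* `make_toy_complex` realises fragments as bonded carbon triples of a
  pseudo-residue (FRG) on a wide grid and places ligand atoms at exact
  anchor distances — every requested contact is recovered by extraction at
  exactly its requested distance.
* `make_planted_pattern_corpus` plants Gaussian contact clouds (truncated
  to the 0.6–4.9 Å annulus so every planted point yields exactly one pair)
  in chosen groups, optionally with uniform decoy contacts, and returns the
  ground truth alongside.
* `make_pose_set` displaces each ligand atom by the target distance along a
  random direction, hitting any requested in-place RMSD exactly.
* `make_feature_table` produces separable, label-independent (null) and
  monotone two-feature tables for the classifier stage.

Every generator is a pure function of its spec and seed. What they do *not*
emulate: real amino-acid chemistry and its fragment-type diversity,
correlated contacts from a connected ligand (synthetic ligand atoms are
independent), anisotropic or multi-modal contact noise, and the class
imbalance of real pose sets. Passing tests therefore demonstrate that the
algorithms implement their contracts and that the pipeline separates
planted signal from planted noise — not that the shipped thresholds will
reproduce their published error rates on real docking output, which would
require the original crystal-structure corpus and docking runs.

In the end-to-end discrimination study, near-native poses carry contacts
drawn around the trained pattern means while decoys carry contacts in group
keys absent from the library plus off-pattern geometry. This is a design
consequence, not a convenience: with the Mahalanobis gate off (the default,
matching the published method), argmax assignment inside a group whose only
components are significant cannot discriminate by position alone, so decoy
character has to come from group membership — chemically, from contacts the
training corpus never saw.

## Problem sizes and determinism

The shipped test suite and `scripts/acceptance.R` use: 100 random contact
fixtures up to 50 ligand atoms × 200 fragments checked against exhaustive
scans; 30 random bond graphs up to 200 atoms for fragment enumeration; 100
seeded mixture fits for planted recovery (2–4 clusters, 50–80 points each,
8σ separation); 1,000 random score sets for the ROC oracles; every 2×2
table with at most 20 observations; and a 220-pose end-to-end screen (110
near-native, 110 decoys) for the five-model comparison, with a label
permutation as negative control. These sizes were chosen as the smallest
that exercise each property convincingly; all of them are pure functions of
the seed, and a rerun under the same seed is byte-identical in primary
outputs (serialised libraries, scores, metric tables).

## Known limitations

* SYBYL typing is rule-based on heavy-atom geometry; exotic chemistry
  (metals, unusual oxidation states, charged nitrogens without degree-4
  signature) lands in coarse or sink types. The table is versioned so a
  library records exactly which rules built it.
* Whether the original pipeline typed ligand atoms with hydrogens present
  is unknown; this implementation is hydrogen-free end to end and says so
  in its metadata.
* The feature vector clustered per group (the fragment-local 3-vector) is a
  documented reconstruction of an upstream design that is not restated in
  full in the source material; it is the natural rotation- and
  translation-invariant choice that preserves the contact distance, and it
  is recorded in library metadata.
* RMSD carries no molecular-symmetry correction; symmetric ligands can
  receive pessimistic values.
* The published headline numbers (Youden cutoffs 285/0.679 with their
  sensitivities/specificities, the model-comparison table) were computed on
  a 1,252-pose dataset derived from 314 complexes plus docking runs that
  are not distributable; they enter this package as default thresholds, not
  as reproducible quantities.
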