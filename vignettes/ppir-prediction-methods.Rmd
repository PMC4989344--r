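---
title: "Methods: predicting interface localization of modification sites"
author: "ppirpredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting interface localization of modification sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppirpredict)
```

# The problem

Post-translational modifications (PTMs) often regulate protein-protein
interactions, and whether a modified residue sits inside a
protein-protein interacting region (PPIR) — the set of residues that
form a binding interface between polypeptide chains — changes how that
modification can act.  Structural coverage is sparse: only a small
fraction of known modification sites fall on residues with a solved
complex structure.  `ppirpredict` implements a complete workflow that
(i) derives inside/outside-PPIR labels for modification-site sequence
windows from atomic coordinates, and (ii) learns sequence-based
classifiers from those labels so that the inside/outside call can be
made for the vast majority of sites that have no structure.

# Interface mapping from coordinates

A residue pair on two *different* chains is called interacting when
some pair of heavy atoms overlaps in the Van der Waals sense:

$$ d(a, b) < r(a) + r(b) + \tau $$

with per-element radii $r$ (defaults C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80, Se 1.90 Å) and tolerance $\tau = 0$ Å.  Making the radii table
and tolerance explicit arguments keeps the rule reproducible; both can
be changed in `detectContacts()`.  Hydrogens are ignored (most
deposited structures lack them), waters are ignored, only the first
model of a multi-model file is read, and alternate locations resolve
to the highest-occupancy conformer (ties: first seen).  Intra-chain
contacts are never counted, and each unordered residue pair counts
once — including between identical chains of a homodimer.

Structures with fewer than two chains have no interaction partner and
are dropped by `buildPpirMap()`; every residue of every retained chain
is recorded with an interacting flag (true iff it participates in at
least one inter-chain contact).

Modification-site windows are 15-mers with the modified residue at
position 8.  Windows shorter than 15 residues (sites near protein
termini) or containing non-standard letters are removed before
matching.  A window is labeled by exact substring matching against the
one-letter chain sequences of the map: windows with no match anywhere
are removed (no structural evidence), and a matched window is `inside`
when, in at least one match, the residue aligned with window position
8 is flagged interacting.  Residues with non-standard names become `X`
in the chain sequence, which deliberately breaks matching across them.

# Encoding

Each amino-acid property scale (an AAindex1 entry: one real value per
residue) turns a window into 14 features: the value at each flank
position minus the value at the modified position, flanks ordered
$-7\ldots-1, +1\ldots+7$.  The subtraction removes the site's own
contribution — with a complete scale and 102 scales the feature array
is $n \times 1428$, organised in contiguous 14-column blocks, one per
scale.  Adding a constant to a scale leaves its block unchanged;
scaling a scale scales its block.  Scales with missing values are
excluded at load time (`parseAAindex(drop_na = TRUE)`) because the
subtraction is undefined for them.  The specific set of scales is
configuration, not algorithm: any complete set is accepted, and the
package ships the Kyte-Doolittle hydropathy scale (also exposed
unsubtracted, per position, via `kdHydropathyFeatures()` as the
conventional baseline).

# Class balancing

Mapped datasets are heavily imbalanced (interface sites are the small
minority).  The majority class is reduced by clustering, not by naive
random dropping, so that motif diversity survives: the outside-class
windows are clustered into $K = 10$ groups by Gibbs sampling over
position-specific scoring matrices, and each cluster contributes a
quota of randomly drawn windows.

The clustering model: cluster $c$ has a $20 \times 15$ pseudocounted
column distribution $p_{c}$ ($\beta = 50$ pseudocounts distributed by
the background, which is the residue frequency of the input set);
window $w$ scores $\sum_j \log_2 (p_c[w_j, j] / q[w_j])$.  Sweeps
reassign every window by sampling from the posterior over clusters at
a temperature annealed linearly from 1.5 to 0.1 across 100 sweeps,
followed by a greedy polish; the assignment with the largest
information-content objective ($\sum_c \sum_j KL(p_{cj} \| q)$, bits)
seen during the run is returned.  Everything is deterministic given
the seed.

Under-sampling quotas are proportional to cluster size by default,
made to sum exactly to the minority size by the largest-remainder
method, so the balanced dataset has exactly equal classes and each
cluster keeps its share within rounding.  An equal-count-per-cluster
mode is also provided (`mode = "equal"`, `--equal-per-cluster` in the
CLI): the two conventions both appear in descriptions of this
strategy, so neither is hard-coded; proportional is the default.
Over-sampling is deliberately not offered — duplicating minority
windows invites over-fitting.

# Classification and evaluation

The reference classifier is an RBF-kernel SVM (kernlab) with $C = 1$
and epsilon 0.1; epsilon is recorded for fidelity although it only
affects regression solvers.  The kernel width uses the
median-pairwise-distance heuristic computed deterministically from the
training rows and is stored with the model.  k-NN ($k = 10$) and a
plugin contract (`fit`/`predict` functions) cover classifier
comparisons under the identical protocol.

Evaluation is 10 independent iterations of stratified 5-fold
cross-validation.  Within an iteration the five test folds'
predictions are pooled into a single confusion table and one
score-based AUC; measures are averaged over iterations with their SD.
The positive class is `inside` (the minority, target class).  Measures
follow the standard confusion formulas (ACC, MCC, PPV, F1, Sn, Sp,
FPR, FNR); MCC returns 0 on a zero denominator; AUC is the rank-based
(Mann-Whitney) statistic with ties counted half.  The Combined
Performance Score

$$ CPS = ACC + AUC + MCC \in [-1, 3] $$

is the selection criterion throughout: summing three complementary
measures avoids anchoring rankings to any single one.

Fold assignment is derived from window identifiers (rows are ordered
by id before folds are drawn), so cross-validation results are
invariant to row order and bit-reproducible given the seed.  Test
folds are never touched during fitting, feature ranking, or selection;
the test suite asserts this with a plugin classifier that records
every row id it sees at fit time.

# Two-stage feature refinement

**Stage 1 — scale selection.**  Each scale's 14-column block is
cross-validated alone; scales are ranked by standalone CPS (ties
broken by accession for determinism).  Blocks are then accumulated in
rank order and the prefix with the global maximum CPS is kept.  The
full trajectory is returned, so the alternative stop-at-first-maximum
convention can be audited from the same output; the global argmax is
used because the sweep is cheap and unambiguous.

**Stage 2 — individual features.**  Within the reduced array,
features are ranked by Relief-F ($k = 10$ neighbours, all instances,
Manhattan distance on min-max-normalized features) or by information
gain with entropy-based MDL-stop discretization (features the MDL
criterion refuses to split get weight 0).  These are the documented
defaults of the commonly used reference implementation, pinned
explicitly so results do not depend on external software.  Features
are added from the top of the ranking and the CPS-maximal prefix is
kept; a `step` parameter thins the evaluated prefix sizes for large
arrays.

Ranking sweeps default to a single 5-fold pass per candidate (the cost
is linear in the number of candidates); final models are always
evaluated with the full 10 iterations.

# Synthetic data: what it emulates and what it does not

All tests and the acceptance script run on generated data; nothing is
downloaded.

* `simulateComplex()` builds Cα-only multi-chain structures on a grid
  whose pitch guarantees no accidental Van der Waals overlap, then
  moves planted partner residues to within contact distance of their
  targets; every non-planted inter-chain pair clears the threshold by
  at least 1 Å.  The generator verifies its own geometry against the
  contact rule and emits PDB text plus the planted truth.  Residue
  identities are random so chain sequences support exact matching.
* `simulateWindows()` draws outside-class residues from a background
  (uniform by default; a Swiss-Prot-like table is available) and
  inside-class flank residues from an exponentially tilted background.
  `effect_size` is calibrated at the window level: the mean of the
  signal scale over the 14 flank positions shifts by `effect_size`
  standard deviations of that mean (per position,
  `effect_size`/√14 residue-level SDs).  A per-position shift of
  several SDs is not attainable on a 20-letter alphabet — the largest
  standardized scale value is around 2 — so the window-level
  definition is the one under which "strong but not degenerate"
  signals exist.  The tilt direction is the component of the signal
  scale orthogonal (background-weighted) to the other supplied scales;
  without this, any frequency shift is visible through *every*
  injective scale and the notion of "noise scales" collapses.
  Exponential tilting is used because it is the minimum-KL
  distribution achieving a given mean shift: a smooth single-knob
  signal.
* `simulateMotifFamilies()` plants consensus 15-mers copied
  per-position with probability `strength`, else background.

What passing tests on these data do **not** show: real interface
windows have positional dependence, compositional biases tied to
structure, and label noise from crystal-packing contacts; synthetic
windows are positionally i.i.d. given class.  Recovery of planted
truth validates the machinery (contact geometry, bookkeeping, ranking,
selection, CV hygiene), not biological performance.

# Numerical and design choices

* Tie-breaks are deterministic everywhere: accession or feature id as
  the secondary sort key; first-attained maximum for CPS prefixes;
  first-seen conformer for equal-occupancy altLocs.
* The per-feature encoding sign is flank minus centre; the opposite
  convention is a global per-block sign flip and changes no
  distance-based or entropy-based result.
* Degenerate inputs fail loudly: empty structures, single-class
  datasets, classes smaller than the fold count, targets exceeding the
  majority size, unknown elements with no radius entry, residues
  missing from a scale.
* The SVM decision-value sign convention of the backend depends on
  label encounter order; scores are oriented using training-set means
  only, never test outcomes.
* All randomness flows from a single integer seed per entry point;
  repeated runs are bit-identical.

Problem sizes used by the test suite and the acceptance script —
500/500 windows for planted-signal recovery, 5 scales (one signal),
2 × 1000 windows with 2 motif families for balancing, ≤ 500-atom
complexes for the brute-force contact oracle, a single 5-fold pass for
ranking sweeps — were chosen as the smallest sizes at which the
planted effects are unambiguous.

# Known limitations

* The interface definition is purely geometric Van der Waals overlap;
  buried-surface-area or distance-cutoff definitions, biological
  assembly reconstruction, and cross-validation of chain sequences
  against reference databases are out of scope.
* Exact 15-mer matching cannot label windows whose protein has no
  solved complex, which is precisely why the classifier exists; it
  also silently merges identical 15-mers from homologous proteins
  (handled by the at-least-one-interface rule and non-redundancy per
  site).
* The shipped scale list contains only the Kyte-Doolittle entry; users
  supply their own AAindex1 file for full-scale encodings, and the
  synthetic scale generator covers testing.
* mmCIF input and NMR ensembles beyond model 1 are not parsed.
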