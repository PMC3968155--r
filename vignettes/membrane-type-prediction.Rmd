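---
title: "Predicting multi-type membrane proteins: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting multi-type membrane proteins: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtype)
```

## The prediction problem

Human membrane proteins are classified into six types by how they sit in
or on the membrane: GPI-anchor, lipid-anchor, multi-pass, peripheral,
single-pass type I and single-pass type II (this index order is fixed
throughout the package). A protein can hold several types
simultaneously — in curated human data the mean number of types per
protein is only slightly above 1 (around 1.03) and no protein carries
more than three — so the prediction target is a non-empty subset of the
six types, encoded as a 0/1 vector of length 6.

Two information sources carry the signal. Sequence homology: proteins
with similar sequences tend to share structure and hence membrane
topology. Interaction networks: proteins that interact tend to share
location and function, and the strength of the evidence is summarized by
a confidence score on the STRING 0–1000 scale (two proteins count as
*interactive* whenever their score is greater than zero).

## The cascade

For a query protein the three stages are tried in fixed order and
exactly one fires.

**Stage 1 — homology transfer.** The query is aligned against every
labelled training protein. Among hits with E-value at or below the gate
(default 0.01), the subject with the maximal alignment score donates its
entire label set. The stage abstains, rather than guessing, when no hit
passes. The package deliberately transfers the *whole* label set of a
single best homolog instead of voting over several: the best homolog is
empirically far more reliable than the runners-up, and set transfer is
what makes multi-type predictions possible at all.

**Stage 2 — confidence-weighted voting.** With no usable homolog, the
direct interaction partners vote. Writing `w_q` for the confidence
between the query and training protein `q` and `l_qk` for `q`'s label
indicator, the type-`k` probability is

$$p_k = \frac{\sum_q w_q\, l_{qk}}{\sum_q w_q}.$$

The sum-of-weights normalizer makes `p_k` the confidence-weighted
fraction of partners carrying type `k` — a probability, equal to 1 when
every partner carries the type, and identically zero exactly when the
query has no interactive training partner (the condition for falling
through to stage 3). Because the normalizer cancels any common scaling
of the scores, the vote depends only on relative confidences; a
`normalizer = "none"` switch is provided for sensitivity checks. The
`t` highest-probability types are predicted, with `t` the smallest
integer at or above the dataset's mean number of types per protein
(`top_t()`; 2 for means in the realistic 1.02–1.04 range). Two
safeguards apply: a type with `p_k = 0` is never predicted even if fewer
than `t` types are positive, and ties at the `t`-th rank go to the
smaller type index for determinism.

**Stage 3 — shortest-distance transfer.** Strong interactions compose:
if a interacts strongly with b and b with c, then a and c plausibly
share types even without a direct edge. The interaction network is
turned into a weighted graph whose edges exist iff the confidence is
positive, with length

$$d(n_1, n_2) = 1000 - w(p_1, p_2),$$

chosen because it is strictly decreasing in confidence (stronger
interaction, shorter edge), exploits the hard 1000 bound of the score
scale, and keeps lengths non-negative as Dijkstra's algorithm requires;
a maximal-confidence edge has length exactly 0, which Dijkstra handles.
A reciprocal alternative `d = 1000/w` is available behind
`transform = "reciprocal"` for sensitivity analysis — it compresses
differences among strong edges and exaggerates weak ones, but yields the
same ranking for single-edge paths. The query copies the labels of the
training protein at minimal shortest distance. So that the cascade
annotates *every* protein, a query unreachable from all training
proteins receives the most frequent single training type; such
predictions are flagged `fallback = TRUE` so evaluations can segregate
them.

In leave-one-out evaluation the query's node and edges stay in the
graph and only its labels are hidden: the experiment removes knowledge
of the types, not the physical interactions.

## Alignment scores and the E-value gate

The built-in provider computes optimal Smith–Waterman local alignments
under BLOSUM62 with affine gap costs (a gap of length `k` costs
`11 + k`, i.e. open 11 / extend 1). The E-value uses the Karlin–Altschul
form `E = K·m·n·exp(−λS)` with the standard gapped-BLOSUM62 constants
`λ = 0.267`, `K = 0.041` and the two sequence lengths as `m`, `n`. These
constants only calibrate the abstention gate; label transfer itself
depends on score ranking, which they do not affect. Users with an
external BLAST/PSI-BLAST run can substitute its tabular report
(`parse_blast_tabular()`); the predictor consumes only
(score, E-value) pairs, so iterated PSSM searches plug in without any
change. Low-complexity filtering should be left off when running
external BLAST on membrane proteins: their hydrophobic stretches are
exactly the regions that determine topology.

Where "alignment score" is ambiguous, the package ranks by bit score
with ties broken by smaller E-value and then lexicographic subject id;
with the built-in provider the bit score is a monotone transform of the
raw score, so the choice only matters when mixing providers.

The gate default of 0.01 balances two failure modes, which
`evalue_sweep()` makes measurable: tightening the cutoff leaves more
proteins unannotated (NU rises), while loosening it admits weak,
often wrong homologs (Acc falls). Coverage is monotone in the cutoff by
construction.

## Pseudo amino acid composition and the NNA baseline

The PseAAC encoding represents a sequence of length `L` by 20 relative
residue frequencies plus, for each of five property profiles (polarity,
secondary-structure propensity, molecular volume, codon diversity,
electrostatic charge — in that fixed block order), `λ = 50` tiered
correlation factors

$$\theta_j = \frac{1}{L-j} \sum_{i=1}^{L-j} \big(F(P_{i+j}) - F(P_i)\big)^2,$$

where `F` is the property value standardized over the 20 amino acids to
mean 0 and standard deviation 1 (the sample standard deviation with
denominator 19; any fixed convention works since the affine map is
shared by all residues). The full vector is normalized by
`D = Σf + w·Σθ`, so its `20 + 5·50 = 270` components are non-negative
and sum to 1. The sequence-order weight defaults to `w = 0.15`,
following the parameterization established for this five-property,
λ = 50 variant in the membrane-protein literature; both `λ` and `w` are
arguments. Sequences must have more than `λ` standard residues: the
package raises an error instead of silently lowering `λ`, because a
per-sequence reduction would change the vector length and break
distance comparability across the dataset (lower `λ` explicitly and
dataset-wide if short sequences are unavoidable). Non-standard residues
(B, Z, X, U, O) are dropped from both the frequencies and the
correlation factors, with a warning.

The NNA baseline assigns the label set of the training protein whose
PseAAC vector is nearest. Euclidean distance is the default; since the
vectors are normalized to a simplex, cosine distance is offered as an
alternative (`distance = "cosine"`), and rankings rarely differ.

## The RWC baseline

The real-weighted combination scores each training candidate by fusing
the three raw signals. Each component is min–max normalized to [0, 1]
over the candidate set — alignment bit score and confidence directly,
shortest distance inverted as `1 − d̂` so that 1 always means closer —
and combined as `S = α·ŝ + β·ŵ + γ·(1 − d̂)` with equal weights
`(1/3, 1/3, 1/3)` by default (exposed as `weights`). Min–max
normalization makes `S` invariant to affine rescaling of any raw
component, which is essential when fusing quantities measured in
unrelated units. Two conventions close the gaps: a component missing for
a candidate (no alignment, no edge, unreachable) contributes its worst
value 0, keeping `S` defined for every candidate; and a component whose
defined values all coincide carries no ranking information and
contributes its best value 1 (equivalently 0 distance), so it cannot
spuriously separate candidates. The candidate with maximal `S` donates
its labels, ties to the lexicographically smaller id. RWC is included
as a comparison method: fusing scores obtained in incommensurable ways
tends to dilute the most reliable signal, which is precisely what the
cascade's strict priority ordering avoids, and the evaluation harness
lets users quantify that on any dataset.

## Metrics

With actual label set `L` and prediction `L*`, per-protein Precision is
`|L ∩ L*|/|L*|` and Recall is `|L ∩ L*|/|L|`, averaged over annotated
proteins. Neither suffices alone: predicting all six types forces
Recall to 1, predicting any non-empty subset of the truth forces
Precision to 1. The headline Accuracy therefore combines a recall term
with an over-prediction penalty,

$$\mathrm{Acc} = \frac{1}{n}\sum_i \left[\frac{|L_i \cap L_i^*|}{|L_i|}
  - \frac{|L_i^* \setminus L_i|}{|L_i^*|}\right] \in [-1, 1],$$

which equals 1 iff every prediction is exact and −1 when every
prediction is disjoint from the truth. Because the penalty form is a
design choice, a bounded Jaccard variant
`|L ∩ L*|/|L ∪ L*| ∈ [0, 1]` is computed alongside in every report;
the two agree at the exact-match extreme, so conclusions that depend on
the variant are immediately visible. Abstaining single-method runs
report abstentions as NU and compute metrics over annotated proteins
only; the integrated cascade never abstains, and its per-stage annotated
counts (NA) always partition the dataset. The c/p/e breakdown counts,
per type-multiplicity group, predictions that are completely correct,
partly correct (some overlap) and incorrect (disjoint).

## The synthetic benchmark

`generate_dataset()` plants the two signals the predictor exploits.
Homologous families of balanced size receive a random ancestor sequence
(default length 120, comfortably above λ = 50) and a shared label set;
members are independent per-site substitution mutants
(`mutation_rate`, default 0.05 — within-family identity ≈ 90%,
squarely in "easy homolog" territory; raise it towards 0.5–0.6 to
starve the homology stage). Family label multiplicities are drawn with
probabilities (0.97, 0.025, 0.005) for 1–3 types, giving a mean of
about 1.035 types per protein and hence top-t = 2, matching curated
human membrane-protein datasets. Edges are drawn with probability
`p_same` (default 0.3) between proteins with *identical* label sets and
`p_diff` (default 0.01) otherwise, with integer confidences uniform on
[150, 999]. The identical-label-set reading of assortativity is what
makes the construction analyzable: with `p_same = 1, p_diff = 0` every
partner of a query carries exactly the query's label set, so the
network vote is provably exact for every non-isolated protein — a
property the test suite exercises. Optional orphans (singleton,
family-less proteins) and decoys (heavily mutated copies of a target
carrying a disjoint label set, `decoy_mutation_rate` default 0.9) plant
the failure mode that motivates the E-value gate: decoy alignments land
at E-values of order 0.1–1, invisible at a 0.01 gate but admitted and
mislabelled at 10.

What the generator does **not** emulate: real mutation processes
(substitutions only, no indels, no rate heterogeneity), realistic family
size and degree distributions (balanced families, Erdős–Rényi-style
edges rather than scale-free), database-scale length variation, and
cross-family homology gradients. Passing tests therefore demonstrate
correctness of the machinery and recovery of planted structure, not the
accuracy levels attainable on curated human data with a full STRING
network and BLAST databases — those require the original large datasets
and are out of scope here.

## Numerical and engineering choices

- Scores are kept internally on the raw 0–1000 STRING scale;
  unit-interval edge lists are rescaled on ingest so the distance
  transform has a single domain. Conflicting duplicate edge rows keep
  the maximum, with a warning; self-interactions are dropped.
- Self-hits are excluded at the provider level, so leave-one-out can
  reuse one all-against-all hit table (`homology_hits()`), computed once
  per dataset.
- All tie-breaks are documented and deterministic (bit score, then
  E-value, then id; probability, then type index; distance, then direct
  confidence, then id), so identical inputs always yield identical
  reports.
- PseAAC normalization is checked to 1e-9 in tests; the encoding is
  exact up to floating-point rounding, with no iterative steps.
- Leave-one-out problem sizes in the tests and the acceptance script
  (mostly 20–200 proteins, length-120 sequences) were chosen so the
  planted-structure guarantees hold with comfortable margins while the
  full suite stays quick to run on a laptop.

## Known limitations

- The built-in aligner is a single-pass Smith–Waterman: it will not find
  the remote homologs PSI-BLAST's iterated PSSMs can reach. The provider
  contract exists precisely so external reports can replace it.
- Karlin–Altschul constants are fixed for BLOSUM62 11/1; supplying a
  different matrix changes scores but not the E-value calibration, so
  non-default matrices should be paired with external E-values.
- The shortest-distance fallback (most frequent type) is a coverage
  device, not a prediction; treat `fallback = TRUE` records accordingly.
- Sequence-less proteins are supported everywhere except as homology or
  NNA queries, where the package errors rather than silently abstaining.
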