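---
title: "Inferring domain-domain interactions from multi-source PPI data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring domain-domain interactions from multi-source PPI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddinfer)
```

## The model

`ddinfer` treats DDI inference as link prediction in a tripartite graph.
For one PPI source, the middle layer is the set of distinct,
alphanumerically ordered protein pairs; the two outer layers are the
Pfam-style domains of the left and of the right proteins. Two domains
are candidate interactors when their incidence rows share at least one
PPI column; the strength of the candidate is the cosine of the two
binary rows,

$$C_{xy} = \frac{K_{xy}}{\sqrt{N_x N_y}},$$

where $K_{xy}$ counts shared PPI neighbors and $N_x, N_y$ count each
domain's PPI neighbors. The underlying assumption is that a true DDI
makes its two domains co-occur across *many* independent interactions,
while both the left/right split and the normalisation by
$\sqrt{N_x N_y}$ penalise promiscuous domains.

Because frequent domains can share neighbors by chance, each candidate
also receives the hypergeometric tail probability
$p = P(K \ge K_{xy} \mid N_x, N_y, N_z)$ ($N_z$ = number of PPIs in the
source), computed through the survival function so it remains accurate
when $N_z$ is large. Significance is a family-wise bound: $p <
\alpha/|E|$ where $E$ is the *merged* candidate set across all sources
and $\alpha = 0.05$ by default. Using one global family (rather than one
per source) is the stricter reading and is exposed as a parameter via
`alpha`; the comparison is strictly less-than.

### Orientation

A domain can occur on both sides of the PPI order, so the same unordered
pair may be scored in two orientations. The package keeps the
orientation with the larger cosine (ties: larger $K_{xy}$, then the
orientation whose left-role domain is the lexicographically smaller
identifier). This is deterministic and favors the stronger evidence; it
also means a true DDI's common-neighbor count is split between
orientations, which makes per-source significance conservative on small
sources.

Identifier comparison everywhere is raw byte order (`"Q10" < "Q9"`),
fixed so that results cannot depend on the session locale.

## Multi-source consensus

Per-source cosine matrices are fused by a non-zero weighted average: a
source where the pair is absent contributes to neither numerator nor
denominator. With a single source the consensus is that source's cosine,
and the combination is invariant to rescaling all weights.

Weights live on the grid $0.01, 0.02, \dots, 1.00$ and are selected to
maximise the AUC of the consensus ranking against the gold standard,
with the background formed by all other scored pairs and midrank tie
handling. Exhaustive grid search is only feasible for up to three
sources ($100^D$ combinations); beyond that the package uses seeded
coordinate ascent: from a set of starts, each source's weight is set in
turn to its best grid value until a full sweep yields no improvement.
Because the AUC landscape is a step function with wide plateaus, single
random starts are unreliable; the optimiser therefore always includes
deterministic starts (equal weights, plus one "emphasise source $d$"
start per source) before the seeded random restarts (default 3). Ties
between weight vectors resolve to the lexicographically smallest tuple,
so results are reproducible. On two-source fixtures the test suite
verifies that coordinate ascent reaches the exhaustive optimum.

## Threshold calibration

Positives are the gold-standard DDIs; negatives are produced by
degree-preserving double-edge swaps of the gold-standard edge set, with
three constraints: no returned edge may be an original, no duplicate
edges, and no *new* self-edges (a homo-DDI counts 2 toward its domain's
degree; forbidding new self-edges is the conservative null). Edges that
cannot be rewired within the proposal budget (default $1000\times$ the
edge count) are dropped with a message — on sparse inputs this does not
happen; it only occurs on structurally rigid degree sequences, where no
valid rewiring exists at all. Shuffled pairs without a nonzero consensus
score cannot be placed on the score axis and are dropped, mirroring how
a scored learning set must be assembled in practice.

The threshold grid is the union of three inclusive phases — 0 to 1 step
0.01, 0 to 0.04 step 0.001, 0.01 to 0.02 step 0.0001 (227 points,
built over integer multiples of $10^{-4}$ to avoid floating-point
near-duplicates). The union contains every point of any sequential
zooming scheme over the same phases. The learning set is split
stratified into Training (2/3) and Test (1/3); 5-fold stratified CV on
Training picks, per fold, the *smallest* grid threshold maximising F1 on
the in-fold data (smallest = the recall-maximising tie-break), and the
working threshold $T_m$ is the fold mean. F1 at $T_m$ is reported on the
whole Training set and on the untouched Test set. Filtering keeps
consensus entries strictly greater than $T_m$. When the learning set is
too small for 5 folds (toy inputs), the pipeline falls back, with a
warning, to the single F1-optimal grid threshold on the whole learning
set; with no usable negatives at all the F1 criterion degenerates to the
grid floor, which keeps every scored candidate.

## Classification

With $D$ configured sources, a retained DDI supported (nonzero score) in
$m$ sources is **Gold** if $m \ge \lceil D/2 \rceil$ and every
supporting p-value is significant, **Silver** if $m < \lceil D/2 \rceil$
with all supporting p-values significant, and **Bronze** otherwise. The
half-support cutoff is exposed (`half_cutoff`) because "at least half"
and "more than half" readings differ exactly at $m = D/2$; the
default is the at-least-half rule. Categories partition the retained
set, and turning any supporting source non-significant can only demote.

## Evaluation utilities

`coverage()` counts, for an interactome and an annotation map, the PPIs
explained by a DDI set: a PPI is covered when some domain of its left
protein and some domain of its right protein form a DDI of the set.
Only cross-protein domain pairs count — those are the only pairs a
physical DDI can mediate in a binary interaction — and PPIs with an
unannotated side are excluded from the denominator. `overlap3()` gives
the seven Venn regions of three DDI sets. `network_stats()` reports
components and degrees of the DDI graph with these conventions: a
self-loop-only domain is a 1-node component; a node's degree is its
number of distinct partners with a self-loop adding 1 (so a self-only
domain has degree 1, consistent with the separate 1-node-component
accounting); the 99% superior degree is the degree at rank
$\lceil 0.99\,n \rceil$ in ascending order; maximal-degree ties resolve
lexicographically.

## The synthetic benchmark

`generate_world()` plants a hidden truth and emits everything the
pipeline consumes. Defaults: 50 domains, 200 proteins, 30 true DDIs of
which 10% homotypic, half revealed as the gold standard, three sources
of 500 PPIs at 80% signal. Each protein carries $1 + \mathrm{Poisson}(2)$
distinct domains (the `domains_per_protein_mean` parameter sets the
Poisson mean; the +1 guarantees annotation). Signal PPIs sample a
planted DDI, then one carrier protein per side; noise PPIs are uniform
random protein pairs — the simplest exchangeable null. The homotypic
share of 10% reflects the rough share of self-interacting families in
curated DDI resources. Worlds are byte-reproducible from the seed.

What the generator does *not* emulate: real Pfam frequency
distributions (real domain families are heavy-tailed; here they are
near-uniform), correlated evidence between databases, study bias,
spoke-expanded complexes, or proteins with no annotation. Passing the
planted-recovery benchmark therefore shows the machinery is correct and
calibrated for exchangeable noise, not that precision on real
interactomes will match.

### What the benchmark shows — and its sharp edge

On the default world the consensus ranking is excellent (AUC ≈ 0.995)
and recall of the hidden truth is complete, but the precision of the
thresholded set is low (≈ 0.2 averaged over seeds, as
`scripts/acceptance.R` recomputes). The cause is instructive. Because
carrier proteins carry extra "passenger" domains, every planted DDI
$(d_A, d_B)$ drags along pairs $(d_C, d_B)$ with $d_C$ co-annotated
beside $d_A$; these co-occur across *all* sources and score between the
shuffled negatives and the planted positives. The degree-preserving
shuffle, by contrast, pairs up gold-standard domains, which are
high-degree in the incidence structure, so shuffled negatives score
systematically *below* the passenger band — and the F1-calibrated
threshold, sitting just above the negatives, admits the passengers. In
other words: the calibration null measures chance co-occurrence, not
indirect co-occurrence, and the benchmark makes that gap visible. At
production scale (millions of PPIs, tens of thousands of domains)
annotation sets are sparser relative to the pair universe and the same
machinery filters far more aggressively (retaining on the order of 2%
of candidates). The per-source significance flags carry the remaining
information: on the benchmark almost nothing clears the global
Bonferroni bar in every source, which is why the toy worlds produce
Bronze-dominated output.

## Numerical and reproducibility choices

* All randomness (shuffle, CV split and folds, optimiser restarts,
  world generation) is driven by explicit integer seeds; the fitting
  function derives distinct sub-seeds for each stage from its `seed`
  argument, and restores the caller's RNG state afterwards.
* Strict inequalities follow the definitions: prediction is
  `score > t`, filtering is `CS > T_m`, significance is
  `p < alpha/n_tests`.
* Degenerate inputs fail loudly (empty sources, all-zero incidence
  rows, unshuffleable single edges, AUC without positives or without
  background) except where the pipeline documents a fallback.
* Test problem sizes: brute-force hypergeometric enumeration up to
  $N_z = 12$; AUC oracles up to 50 keys; 1,000 shuffle-null instances up
  to 50 edges; planted recovery over 5 seeds at the default world size.
  These sizes keep the whole suite around a minute while exercising
  every code path.

## Limitations

* Indirect (passenger) co-occurrence is not separated from direct
  interaction evidence; on dense annotations the thresholded set should
  be read together with the significance flags and categories.
* The exhaustive weight search is limited to three sources; coordinate
  ascent is a heuristic, mitigated by deterministic starts, restarts and
  tie-breaks, and verified against exhaustive search only on small
  fixtures.
* Incidence is binary: interaction confidence values, splice isoforms
  and domain architectures (multi-domain subsets) are out of scope.
* The file interface is deliberately minimal (two-column TSVs); mapping
  from native database formats and identifier systems is the caller's
  responsibility.
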