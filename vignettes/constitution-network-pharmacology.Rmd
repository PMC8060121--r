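---
title: "Constitution-stratified network pharmacology: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constitution-stratified network pharmacology: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnetpharm)
```

## The analysis

Sasang constitutional medicine stratifies patients into four types (SE, SY,
TE, TY) and treats each with herbs held to sustain that type's "requisite
energy". `scnetpharm` operationalises a drug-centric reading of this
system: if the herbs of a type address that type's characteristic
physiology, then the molecular targets of those herbs' compounds should
carry a type-specific signature. The pipeline therefore:

1. builds a tripartite herb–compound–target network from edge tables,
2. pools per-type target gene sets and quantifies their overlap,
3. clusters the types by their target profiles and checks that the picture
   is stable under the per-compound target cap,
4. tests whether type-exclusive targets exceed chance by permutation,
5. characterises each type's targets by GO overrepresentation, first-level
   category profiles, and ICD-10 disease-chapter profiles.

The package assumes compound–target interactions arrive *scored* (a 0–1000
confidence from an upstream prediction resource); it never predicts
interactions itself. Gene identifiers are treated as opaque symbols
(upper-cased on load); no identifier-mapping service is bundled.

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `score_threshold` | 700 | interaction-confidence cutoff on the 0–1000 scale; edges survive only with score strictly greater. |
| `cap` | 10 | per-compound target cap, guarding against a few promiscuous compounds dominating the type signature; robustness is re-checked at 10/50/100/500/unlimited. |
| `R` | 999 | permutations for the exclusivity test; the smallest attainable p is 1/(R+1) = 0.001. |
| `R_cal` | 200 | random gene lists used to calibrate each term's expected rank for the Z-score; ≥ 30 enforced so the rank SD is estimable. |
| `alpha` | 0.05 | significance level on BH-adjusted p. |
| `k` | 3 | top-scored diseases kept per gene for the chapter profiles. |

## Conventions where the method is underdetermined

Several steps admit more than one defensible convention; the package fixes
each one explicitly and deterministically.

* **Cap tie-breaking.** When more than `cap` edges tie on score, the
  lexicographically smallest gene symbols are kept. Deterministic and
  auditable; capping is idempotent and monotone in `cap`.
* **Threshold strictness.** `score > threshold`, so a score of exactly 700
  is dropped.
* **Shared compounds.** A compound listed under several herbs is one node;
  its targets flow to every type owning one of those herbs.
* **UPGMA.** Merge height is half the inter-cluster distance (so cophenetic
  distances equal average-linkage merge distances); ties for the closest
  pair break on the lexicographically smallest sorted label pair; within a
  merge, the child containing the smallest label is written first in the
  newick string. Topology equality across caps compares the unordered
  merge-partition sequence, ignoring heights.
* **Cosine distance** is undefined for a zero vector; a type with no
  surviving targets raises an error naming the type rather than silently
  producing a degenerate tree.
* **Exclusive proportion of an empty set** is defined as 0, keeping the
  permutation statistic defined for degenerate networks.
* **Permutation null.** The shuffle permutes target endpoints (with their
  scores) across the compound–target edges of the *already filtered and
  capped* network: compound degrees and the global target multiset are
  conserved before duplicate (compound, target) pairs are collapsed
  (keeping the higher score). This is the least-structured null consistent
  with "shuffling the interactions"; a full bipartite rewiring would also
  randomise compound degrees, which are an observed property of the
  chemistry, not of the type assignment being tested. The add-one rule
  (1 + #{null ≥ obs})/(R + 1) keeps p strictly positive. Both the per-type
  statistic and the pooled mean are reported, since "the proportion of
  exclusive targets" can be read either way.
* **Enrichment.** `n` in the expected count nK/N and the Fisher tail is the
  number of *mapped* target genes (identifiers absent from the annotation
  universe are dropped first), which is how annotation services behave and
  the only reading under which published expected-value columns are
  internally consistent. The p-value defaults to the one-sided
  hypergeometric tail; a binomial option (success probability K/N) is
  provided because summary tables of such services sometimes describe the
  test as binomial. The combined score uses the natural log.
* **Z-score reconstruction.** The rank-deviation Z-score is documented as a
  reconstruction: for `R_cal` random lists of the same size, all terms are
  ranked by p each time; z = (r_obs − μ)/σ with ties ranked by their
  average; σ = 0 yields z = 0 with a warning. Combined = z·ln p is 0
  whenever p = 1 or z = 0.
* **Category profiles** normalise by total assignments (a gene in several
  first-level categories contributes one assignment to each), because
  gene-count normalisation does not sum to 1 under multi-assignment; a
  per-gene alternative is available. Unannotated genes are tallied
  separately and excluded from the proportions.
* **Disease profiles** count a disease once per contributing gene
  (frequency semantics); `unique_diseases = TRUE` gives the set-based
  alternative. Ties at the top-k score cutoff break on disease id.

## What the synthetic generator emulates

`generate_bundle()` produces every input the pipeline reads, with ground
truth in a manifest. Its defaults are the study conditions at desk scale:
28 herbs split 8/8/8/4, ≈ 230 compounds (about 10 per herb, 1-truncated
Poisson, with a 10% chance of reusing a compound within the same type),
a 1500-gene universe, and per-type target pools of 150/90/75/45 genes —
preserving the SE > SY > TE > TY ordering of the reported per-type target
counts at roughly 0.4 scale. Pairwise pool overlaps are planted as
fractions of the smaller pool (SE–SY 0.30, SE–TE and SY–TE 0.15, SE–TY
0.05, TE–TY 0.02, SY–TY 0), mirroring the reported structure in which SE
and SY share by far the most targets while TY is nearly isolated; overlap
blocks are disjoint across pairs, so no triple overlaps are planted.
Interaction scores follow a Beta(4, 2) rescaled to [0, 1000] with a
configurable 70% of mass above 700. A tenth of compounds are
"promiscuous" (mean 18 targets rather than 4), so the per-compound cap
actually binds — the situation the cap exists for. Every pool gene is
guaranteed one supra-threshold edge within its type, which is what makes
`collect_targets()` on the uncapped network recover the planted pools
*exactly* and lets the manifest serve as an oracle in tests.

The annotation side plants: (i) a first-level category skew (70% of TY-pool
genes assigned primarily to one category, so that category holds a majority
of TY's assignments — mirroring a type whose targets concentrate in
metabolic processes); (ii) one specific term drawing 80% of its 30 genes
from the SE pool (the planted enrichment the combined score must rank
first); and (iii) per-type ICD-10 chapter skews (60% of a gene's disease
draws fall in its type's planted chapter). Genes shared between types
follow the skew of the first type in SE/SY/TE/TY order that owns them.

What the generator does **not** emulate: real gene symbols or chemistry,
correlated term memberships of a true GO hierarchy, the heavy-tailed
degree structure of curated gene–disease resources, or triple/quadruple
pool overlaps. Passing the planted-recovery tests therefore shows the
pipeline's logic is correct under the planted statistical structure, not
that real-database results would be numerically reproduced; the published
per-type gene lists depend on proprietary upstream databases and are out of
reach offline.

## Numerical and statistical checks

The test-suite problem sizes are the package's own choices, balancing
resolution against a test run of about a minute and a half:

* Fisher tails are checked against direct binomial-coefficient enumeration
  over *every* contingency configuration with N ≤ 60 (≈ 1.2 million
  tables); UPGMA against `stats::hclust(..., "average")` cophenetic
  matrices on random tie-free 5×5 matrices; Venn regions against per-gene
  membership tallies.
* Permutation calibration uses 200 replicate null datasets (no planted
  exclusivity, 300-gene universe) at R = 199; the empirical p-values are
  required to sit within Kolmogorov–Smirnov distance 0.15 of uniform. The
  band is wider than the iid-uniform critical value because the exclusive
  proportion is discrete: ties between observed and permuted statistics
  make the add-one p conservative, which is visible as a modest KS
  distance (≈ 0.12–0.14) rather than a defect.
* The type-I calibration of the raw Fisher p uses a library of 50 terms of
  sizes 100–300 in a 1500-gene universe and lists of 200 genes, where
  hypergeometric discreteness is small; the observed rate (~0.04) sits
  slightly below the nominal 0.05 precisely because an exact test can only
  be conservative. Small-term libraries would be far more conservative —
  a property of the test, not an implementation artefact.
* Planted-recovery checks assert the qualitative published structure on
  synthetic data: SE–SY merging first and TY last at every cap, the
  planted term ranked first by combined score, and each type's planted
  disease chapter recovered as its modal chapter.

## Limitations

* Confidence scores are consumed, never computed; results inherit whatever
  biases the upstream interaction predictor carries.
* The analysis is direction-blind: it cannot say whether a target or
  process is up- or down-regulated by a type's herbs.
* The Z-score/combined-score formulation is a documented reconstruction of
  a service-side algorithm whose internals are not public; combined scores
  should be compared within one run, not across tools.
* Venn-region counting by inclusion–exclusion enumerates all 2^g − 1
  patterns and is intended for a handful of groups, not dozens.
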