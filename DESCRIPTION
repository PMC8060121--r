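Package: scnetpharm
Title: Constitution-Stratified Network Pharmacology of Herb-Compound-Target Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses tripartite herb-compound-target networks
    stratified by Sasang constitution type (SE, SY, TE, TY). Provides
    confidence-score filtering and per-compound target caps, per-type target
    gene sets with Venn-region overlap counts, UPGMA clustering of type
    profiles under cosine distance with cap-robustness checks, a permutation
    test for the exclusivity of type-specific targets, PANTHER-style GO
    overrepresentation (Fisher or binomial tests, Benjamini-Hochberg
    correction, rank-deviation Z-scores and combined scores), first-level GO
    category proportion profiles with Euclidean distances, and ICD-10 chapter
    disease-frequency profiles from top-scored gene-disease associations. A
    synthetic-data generator with planted overlap, enrichment, and
    disease-skew structure makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
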