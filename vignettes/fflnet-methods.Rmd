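---
title: "Methods: feed-forward loop enrichment in a TF-miRNA regulatory network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feed-forward loop enrichment in a TF-miRNA regulatory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fflnet)
```

# The analysis

`fflnet` implements the computational core of a systems-biology analysis of
a transcription factor (TF) that sits on top of a miRNA-mediated regulatory
module — the situation of a zinc-finger homeodomain TF such as HB34, which
represses a miRNA (miR157) while directly activating that miRNA's target
(*SPL10*). Four kinds of evidence are integrated:

1. **ChIP-seq binding**: where does the TF bind, and which genes are
   candidate direct targets?
2. **Promoter motifs**: is a binding consensus (YTAATYAW) over-represented
   in target promoters, and where does it sit relative to the TSS?
3. **Differential expression (DE)** in a TF loss-of-function mutant: which
   genes and miRNAs respond, and in which direction?
4. **miRNA-target topology**: which DE miRNA / DE target pairs form
   feed-forward loops (FFLs) with the TF, and is any loop type enriched
   over a permutation null?

The study's raw sequencing data are not publicly deposited, so the package
ships a synthetic-data generator that emulates the *structure* of each
input with planted ground truth. Every method is exercised and validated
against that ground truth and against independent brute-force oracles; the
headline numbers of the original study (thousands of candidate targets,
specific loop counts) are scale anchors, not reproduction targets.

# Feed-forward loop taxonomy

A three-node FFL here has the TF as the apex, a miRNA as the middle node
and a miRNA target as the third node. The miRNA-to-target edge is fixed as
repression. That leaves the two TF edge signs free, so exactly four types
are realizable:

| TF→miRNA | TF→target | type | coherent? |
|----------|-----------|------|-----------|
| + | + | I1 | no  |
| − | − | I2 | no  |
| + | − | C3 | yes |
| − | + | C4 | yes |

Coherence means the indirect path sign (sign(TF→miRNA) × (−1)) equals the
direct edge sign. C4 — the TF activates the target while repressing the
target's repressor — is the module of interest: it behaves as a
sign-sensitive delay that buffers the target against transient input
fluctuations. `classify_ffl()` is this bijection; an exhaustive test pins
all four cases.

Edge signs come from the loss-of-function contrast (`infer_edge_signs()`):
a feature significantly *up* in the mutant is inferred to be *repressed*
by the TF (sign −1), and vice versa. A significant feature with a log2
fold change of exactly 0 is degenerate and yields no edge (warned).

# The permutation test

`enumerate_ffls()` forms one loop instance per (significant miRNA,
significant mapped target) pair. `permutation_enrichment()` then shuffles
the *expression tuples* — (log2fc, p, adjusted p, significance) travelling
together — among the miRNA nodes and, independently, among the target-gene
nodes, keeping the miRNA→target topology fixed; loop counts are recomputed
for each of `n_randomizations` (default 10,000) shuffles. The per-type
p-value is the frequency with which a randomized network has *strictly
more* loops of that type than the observed network, with no add-one
correction (so the minimum attainable p at 10,000 shuffles is 0, and
1/10,000-scale p-values are representable). The randomized mean is taken
over the same shuffles.

Three design points deserve spelling out:

* **Shuffle pool.** The tuples are permuted among *all* measured features
  the caller supplies — non-DE features participate, which is the natural
  exchangeability null. Restricting the pool to map-listed genes is a
  matter of subsetting the records before building the network, and
  `shuffle_scope = "significant"` permutes only among DE features.
* **Strict inequality.** Counting only strictly-greater randomizations
  follows the test's published definition, but it has a sharp corner: if a
  sign pattern (say, significantly-down miRNA) is entirely absent from the
  measured tuples, the type can never form under any shuffle, both the
  observed and every randomized count are 0, and the p-value is exactly 0
  without any enrichment being present. This is a property of the
  statistic, not a bug; the practical consequence is that the test is only
  meaningful on datasets whose tuple multiset represents both directions
  of regulation — which real smRNA contrasts do. The generator's DE
  background (below) guarantees it for synthetic data.
* **Observed counts are invariant** under an identity shuffle, and on tiny
  networks the Monte-Carlo p and mean converge to the exhaustive average
  over all joint permutations; both are tested.

`annotate_direct()` flags loops whose miRNA host gene *and* target are both
candidate ChIP targets — the direct-module case — without filtering, since
the enrichment analysis is expression-based.

# ChIP peak consolidation and target assignment

Peaks arrive as MACS-style tables (interval, summit, −log10 p) per
replicate. `merge_peaks()` applies, as a transitive closure, the rule:
merge two peaks iff their intervals overlap and summits are within 600 bp,
or the intervals are disjoint and summits are within 300 bp. The closure
makes the result independent of input order; the merged peak spans the
union, and inherits the summit and significance of its most significant
member (ties resolved toward the leftmost summit — the rule has to pick
something and the leftmost choice is deterministic).

`high_confidence_peaks()` keeps a replicate-1 peak iff a replicate-2 summit
lies within 600 bp (the merge distance re-used as the support distance; no
separate value is standard), takes the span union with the nearest
supporter and the significance maximum over *all* supporters — using all
supporters rather than just the nearest keeps support exactly symmetric
between replicates even when two peaks share one partner — and then
filters at p < 1e-5.

`assign_candidate_targets()` marks a gene as a candidate target iff a
high-confidence summit falls in the strand-oriented window from 3 kb
upstream of its TSS to 1 kb downstream of its TTS, gene body included (the
genic fraction of binding sites is itself a reported quantity, so the body
cannot be excluded). Coordinates are 0-based half-open internally; GFF3 is
converted at the boundary (1-based inclusive); filtering order is merge →
support → significance → window.

`peak_location_profile()` histograms nearest-summit distances to the
TSS/TTS and reports the fraction of candidate genes whose nearest summit is
within ±0.5 kb of the TSS; `genic_distribution()` classifies every summit
as upstream / genic / downstream / intergenic with precedence upstream >
genic > downstream across colliding windows and |distance-to-TSS|
tie-breaks.

# Motif scanning

`scan_pwm()` scores both strands with log2 odds against a background base
distribution (uniform by default); `N` contributes 0 bits. The default
threshold is 80% of the maximum attainable score — no published cutoff
exists for this analysis, so the conventional fraction-of-max rule is used
and is configurable. Offsets are reported for the match's 5′-most base
relative to the TSS in gene orientation. `iupac_scan()` does exact
degenerate matching (Biostrings) for consensus patterns such as YTAATYAW,
and coincides with the 0/1-matrix PWM scan at the maximum-score threshold —
a tested invariant, as is exact agreement of `scan_pwm()` with a naive
per-window rescoring oracle.

`overrepresentation_test()` replaces the original STORM-based screen with
an explicit empirical test of the same comparison: count foreground
matches, count matches in `n_bg_sets` random background sets of matched
cardinality and lengths, and report
p = (#{background ≥ observed} + 1) / (n_bg_sets + 1). The add-one keeps
p in (0, 1]; with 999 background sets the minimum is 0.001, matching the
decision threshold used for over-representation calls.

# The synthetic-data generator

`sim_config()` defaults define the study conditions used throughout the
tests and the acceptance script:

* **Annotation**: 200 protein-coding genes + 30 miRNA host genes, 1–3 kb
  long, placed on 2 chromosomes of 1.5 Mb so that every gene's
  TSS−3kb/TTS+1kb window is disjoint from its neighbours' (a 500 bp spacer
  beyond the windows); about half the genes on each strand. 40 genes are
  TF-bound.
* **ChIP**: each bound gene gets one peak per replicate; the summit is the
  planted motif position jittered by Normal(0, 50 bp) per replicate, with
  −log10 p in [12, 30]. Each replicate also gets 10 independently placed
  noise peaks with −log10 p in [2, 4.9] — they fail both the significance
  and (almost surely) the replicate-support filters, and the tests use
  thresholds rather than exact counts where collisions are conceivable.
* **Promoters**: TSS±1000 bp, i.i.d. uniform ACGT, one exact expansion of
  YTAATYAW planted at Normal(−200, 50) bp in bound promoters. The uniform
  background makes match-count expectations analytic (the per-position
  match probability of YTAATYAW is 8/4^8 per strand), which the tests
  exploit; a composition-matched background would be a config extension.
* **Expression**: planted features get |Normal(2, 0.3)| log2 fold changes
  with the sign dictated by their edge role and adjusted p far below
  α = 0.05; null features get Normal(0, 0.3) with uniform p, so ~5% are
  flagged. P-values are simulated directly rather than derived from count
  models — DE estimation is out of scope and the flag behaviour is all the
  downstream analysis consumes.
* **Loops**: 40 coherent type-IV loops, *packed* five per miRNA (the map
  size), so 8 of the 30 miRNAs carry the planted signal. Packing mirrors
  the biology being emulated — one strongly responding miRNA family with a
  whole anticorrelated target family, like miR157 with nine SPL genes —
  and it is what makes the planted excess detectable: spreading 40 loops
  over all 30 miRNAs would make essentially every miRNA significant, and a
  shuffle that permutes near-identical tuples reproduces the observed
  network, washing out the enrichment signal.
* **DE background**: 6 miRNAs (alternating up/down) and 20 genes
  (alternating) are DE outside any loop, emulating the miRNAs a real
  contrast shows in both directions (the co-expression categories I and II
  both exist in real data) and the broad TF-family response beyond miRNA
  targets. The background also keeps the permutation p-value well-defined
  for every loop type, per the strict-inequality corner above. Background
  DE genes are never used as map decoys: decoys model *non-responding*
  miRNA targets, while the DE background models responding genes that are
  not miRNA targets.

Everything is a pure function of the configuration and its seed (the RNG
state is scoped and restored), so identical configs give byte-identical
outputs; each generator stage derives an offset sub-seed so stages can be
re-run independently.

What the generator does *not* emulate: read-level data, fragment-size and
strand-shift effects in ChIP, GC and repeat structure in promoters,
correlated expression noise, miRNA families sharing targets, more than two
replicates, more than one TF. Passing tests therefore demonstrate the
correctness and calibration of the *methods* under idealized noise, not
performance on real libraries.

# miRNA co-expression categories and family summaries

`classify_mirna_category()` assigns category I to a significantly
up-regulated miRNA whose significant mapped targets are majority-down,
category II to the mirror case, and category III to a significant miRNA
whose targets are not anticorrelated. The defining rule for category III
is not published beyond its membership; "significant but not
majority-anticorrelated" is this package's modelling choice, the majority
is computed over significant targets only, and ties are not a majority.
Significance uses the adjusted p-value at α = 0.05 by default
(`use_padj = FALSE` switches to raw p; which the original analysis used is
not stated). `family_de_summary()` aggregates DE per gene family — size,
DE count, mean log2 fold change over DE members (undefined when none) and
an up/down tally.

# Numerical choices and problem sizes

* Permutation counts: 10,000 shuffles for reported p-values (the published
  resolution); tiny-network oracle comparisons use exhaustive enumeration
  (≤ 3!·4! joint permutations) and 3-binomial-SE tolerances.
* The planted-enrichment study uses 20 seeds of the default 30 × 200
  condition; null calibration uses 200 structure-free seeds (no planted
  loops, DE background retained). These sizes give the comparisons stable
  Monte-Carlo error while keeping the default test run inside a normal
  development cycle.
* Motif over-representation uses 999 background sets; background-count
  expectations are validated on 2,000 simulated promoters against the
  analytic Poisson mean within 3 SD.
* The ChIP merge is validated against an O(n²) pairwise-closure oracle on
  1,000 random peaks; window assignment against a per-base membership
  oracle.
* Degenerate inputs: empty replicates warn and return empty; empty match
  sets give all-zero histograms; a score threshold above the attainable
  maximum warns and returns no matches; a zero log2 fold change with
  significance yields no edge.

# Known limitations

* The strict-inequality p-value is anti-conservative at discrete atoms and
  degenerate (p = 0) when a sign pattern is absent from the tuple multiset;
  it is implemented as published. Interpret p for a type with observed
  count 0 with care.
* Replicate support uses summit distance only; no IDR-style reproducibility
  modelling, no input/control normalization.
* One TF, one contrast; multi-TF networks and loop types with the miRNA in
  other positions are out of scope.
* The over-representation background is uniform-random sequence, not
  genomic; with real promoters a composition- or repeat-matched background
  would be required.
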