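---
title: "Deciding between whole-genome and independent duplication by synteny and parsimony"
author: "paralogon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding between whole-genome and independent duplication by synteny and parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogon)
```

## The question

Eels carry two rhodopsin genes: a freshwater type (*fw-rho*) and a
deep-sea type (*ds-rho*), expression-switched across their catadromous
life cycle.  The two genes sit in two different genomic regions that
both resemble the single *rho* region of spotted gar, a pre-duplication
outgroup.  Two histories can produce this pattern:

1. **Single whole-genome duplication (WGD)** on the stem lineage of the
   teleosts, before eel (Elopomorpha) and arowana (Osteoglossomorpha)
   diverged, followed by lineage-specific gene losses; or
2. **Independent segmental duplications** in each lineage after their
   divergence.

`paralogon` implements the comparative-genomics procedure that separates
these: project each candidate region onto a reference gene panel, read
off which genes were retained or lost on each synteny copy, and count
the evolutionary events (duplications plus Dollo losses) each candidate
history requires.  The history requiring fewer events wins, by
parsimony.

## Data model

A `Region` is an annotated genomic interval with ordered, stranded gene
models (1-based inclusive coordinates, GFF3 convention; BED input is
converted on read).  A `PresenceOrderMatrix` records, for each
(species, synteny copy) region and each gene of a reference panel,
a state `P`/`A`/`U` (present / absent / unknown), the rank of present
genes in genomic order, and their orientation relative to the reference
copy.  Copy labels `#1`/`#2` distinguish the two paralogous regions of
each duplicated species; `#1` denotes the ancestral-collinear region
(the one that retains the genes flanking the duplicated segment).

The worked example built into the package
(`emitFixtureMatrix()`) is the 11-gene panel around *rho* on spotted-gar
linkage group 5 — *lrig1*, *slc25a26*, *magi1*, *rho*, *adamts9*,
*prickle2*, *pphln1*, *slc2a9l1*, *psmd6*, *atxn7*, *thoc7* — scored
across gar and the two synteny copies of Japanese eel and Asian
arowana.  One state is deliberately `U`: the eel copy-#2 region ends
right at *atxn7*, so the absence of the next panel gene (*thoc7*)
cannot be asserted; the matrix records it as unknown rather than
absent.

```{r fixture}
m <- emitFixtureMatrix()
m
```

## From annotations to the matrix

When starting from annotations and sequences rather than a curated
matrix, the pipeline is:

* `reciprocalBestHits()` anchors genes between regions.  Each gene pair
  is anchored when each member is the other's best local-alignment hit
  (Smith–Waterman, BLOSUM62) with identity above a threshold
  (default 40%); ties break by identity then gene id, so anchoring is
  deterministic.  At panel scale with single-copy genes this yields the
  same anchors as graph-based orthology clustering while remaining
  fully self-contained.
* `buildDotplot()` / `macrosyntenyStats()` summarize macrosynteny: one
  dot per anchor at the gene midpoints (floor of the mean of start and
  end — coordinates are integer base pairs), closed/open by
  transcriptional orientation agreement.
* `extractMicrosynteny()` projects regions onto the panel.  A panel
  gene missing from a region is normally `A`; when the boundary flag is
  on, a missing gene whose expected position (given the flanking
  present genes and the row's mapping direction) lies beyond the region
  boundary, with the flanking gene within `edgeMargin` (default
  5000 bp) of that boundary, is scored `U`.  Two anchors of one panel
  gene into one region abort with an error: that is a candidate tandem
  duplication, outside this model.

Order conservation of a row (`orderConservation()`) is the length of
the longest common subsequence between the row's present genes in
genomic order and the panel order.  It equals the number of present
genes exactly when the order is perfectly conserved; inversions change
orientation, not rank, so a strand flip alone does not reduce it.

```{r order}
orderConservation(m, "eel #1")   # 10 of the 11 panel genes
sharedLossPattern(m, c("eel", "arowana"))
```

`sharedLossPattern()` returns panel genes with an identical
(copy #1, copy #2) presence pattern in both species that records
exactly one loss.  It is restricted to the duplicated template (below):
genes outside the template are absent from copy #2 because they were
never duplicated, not because a copy was lost, so counting them as
"shared losses" would conflate non-duplication with loss.

## Scenario scoring by Dollo parsimony

`minimalDuplicatedSegment()` infers the template: the smallest
contiguous interval of the panel containing every gene seen on any
copy-#2 row.  For the worked example this is the eight genes
*magi1*..*atxn7*.

A `DuplicationScenario` places one or more duplications on branches of
a rooted species tree (a branch is named by the tip set of its clade).
`scenarioTotalEvents()` charges one event per duplication placement
plus, for every (copy lineage × template gene) column, the minimal
number of Dollo losses explaining the tip states.  A loss is
clade-wide and irreversible: one event removes the copy from an entire
descendant subtree, and a copy once lost is never regained.  The
minimum is the number of maximal present-free subtrees containing an
absent tip, computed by a post-order dynamic program; `U` states are
unconstrained and resolve in whichever direction is cheapest.  Genes
outside the template incur no events.  For the independent-duplication
scenario the same minimal template is assumed copied in each lineage —
the assumption most favorable to that scenario, so the comparison is
conservative.

```{r scenarios}
tree <- scenarioTree()
s1 <- duplicationScenario("single-WGD", list(c("eel", "arowana")))
s2 <- duplicationScenario("independent", list("eel", "arowana"))
rankScenarios(list(s1, s2), m, tree)$ranking
```

The single WGD explains the matrix with 1 duplication + 5 losses
(*pphln1* once on the ancestral copy-#1 branch; *adamts9*, *slc2a9l1*,
*psmd6* once each on the ancestral copy-#2 branch; *rho* on the arowana
copy-#2 branch), against 2 duplications + 9 losses for independent
duplications, where every ancestrally shared loss must be paid twice.
Ties in total events rank the scenario with fewer duplications first —
a genome duplication is a rarer event than a single-gene loss.  The
test suite confirms both totals against a brute-force enumeration of
all loss-branch subsets.

`dolloViolations()` performs the irreversibility audit: a gene present
on a copy-#2 row outside the scenario's template, or a duplicated-copy
row in a species that does not descend from any placement, would
require a regained gene and is reported; the worked example is clean.

## Supermatrix likelihood and RELL support

The phylogenetic layer supports the companion analysis: do the
concatenated sequences of the duplicated genes recover two mutually
monophyletic synteny clusters?

* `pruneGapSites()` removes alignment columns with gaps in more than
  half of the OTUs (a column with gaps in exactly half is kept).
* `thirdPositionTreatment()` handles fast-evolving third codon
  positions: `include` (unchanged), `ry` (A,G→R, C,T→Y, keeping
  transversion information only), or `exclude`.  RY-coded columns stay
  in the DNA alignment as IUPAC codes, which the likelihood treats as
  two-state partial information; a fully binary alignment with the
  2-state `RY` model is also available via `ryCode()`.
* `concatenateAlignments()` builds the supermatrix, matching OTUs by
  label and recording a per-column partition map.
* `siteLogLikelihoods()` computes per-site log-likelihoods by the
  pruning algorithm over compressed site patterns, for JC69 / K2P /
  HKY / TN93 / GTR, a binary RY model, Poisson amino-acid, or an
  empirical amino-acid model with a user-supplied exchangeability
  table (e.g. JTT).  Rate matrices are scaled to one expected
  substitution per unit branch length.  Among-site rate variation uses
  a discrete gamma with 4 mean-per-category rates by default; the
  shape is a config parameter (or can be profiled with any 1-D
  optimizer against `treeLogLik()`).  Gaps and ambiguity codes are
  missing data (all-ones partials).  Zero-length branches contribute an
  identity transition.
* `optimizeBranchLengths()` does coordinate-wise golden-section search
  per branch, sweeping until the log-likelihood improves by less than
  1e-6 (at most 50 sweeps); the total is non-decreasing by
  construction.
* `mlLocalRearrangementSearch()` hill-climbs over nearest-neighbor
  interchanges with branch-length re-optimization until no NNI
  improves the likelihood.  Polytomies in the start tree are resolved
  randomly under the seed, making runs reproducible.
* `rellSupport()` scores each internal branch of the ML tree against
  its two NNI alternatives by resampling estimated log-likelihoods:
  alternative branch lengths are optimized once, then bootstrap site
  weights are drawn (default 1000 replicates) and support is the
  percentage of replicates in which the ML tree's resampled total is
  strictly highest.  No re-optimization inside the bootstrap — that is
  the point of RELL.  `cladeSupport()` looks up the support of a taxon
  set's bipartition (e.g. a synteny cluster).

The test suite validates the likelihood against exhaustive summation
over interior-node states and against an independent implementation,
the search against exhaustive scoring of all 15 five-taxon topologies,
and the resampler against dominance (100%) and symmetric
(three equally supported trees, about 33%) cases.

## Selection scan

`ng86PairCounts()` implements Nei–Gojobori (1986) counting:
synonymous/nonsynonymous sites by per-codon mutation enumeration
averaged over both sequences; differences averaged over all shortest
mutational pathways between differing codons (pathways through stop
codons excluded; changes *to* stop codons count as nonsynonymous in
site counting); Jukes–Cantor multiple-hit correction
`d = -3/4·log(1 - 4p/3)`, flagged undefined when `p >= 3/4`.  Codons
containing a gap or ambiguity in either sequence are skipped.
`slidingDnds()` applies this in 25-codon windows advanced by 5 codons
for a named focal pair (e.g. the two eel *rho* copies), keeping a final
partial window of at least half a window.  `maskWindows()` removes
every codon column covered by a window whose ratio exceeds a threshold
(the threshold is analysis-specific and deliberately has no default),
falling back to a dN quantile for windows where dS is zero.

A caution the tests make explicit: the per-window ratio has few
synonymous counts in its denominator, so the *mean of window ratios* on
neutral data is noisy and upward-biased at low divergence.  The
package's neutrality check therefore pools windows over ten replicate
1000-codon alignments at 1 substitution/codon, where the pooled mean is
stably near 1.

## The simulator

`simulateWgdDataset()` generates datasets with the structure the
analysis assumes, plus truth labels: an ancestral segment of
`panelSize` genes (default 11, matching the worked example) on a rooted
species tree (default `figTeleostTree()`, gar outgroup and four
teleosts); one WGD on a configured branch (default: the teleost stem)
or independent duplications; per-branch per-gene copy losses below the
duplication (Bernoulli, default 0.2 — of the order implied by the
observed matrix, where 5 of 16 duplicated gene copies were lost across
two lineages); occasional contiguous inversions (default probability
0.1 per branch) that reverse gene order and strands; intergenic
spacing uniform on 2–20 kb and lognormal gene lengths (median 250
codons) — only midpoints and order matter downstream.  Sequences evolve
by an HKY process (default), by a 61-state GY94-style codon model with
per-gene omega (no stop codons, used for selection-scan tests), or not
at all (`sequences = "none"`, for fast presence/order studies).  One
global seed drives a single generator stream, so equal seeds give
identical datasets.

What the simulator does *not* emulate: assembly fragmentation, tandem
arrays, introns, transposition, gene conversion between copies, and
rate heterogeneity along the genome.  Passing recovery tests on these
simulations therefore shows the inference machinery is correct under
its own model, not that real assemblies are this clean — the
edge-unknown mechanism exists precisely because real scaffolds
truncate.

Recovery behaves as the parsimony argument predicts: when the truth is
a single WGD, the independent-duplication scenario can never score
fewer events on the same template (every ancestrally shared loss costs
it double, and it pays an extra duplication), so `rankScenarios()`
recovers the generating scenario essentially always; the test suite
requires at least 90% over 100 replicates at loss probability 0.3.

## Numerical and design choices

* Coordinates are 1-based inclusive internally; BED converts on read.
  Unstranded features are rejected — orientation agreement is a core
  statistic.
* The gene-model length filter keeps a prediction when
  `|len_pred − len_ref| / len_ref < 0.05`, strictly: exactly 5%
  difference is rejected.  Marker-based linkage assignment applies the
  identity threshold (default ≥ 90%) before the unique-hit rule, drops
  markers hitting two or more scaffolds, and flags scaffolds named by
  two or more linkage groups as `split-required`.
* RBH ties break by score, then identity, then lexicographic id.
* Problem sizes in the test suite are desk-scale by design: trees of
  3–7 taxa, alignments of 10–1000 columns, 100–200 randomized oracle
  instances per property; the exhaustive oracles (loss-branch subsets,
  interior-state summation, all 15 five-taxon topologies) are only
  feasible at that scale, which is exactly what makes them trustworthy.
* Branch-length optimization bounds branches at 10
  substitutions/site; `optimize()` tolerance 1e-7 on the branch, 1e-6
  log-likelihood units per sweep.
* `cladeSupport()` returns `NA` (with a message) for a taxon set whose
  bipartition is absent, keeping a stable numeric return type.

## Limitations

The scenario machinery compares user-supplied candidate placements; it
does not search all branches (the biological question is a comparison
of two named histories).  The selection scan is the classical counting
method, not a codon-model likelihood; it supports the
"is tree skewness driven by selected sites?" robustness check, not
formal tests of positive selection.  Real-data genome-scale numbers
(scaffold counts, genome-wide ortholog tallies, printed branch-support
averages) depend on external sequencing data and are outside the
package's scope.
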