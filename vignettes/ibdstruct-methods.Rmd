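---
title: "Population structure, ancestry and kinship from IBD sharing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure, ancestry and kinship from IBD sharing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdstruct)
```

# Scope and model

`ibdstruct` analyses cohorts of diploid genomes through the lens of pairwise
identity-by-descent (IBD): genomic segments co-inherited from a recent common
ancestor. For large imputed ancient-DNA cohorts, IBD sharing is a more
recent-history-sensitive signal than allele-frequency methods, and it supports
a family of analyses with almost no modelling assumptions beyond the segment
calls themselves:

* **segment QC** — length/LOD filtering and removal of regions of
  artefactually excessive IBD;
* **population structure** — community detection on the weighted network of
  genome fractions shared IBD;
* **supervised ancestry** — leave-one-out "painting" of each target against
  donor groups, then constrained least-squares mixture fits;
* **kinship** — allele-frequency-free classification of pair relationships
  from joint genotype counts;
* **ROH / UPD** — runs of homozygosity as evidence of recent parental
  relatedness, and whole-chromosome homozygosity as a uniparental-disomy
  signal;
* **haplogroup calls** — from phylogenetic placement weights on an annotated
  reference tree.

The pipeline starts at IBD segments and genotypes; read alignment, imputation
and contamination estimation are out of scope.

All genetic lengths flow through a `GenomeMap`: piecewise-linear anchors
between physical (bp) and genetic (cM) coordinates. Coordinates are 0-based
half-open internally; positions beyond the anchored range are an error rather
than extrapolated, so segment lengths can never be silently inflated.
Haplotype-level segment rows between the same diploid pair are kept distinct
on input; de-duplication happens only where it matters (the sharing matrix
takes a per-pair union before summing).

# Segment QC

Segments are kept iff LOD ≥ 3 **and** length ≥ 2 cM (both inclusive, matching
the printed operators of the filtering convention). ROH analyses and
fine-scale clustering use a 1 cM minimum instead (`mode` argument).

Excess-IBD regions — artefacts of imputation panels and low-complexity
regions — are detected by counting, at every genomic position, the long
(> 10 cM, strict) segments covering it. The per-position counts are
summarized by a **trimmed mean m and trimmed s.d. s**, and every maximal run
of positions with count strictly above `m + 10·s` is flagged; any segment
overlapping a flagged region by at least one base is removed. Design choices
here that the method description leaves open:

* "3 % trimmed" removes 3 % of *mass from each tail* (the convention of the
  common trimmed-mean implementations); configurable.
* The statistic is computed genome-wide over all autosomes; a per-chromosome
  option exists.
* Trimming, means and s.d. are computed *exactly* on bp-length-weighted
  run-length-encoded counts (via `GenomicRanges::coverage`), not on binned
  approximations; partial intervals at the trim boundary contribute their
  remaining mass.
* Excess is one-sided: unusually IBD-poor regions are not artefacts to remove.

A constant coverage profile therefore never produces a region (s = 0 and the
inequality is strict), and the implementation is tested for exact agreement
with a brute-force per-base oracle on random toy genomes.

# Sharing matrix and hierarchical clustering

The sharing matrix entry for a pair is the union-merged cM total of their
segments divided by the total map length, clipped to [0, 1]; HBD rows are
excluded, the diagonal is zero. The weighted network has an edge wherever the
fraction is positive.

Clustering follows an iterative schedule: Leiden community detection at
resolution r = 0.5; if more than one community is found the network is split
and each subnetwork is re-clustered with the resolution reset to 0.5; if not,
r is incremented by 0.5 up to r = 3, after which the node becomes a leaf. The
objective is modularity with a resolution parameter (CPM is available); runs
are deterministic given the seed, with community order fixed by smallest
member ID.

**Split acceptance.** The schedule needs a termination criterion beyond "more
than one community was returned": under a resolution-scaled modularity
objective, *any* graph is eventually split at high enough resolution — at
r ≥ 2 even a uniform-weight clique is cut into singletons, which is a
statement about the resolution penalty, not about structure in the data. We
therefore gate every candidate split with a null-model test: the split's
plain (γ = 1) weighted modularity must exceed the best modularity that the
same Leiden procedure attains on each of 59 degree-preserving rewired,
weight-shuffled null graphs. Genuine structure passes the gate easily
(observed modularity far above every null); splits manufactured by the
resolution penalty fail it, so homogeneous communities terminate as leaves.
Raising the resolution retains its intended role — escaping the resolution
limit to find small, dense subcommunities. The literal behaviour is available
with `split_test = "none"`.

On planted partitions (4 groups × 15 individuals, within-pair segment rate
λ_in = 6 against λ_out = 0.3, the package's default simulation conditions)
the leaf-level partition attains a median adjusted Rand index of 1.0 against
truth over 20 seeds.

The manual curation that turns a deep hierarchy into interpretable clusters
is approximated by an explicit, deterministic rule: sibling leaves merge when
they share a region annotation and their members' age ranges are within
1,000 years (transitively within a sibling set, never across parents). The
rule is configuration, logged, and intentionally crude — it stands in for
expert curation, not for a statistical claim.

Two descriptive summaries mirror common presentations of such data: per-period
networks keeping each individual's top 10 sharing partners (ties at rank k
broken by partner ID), and per-cluster timelines of mean pairwise sharing per
time bin (bins with fewer than two members are reported as missing, not
zero).

# Painting profiles and supervised ancestry

A target's painting profile is the vector of total cM shared with each donor
group, normalized to sum to 1. The recipient is excluded from its own group
(leave-one-out) but other members of its group still act as donors. Per-
chromosome totals are retained because the jackknife needs them. A target
sharing nothing with any donor has *no* profile; it is reported and dropped,
never imputed as zeros. Source-group profiles are the mean of member
profiles (a pooled-total variant is a one-line change via `paintingTotals`);
donor groups for ancient cohorts are the collapsed clusters, for modern
cohorts the metadata labels.

The mixture fit solves

$$\min_w \; \lVert S w - p \rVert_2 \quad \text{s.t.}\; w \ge 0,\; \textstyle\sum_i w_i = 1$$

with the sum-to-one condition as a **hard equality constraint**, not a
post-hoc renormalization — this matches the mixture interpretation and makes
the delete-one jackknife well defined. The solver enumerates candidate
support sets and solves each equality-constrained KKT system exactly, keeping
the feasible solution with the smallest residual; for the panel sizes used in
supervised modelling (≤ 15 sources) this is exact and fast, and it is tested
against a 0.01-step simplex grid search.

Standard errors come from a weighted block jackknife leaving out each
chromosome in turn: target and source profiles are rebuilt without the
chromosome, re-fit, and combined with block weights proportional to the
deleted chromosome's cM length using the standard weighted delete-one
variance formula (which reduces to the classic jackknife for equal-length
blocks). On synthetic cohorts with independent per-chromosome noise the mean
jackknife SE sits within a few percent of the Monte-Carlo s.d. of the
estimates (ratio ≈ 0.95–1.02 in the shipped acceptance runs; the package
asserts agreement within a factor 1.5).

# Kinship

For each pair, the 3×3 joint genotype-dosage table over doubly non-missing
sites yields, with O = opposing homozygotes, H = double heterozygotes, D =
all discordant pairs and het_i, het_j the per-individual heterozygote totals:

$$R0 = O/H,\qquad R1 = H/D,\qquad \widehat{\text{KING}} = \frac{H - 2O}{het_i + het_j}.$$

The underlying method description names R0 and R1 without printing formulas;
these ratio definitions follow the allele-frequency-free estimator family
they come from, and the package treats the prescribed self-consistency check
as the arbiter: under gene-dropped pedigrees with founder MAF ~ U(0.05, 0.5),
simulated parent–offspring pairs satisfy R0 ≤ 0.02 and 0.4 ≤ R1 ≤ 0.6 in
100/100 seeded replicates, duplicates give KING = 0.5 and R0 = 0 exactly, and
full siblings separate from parent–offspring through R0 > 0.02.

Degrees use the established KING-robust powers-of-two cut-offs
(2^{-3/2} … 2^{-9/2}); pairs with fewer than 20,000 contributing sites are
excluded, first-degree pairs are split into parent–offspring by the R0/R1
window above. All boundary comparisons implement the printed operators
literally and are unit-tested at the boundary. The estimators here are
computed from hard diploid genotype counts; the original genotype-likelihood
(2D-SFS) route belongs to the upstream toolchain and is out of scope — the
downstream classification rules are identical.

Within each first- or second-degree pair the lower-coverage member receives a
`1d_rel`/`2d_rel` flag (coverage ties broken by sample ID), which feeds the
sample-level QC verdicts (`contMT5pct`, `contNuc5pct` for contamination > 5 %,
`lowcov` for coverage < 0.1×, `lowGpAvg` for mean genotype probability
< 0.98). The flag vocabulary is closed so downstream filtering is exact.

# ROH and uniparental disomy

An individual is flagged for recent parental relatedness when more than
50 cM of its genome lies in ROH segments each longer than 20 cM (both
strict). UPD screening flags a chromosome whose ROH covers at least 90 % of
its genetic length while the ROH total elsewhere stays below 50 cM. The
50/20 cM rule follows the established criterion; the 0.9/50 UPD thresholds
are this package's operationalization of a qualitative observation
(whole-chromosome homozygosity without genome-wide ROH) and are labelled
heuristics, exposed as arguments.

# Haplogroup calling

Each branch of a rooted reference tree resolves to a haplogroup label,
inheriting rootward where annotations are sparse. Placement weights are
accumulated over subtrees, and the call is the label of the **deepest**
branch accumulating at least 99 % of the weight (inclusive). Read literally,
a "most basal" branch accumulating the weight would always be the root —
the root accumulates 100 % by construction — so the rule is implemented as
the informative deepest-qualifying-branch inversion; this reading is
deliberate and documented rather than asserted as anyone's intent. Since two
disjoint subtrees cannot both hold ≥ 99 % of a unit weight, qualifying
branches always form a root path and the call is unique; accumulation is
monotone toward the root, and raising the threshold can only move calls
rootward.

# Synthetic cohorts: what they emulate and what they do not

Every stage is validated on generators that plant known truth:

* `simulateGroupIBD` — pairwise segment *counts* are Poisson (λ_in = 6
  within groups, λ_out = 0.3 between, the defaults used throughout the
  package's validation), segment lengths exponential with mean 3 cM
  truncated at the 2 cM QC minimum (the pipeline only ever sees
  post-threshold segments), positions uniform on the map, LOD drawn above
  the passing threshold. Admixed targets share with group g at rate
  w_g·λ_in, so their expected painting profile *is* the mixture vector and
  NNLS truth is exact by construction — deliberately generated at the
  IBD-rate level rather than by coalescent simulation.
* `simulatePedigreeCohort` — gene-dropping with Poisson crossovers on the cM
  map; founder MAF uniform on [0.05, 0.5], mimicking a MAF ≥ 0.05 site
  ascertainment. True IBD tracts are recorded from transmitted founder
  haplotypes. Second/third degree are realized as half-siblings and first
  cousins.
* `simulateROHFixtures` and `simulatePlacements` — planted ROH/UPD segments
  and placement-weight scenarios whose truth labels are computed by
  independent code paths (planted lengths; brute-force subtree sums).

These generators reproduce the *statistical structure the methods assume*,
not demographic realism: no LD beyond pedigree linkage, no imputation error,
no age-dependent segment-length decay, no spatial autocorrelation. Passing
tests demonstrate that the machinery recovers truth when its assumptions
hold; they do not certify behaviour on data violating them (e.g. contaminated
or badly imputed genomes).

Default problem sizes — 60 grouped individuals + 6 targets for the demo
cohort, 100,000 sites for kinship replicates, 20 seeds for clustering
recovery, 200 Monte-Carlo replicates for jackknife calibration — were chosen
as the smallest sizes at which the sampling error of each check is well below
its decision threshold.

# Numerical conventions

* Profile and proportion vectors are held to their normalization invariants
  at 1e-9/1e-8; the NNLS support enumeration clamps components below 1e-9.
* Interpolation inverse (`cmToBp`) returns the left-most bp of flat cM
  stretches.
* Leiden runs fix the RNG seed and 5 iterations; community and tie order is
  by smallest member ID; per-node seeds derive deterministically from the
  global seed.
* The pipeline writes every output with `#`-prefixed headers and no
  timestamps, so a rerun with the same config is byte-identical.

# Known limitations

* The collapse rule is a caricature of expert curation; real analyses will
  want their own rule or manual post-processing.
* The excess-IBD threshold assumes a unimodal background; cohorts dominated
  by close relatives violate it.
* The kinship estimators assume hard genotypes; at very low coverage the
  upstream genotype-likelihood route is preferable.
* UPD screening cannot distinguish isodisomy from long terminal ROH on
  acrocentric-like maps; it is a screen, not a diagnosis.
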