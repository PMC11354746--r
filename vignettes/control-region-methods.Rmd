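---
title: "Methods: control-region variability, diversity decomposition and haplotype networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: control-region variability, diversity decomposition and haplotype networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crhaplo)
```

`crhaplo` implements the descriptive population-genetic toolkit used in
mitochondrial control-region (CR) phylogeography: from an aligned FASTA and
a sample-to-population table it produces haplotype sets, site-variability
profiles, distance and diversity tables with bootstrap errors, clock-based
divergence times, and median-joining haplotype networks. This vignette
explains each model, the parameters that matter, and the design choices
made where the methodology is genuinely open.

## Sequence model and data hygiene

All analyses operate on equal-length sequences over the IUPAC alphabet.
Three rules keep artefacts of direct Sanger sequencing of mtDNA out of the
statistics:

* **Haplotype identity** defaults to strict byte identity on the aligned
  string, gaps included. The alternative `ignore-missing` rule merges
  sequences that agree wherever both are unambiguous; it is greedy
  (first-seen representative), which is the conventional behaviour but
  makes merging order-dependent when partial sequences chain — one reason
  strict identity is the default.
* **Ambiguity resolution** (`resolve_ambiguities`) replaces IUPAC codes by
  the majority unambiguous base of their column, optionally restricted to
  parsimony-informative sites. Ties go to the lexicographically smallest
  base and are logged; a logged deterministic tie-break was preferred over
  random or frequency-weighted choices because it is reproducible and
  auditable.
* **NUMT double peaks** (`apply_numt_policy`) follow a three-branch
  decision: keep the alternative states (only by explicit per-record
  override, since "no phylogenetic contradiction" is a judgement external
  to this package), resolve toward a matching known haplotype, or drop the
  record (no match, or more than `max_ambiguous = 3` annotated sites). The
  threshold formalises "more complex cases"; it is configurable because no
  principled universal value exists.

Distance comparisons between lineages use **unique haplotypes** (repeated
sampling of a common haplotype would deflate means), while nucleotide
diversity uses **all samples** (haplotype frequencies are the signal).
When a haplotype's members span groups, the haplotype inherits the
majority group — a situation that real introgressed samples do create; the
assignment is deliberate and visible in the haplotype table.

## Site statistics

A site is *segregating* (S) when ≥ 2 distinct unambiguous bases occur
among its non-missing characters, and *parsimony-informative* (PIS) when
≥ 2 bases each occur in ≥ 2 sequences. Gaps, `N` and ambiguity codes never
make a site segregating: indels in CR homopolymer tracts would otherwise
dominate S. The sliding-window profile counts segregating sites in windows
of `window = 40` bp advanced by `step = 1` bp — defaults sized to CR
conserved sequence blocks (CSBs), which are tens of bp long.

Conserved-block detection is an explicit heuristic: maximal runs of
windows with Ss at or below a threshold (default the 25th percentile of
the profile), reported as bp spans of at least `min_block = 20` bp.
Published CSB annotations are drawn by eye; the detector recovers planted
blocks exactly in simulation but on real data its output should be read as
candidate spans, not boundaries. Note the geometry: a window can only
reach Ss = 0 if it fits inside the conserved span, so blocks shorter than
the window are detectable only by lowering `window` or raising the
threshold.

## Distances

`pair_counts` excludes, per pair, every site where either sequence is not
a plain base (pairwise deletion — the default because real CR fragments
differ slightly in usable length per sample; complete deletion is offered
for cross-checks against matrix-wide tools). Transitions are A↔G and C↔T.
The G+C fraction θ is estimated per pair over the compared sites of both
sequences rather than once per alignment: with pairwise deletion the
compared site set differs by pair, and a per-pair θ keeps the estimator
self-consistent (the package's values coincide with the common
whole-alignment convention whenever the site sets coincide).

The Tamura 3-parameter distance
d = −h·ln(1 − P/h − Q) − ½(1 − h)·ln(1 − 2Q), h = 2θ(1−θ),
assumes equal rates among sites (no gamma heterogeneity — deliberately,
matching the convention of the tables this package reproduces). When the
log arguments are non-positive the pair is *saturated*: it is excluded
from group means with a warning and a count, rather than silently clamped,
because clamping would bias means downward exactly where the correction
matters most.

Bootstrap standard errors resample alignment **columns** with replacement
(the sites are the exchangeable unit for a fixed set of individuals),
with 100 replicates by default and a mandatory seed. The SE is the
standard deviation across replicate statistics; replicates where the
statistic is undefined are dropped, and more than 50 % undefined is an
error rather than a quietly noisier estimate.

## Diversity decomposition

π is the mean pairwise p-distance over all n(n−1)/2 sample pairs. The
decomposition uses **equal group weights** w = 1/s: π_S is the unweighted
mean of group diversities and π_T = Σ w² π_ij with π_ii = π_i. Equal
weighting (rather than sample-size weighting) is pinned by an in-package
check: the published worked value π_S = 0.25 arises from group diversities
0.17 and 0.32 measured on samples of 23 and 9 — only the unweighted mean
reproduces it (sample-size weights give ≈ 0.21). δ_ST = π_T − π_S and
N_ST = δ_ST/π_T hold as identities on every output. Diversities are
reported ×100, N_ST as a percent. π is p-distance-based (a T3P-based π
would inflate the small within-population values the method targets and
does not match the convention of the tables reproduced); note that with
π_ij the *mean* cross-group distance, δ_ST can be slightly negative in
small samples when within-group pairs happen to be more divergent than
cross pairs — this is a property of the estimator, not a bug.

## Molecular clock

time (ka) = 1000·d(%)/rate(%/My), SE propagated linearly. The default
rate 3.54 %/My is a COI calibration from biogeographically dated beetle
lineages, widely transferred across insect mtDNA studies; it is an
explicit parameter because transferring it to the CR assumes the two
markers share a rate at the depth studied — exactly the assumption the
rate-ratio diagnostic k = d_CR/d_COI interrogates (k rising with depth
indicates saturation of the slower marker, and times computed from it are
then underestimates).

## Median-joining networks

`build_mjn` follows the classic scheme: (1) Hamming distances between
haplotypes over variable sites; (2) the ε-relaxed minimum spanning
network — an edge of weight w enters iff its endpoints are not already
connected by kept edges of weight < w − ε, so at ε = 0 the network is the
union of all minimum spanning trees; (3) for every triplet sharing a
common network neighbour, quasi-median vectors (majority per site; all
three states branch where the triplet disagrees three ways) are generated,
and the new vectors whose connection cost is within ε of the minimum are
added; (4) repeat to a fixed point; (5) prune median vectors and links not
on any minimal path between observed haplotypes.

Defaults and guards: ε = 0 (sparsest network, the common default when a
study does not state ε); all sites weighted equally; lexicographic
ordering of node sequences everywhere ties could arise, making output
independent of input order; a cap of 10 000 quasi-median candidates per
triplet (exceeded caps are a hard error — a network that needs more is
better built on a partitioned data set); a sweep cap of 25 iterations.
Ambiguities must be resolved before construction — the builder rejects
nothing silently, but medians of ambiguous states are not defined.
Group separation is the minimum weighted shortest-path length between two
node sets, matching how "substitutions separating clades" are annotated
on published networks.

## The simulator: what it emulates, and what it does not

`simulate_alignment` evolves sequences under the reversible 4-state chain
that the T3P distance inverts: stationary frequencies gc/2 (G, C) and
(1−gc)/2 (A, T), transitions scaled by κ, rate-normalised so branch
lengths are expected substitutions per site. Defaults are chosen to mimic
a gomphocerine CR fragment: length 691 bp, A+T = 84.6 % (θ_gc = 0.154),
κ = 4 (a typical insect mtDNA transition bias; the exact value only
shapes P/Q ratios, not the validity of the recovery tests), within-group
divergence 0.004 and between-group 0.05 (intraspecific versus
between-lineage scales of the tables reproduced), star genealogies
(the shallow-haplogroup topology the method's source material shows).
Branch lengths are solved from the targets — root→ancestor
(between−within)/2, ancestor→tip within/2 — so expected tip-to-tip
divergences equal the configured values exactly, which is what makes
parameter recovery a well-posed oracle. `simulate_cr_structure` plants
mutation-suppressed conserved blocks and a poly-T stretch (7–11 bp,
flanked by purines) on an A+T-rich background for detector round trips.

What it does **not** emulate: coalescent genealogies with recombination or
demography, indel evolution (alignments are gap-free), rate heterogeneity
among sites, length-polymorphic homopolymers, or sequencing error/NUMT
noise. Passing tests therefore certify the estimators against their own
model assumptions and the bookkeeping around them — not robustness to
alignment error or heterotachy on real data.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: single-sequence classification, groups of
one in decompositions, empty comparable site sets, zero rates, saturated
pairs, unresolvable consensus columns. Determinism is end-to-end: every
stochastic function takes a seed, and seeded runs are byte-identical.

The validation suite runs at deliberately modest sizes — pairs of 10 kb
sequences for distance recovery (analytic-SE scale ~0.2–0.4 % of the
distance), 2 × 8 samples × 3 kb for N_ST recovery with 60–100 bootstrap
replicates, ≤ 6 haplotypes for brute-force MST enumeration, 728 bp for
structural round trips — sizes at which the oracles (closed forms, brute
force, delta-method SEs) are exact or near-exact while the whole suite
stays fast.

## Known limitations

* The `ignore-missing` collapse rule is greedy and order-dependent in
  pathological chains of partial sequences.
* N_ST is a diversity-based differentiation coefficient; no
  haplotype-frequency statistics (F_ST, Tajima's D, mismatch
  distributions) are provided.
* The MJ construction is exact but unoptimised R; hundreds of haplotypes
  with many incompatibilities will be slow (the candidate cap exists to
  fail fast rather than thrash).
* Clock times inherit every caveat of the rate: non-clocklike markers at
  depth (visible as drifting k) bias times, and the linear SE propagation
  ignores rate uncertainty, which usually dominates.
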