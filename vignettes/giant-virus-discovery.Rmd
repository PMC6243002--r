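---
title: "Methods: marker screening, diversity statistics and the mini-metagenomics simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker screening, diversity statistics and the mini-metagenomics simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvpipe)
```

# The problem

Nucleocytoplasmic large DNA viruses (NCLDV, "giant viruses") occur in soil at
relative abundances so low that bulk shotgun sequencing rarely assembles
them. With total yield $Y$ bases, a genome of length $L$ at relative (base)
abundance $a$ has expected bulk coverage $aY/L$; below roughly $2\times$,
assembly and binning fail. Mini-metagenomics changes the denominator: pools
of 100 fluorescence-sorted particles are amplified by multiple displacement
amplification (MDA) and sequenced individually, so a single sorted virion
already represents about 1% of its pool. `gvpipe` implements the decision
logic and statistics of this workflow; it deliberately consumes the *outputs*
of standard tools (HMM searches, ANI estimators, aligners, orthology
inference, tree builders) rather than re-running them.

# Marker screening

Bins are profiled against a set of 20 ancestral NCVOG marker families. A bin
is a candidate giant virus when it has **more than five distinct markers**
(strictly $>5$; five does not pass) **and/or carries the major capsid
protein** (MCP, NCVOG0022). We read "different hits" as distinct marker
identities rather than raw hit rows, because the phrase contrasts with copy
number and the completeness estimate is likewise defined over distinct
markers; `count_mode = "rows"` selects the alternative reading. Completeness
is `distinct ancestral markers / 20`. Bins with fewer than three of the five
core markers are gated out of phylogenomics: concatenated-alignment positions
for such bins would be mostly gaps.

The screening e-value cutoff defaults to `1e-6`. No cutoff is published for
the screening step itself; we borrow the MCP survey's cutoff, which was
calibrated against ~60,000 non-NCLDV genomes, and expose it in `gv_config()`.
Hit tables are collapsed to the best record per (protein, marker) pair by
lowest e-value, comparing on the log10 scale with exact ties broken by the
higher bitscore — comparing raw doubles near 1e-300 invites floating-point
trouble. Bin membership travels through an explicit contig-to-bin map (the
contig of a protein is its id with the trailing `_<gene index>` stripped, the
prodigal convention); binning tools differ too much in naming for id parsing
to be reliable.

The 20-marker set itself is curated elsewhere and only six members are fixed
by their role here (MCP + five core markers); `marker_definition()` therefore
treats the remaining 14 as configurable labels. The MCP is counted inside the
20 and also tracked separately, because the candidate rule applies it as an
independent condition.

# ANI dereplication

Genomes are clustered at ANI $\ge 95\%$ with $\ge 100$ kb aligned.
Asymmetric estimates (A→B ≠ B→A) are symmetrized by the arithmetic mean of
the two ANI values and the minimum of the aligned bases; both threshold
comparisons are inclusive, taking the "at least" wording of the aligned
fraction as the house style for thresholds. "100 kb-aligned fraction" is read
as absolute aligned bases, not a percentage of genome length. Clusters are
the connected components of the thresholded graph (single linkage) — the
simplest rule consistent with "clusters and singletons"; a greedy
longest-first centroid mode is available for sensitivity checks
(`method = "greedy"`). Representatives are the longest member, ties to the
lexicographically smallest id.

# Phylogenetic diversity

PD is the sum of branch lengths; it is invariant under re-rooting. Alignment
columns with less than 10% sequence information (non-gap characters) are
trimmed before tree building. The published procedure also removed "columns
with low information content" without naming a parameter; we implement an
optional secondary rule (drop columns whose modal non-gap residue frequency
falls below a threshold) that is **off by default**, so the documented
primary rule is exactly the quoted one.

The PD gain of novel taxa is
$100\,(PD_{with}-PD_{without})/PD_{without}$. Because "trees with and
without" can mean either one tree pruned or two independent inferences, both
modes exist: pruning (default, testable against the generator's recorded
values — `ape::drop.tip` collapses unifurcations and sums branch lengths
through them) and a two-tree mode that accepts an independently inferred
reduced tree. We do not assert which mode produced the published figures.

Taxonomy transfer walks from each query leaf toward the root to the smallest
clade containing at least one labeled reference leaf; a single shared label
is assigned, a mixed clade leaves the query unassigned — mirroring how MCP
sequences are classified by their nearest labeled neighbors, with
unassignable queries reported as such rather than forced.

# The MCP survey cascade

Four stages in the published order: e-value $\le 10^{-6}$; greedy
longest-first clustering at 95% identity (the semantics cd-hit's result
depends on, without its word-filter heuristics — identities come from a
caller-supplied function or matrix); removal of proteins that have database
hits but no NCLDV MCP within the top 10 (proteins with *no* hits are kept —
only "proteins which had hits" can be excluded; ranking is by bitscore by
default, by e-value as an option, since the original ranking criterion is
not stated); and removal of proteins with fewer than 50 aligned amino acids
after column trimming (exactly 50 is kept). Stages annotate rather than
delete — every record keeps a `dropped_at` stage tag — which makes survivor
sets provably nested and the cascade idempotent.

Fraction accounting splits bulk contigs at 1 kb. A contig of exactly
1,000 bp falls in the short class (the boundary is undefined in the source;
we count strictly greater as ">1 kb" and flag the equal cases). The share of
unbinned survivors is computed among metagenome-derived records
(MAG + bulk-unbinned), and survivors on contigs with read coverage below 2
are counted separately — the signature of extremely low-abundance viruses.

# The gene-sharing network

For genomes $x \in \{a,b\}$ with total protein counts $T_x$, let $S_x$ be
the number of $x$'s proteins (paralogs included — the rule says "percentage
of proteins", not "of groups") in orthogroups shared by both genomes. The
edge weight is $\tfrac12(100\,S_a/T_a + 100\,S_b/T_b)$, i.e. the mean of the
two per-genome percentages; a union-based alternative
($100(S_a+S_b)/(T_a+T_b)$) sits behind `mode = "union"`. Edges below 18% are
filtered (inclusive boundary); isolated genomes remain in the node set,
since a completely disconnected genome is itself a finding. Totals are an
explicit input column because the normalization denominator used by
orthology pipelines (gene calls vs clustered proteins) varies; taxon
exclusions (e.g. an over-represented block of poxviruses) are a generic
exclude list, not hard-coded taxa.

# The mini-metagenomics simulator

Sorted pools are multinomial draws of `pool_size = 100` particles from the
community's **particle** abundance vector. The pipeline converts base
abundances to particle abundances as $a_i/L_i$ renormalized, since sorting
counts capsids and cells, not bases — this is why mini-metagenomics enriches
small genomes. With probability `clump_prob` per pool a "vacuole" clumping
event delivers `clump_copies` clonal copies of one eligible virus, chosen
uniformly by abundance among the eligible set, displacing randomly chosen
particles so the pool size is preserved. The quantitative counterpart of the
vacuole argument is `clonal_copy_probability(p, n) =`
$1-(1-p)^n - np(1-p)^{n-1}$: under the binomial marginal of the pool draw, a
species at abundance $p=0.01$ has probability ≈ 0.26 of appearing twice in
one 100-particle pool, and far less at realistic viral abundances
($p \sim 10^{-4}$: $\approx 5\times10^{-5}$) — so repeated clonal genomes in
one pool point to vacuole delivery, not chance. The binomial marginal is
exact for two species and an accurate stand-in for rare components of the
multinomial.

MDA bias is modeled as an i.i.d. lognormal$(0,\sigma)$ amplification factor
per particle, summed per genome, with the pool's total yield distributed
proportionally and converted to coverage by genome length
($\sum_g d_g L_g =$ `total_yield` exactly; $\sigma = 0$ gives factors
identically 1). The bias has no sequence-position structure because the
workflow uses it only as the reason coverage is uninformative for binning;
$\sigma$ defaults to 1.0, which yields the order-of-magnitude coverage
spreads typical of MDA. Contig QC trims 200 bp from each end, then discards
contigs below 2 kb post-trim length or 2× coverage (both keep-side
comparisons inclusive).

Read simulation and assembly are out of scope, so the mock benchmark emits
contigs per (pool, genome) directly and chimeras are *injected* at a
configurable rate (default 0, matching the observed absence of chimeras in
the benchmarking experiments), not emergent. Two preset designs mirror the
published benchmarks: 59 ten-cell sorts of a five-isolate bacterial mock
(`mock5`) and a twelve-giant-virus community (`gv12`).

# The synthetic community

`generate_community()` plants `n_ncldv = 12` viruses among
`n_cellular = 60` cellular genomes. Rare viruses draw expected bulk
coverages uniformly in (0.05, 0.9)× — below the assembly floor — and one
designated virus sits at 9×, reproducing the regime in which exactly one
giant virus is discoverable from bulk data. That abundant virus always
receives a complete marker complement, mirroring the fact that the one
bulk-recovered genome was a near-complete, screen-detectable MAG; the
remaining viruses draw complete / partial / sub-threshold complements at
0.3 / 0.5 / 0.2, where sub-threshold genomes (≤5 markers, <3 core, no MCP)
are invisible to the candidate rule by construction. Marker copy numbers are
1 + truncated geometric with mean ≈ 1.3, mimicking paralog expansions.
Orthogroup membership probability decays geometrically with lineage distance
(0.8 within lineage, ×0.35 per step), which makes within-lineage edge
weights exceed cross-lineage weights in expectation — a property the tests
assert over seeds. All sub-generators draw from independent named seed
streams, so the whole truth object is reproducible bit-for-bit from one
integer seed.

What the generator does **not** emulate: sequence evolution (markers are
labels, not sequences), read-level error, emergent chimerism, uneven
sorting efficiency across particle types, and database incompleteness.
Passing tests therefore demonstrate the correctness of the decision logic
and statistics under the stated stochastic model, not the behavior of HMM
searches or assemblers on real reads.

# Pipeline, problem sizes and determinism

`run_pipeline()` chains simulate → screen → derep → pd → network →
mcp-survey → benchmark. Each stage writes a JSON manifest with input and
output content digests, the config digest and the seed; a stage whose
outputs exist with unchanged input digests is skipped, so deleting one
stage's output re-executes only that stage and anything depending on it.
Tabular outputs carry a `# stage=... config=... seed=...` provenance header.

Default problem sizes were chosen so a full run completes in seconds on one
CPU while keeping the statistics meaningful: 72 genomes, 360 pools of 100
particles (four samples of 90 sorts), a ~150-group orthogroup table, 10,000
pools for the calibration checks and 200 random graphs for the clustering
oracle. The bulk yield constant (`5e10` bases) only sets the scale linking
abundance to expected coverage.

# Known limitations

* ANI, identities and orthogroups are consumed as tables; there is no
  sequence-level computation of any of them.
* The greedy 95% clustering reproduces cd-hit's greedy longest-first
  semantics but not its alignment heuristics; with a different identity
  function, cluster counts can differ from cd-hit's.
* The published PD gains for real data depend on the deposited reference
  trees; `pd_increase()` reproduces the statistic given those trees but the
  package does not download them.
* `benchmark_mock`'s recovered fractions cap at 1 and ignore overlap between
  contigs attributed to the same genome.
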