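---
title: "Methods: comparative analysis of quadripartite plastid genomes"
author: "plastomeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of quadripartite plastid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomeR)
```

# Scope

plastomeR implements a comparative analysis workflow for chloroplast
(plastid) genomes with the canonical quadripartite architecture: a large and
a small single-copy region (LSC, SSC) separated by two identical inverted
repeats (IRb, IRa). The workflow covers genome summary statistics,
IR/junction geometry, a repeat inventory turned into phylogenetic
characters, Fitch parsimony with consistency/retention indices and
bootstrap, p-distance and per-region variability profiling for molecular
marker discovery, exon-indel coding and polarity mapping, and detection of
small inversions flanked by palindromic repeats. A genome simulator with an
exact, event-maintained true alignment provides planted ground truth for
every stage, so the whole pipeline is testable without any external data.

The motivating system is the woody bamboos (Poaceae: Bambusoideae), whose
plastomes are about 139.5 kb, extremely conserved (pairwise p-distances of
0.002–0.014), and therefore a hard case for marker choice and phylogenetic
resolution. All simulator defaults encode that study design; nothing in the
package is restricted to bamboos.

# Coordinates and containers

All coordinates are 1-based inclusive, both at the GenBank-facing surface
and internally: R's native indexing is 1-based, and keeping a single
convention removes an entire class of off-by-one translation errors that a
mixed convention invites. Genomes are held in a `GenomeRecord` (a
`Biostrings::DNAString` plus a feature table in which a multi-exon
`join(...)` location is a group of rows sharing a `feature_id`); interval
arithmetic (unions, gaps, overlap queries) is delegated to IRanges.
Genomes are analysed in their deposited rotation, i.e. treated as linear;
origin-spanning features are flagged rather than resolved.

# Genome statistics and region partitioning

`genomeStats()` reports length, GC% (ambiguity codes other than G/C/S count
as non-GC), coding% as the union of CDS/tRNA/rRNA exon intervals (so
overlapping annotations are not double-counted), and gene counts. A gene is
"duplicated" when it has copies lying wholly inside both IR arms — the
operational definition that reproduces the unique/duplicated split reported
for grass plastomes. `partitionRegions()` emits coding exons, introns
(named "*gene* intron") and intergenic spacers (named by their flanking
genes, e.g. `trnD(GUC)-psbM`), with a length threshold; marker work
conventionally uses single-copy regions longer than 350 bp, subfamily-level
comparisons 200 bp.

# Quadripartite detection

`detectQuadripartite()` finds the maximal pair of disjoint segments where
one is the reverse complement of the other. Unique 20-mers of the sequence
and of its reverse complement are matched in one pass, hits are grouped by
diagonal, and one seed per diagonal is expanded outward by exact character
comparison — this yields the true maximal run regardless of seed
fragmentation. Arm matching is exact by default because plastid IRs are
homogenized to identity; a Hamming-tolerant mode (`minIdentity < 1`,
greedy outward extension while the running identity holds) is available for
degraded assemblies. The shorter inter-arm gap is the SSC; ties and
alternative extensions resolve toward the lower coordinate for determinism.
The four reported intervals always tile the genome, giving the invariant
|LSC| + |SSC| + 2·|IR| = genome length. `junctionReport()` names the gene
crossing each junction and its extension into the IR; in grasses the
diagnostic pattern is *ndhH* protruding ~170–200 nt into IRa while *ndhF*
stays confined to the SSC.

# Repeat scanning

Three finders share one engine and one match semantics: two positions match
iff both bases are unambiguous and equal (complementary for palindromes);
identity is ungapped Hamming identity, matches/length. Thresholds follow
the conventional plastome settings: dispersed copies ≥ 30 bp, tandem units
≥ 15 bp, palindromic arms ≥ 20 bp with an arm gap of at most 3 kb, identity
≥ 90% everywhere.

A reported repeat is a *maximal* qualifying window: one not contained in a
longer window that still meets the identity cutoff. Two consequences are
worth spelling out. First, a planted perfect repeat whose flanks happen to
tolerate extension is reported at its maximal extent with identity below 1;
exact mode (`minIdentity = 1`) recovers perfect copies verbatim. Second,
maximality admits an exact algorithm: every window at ≥ 90% identity
contains an exact run of at least 6 matches (pigeonhole), and extending a
window across an exact run never lowers its identity below the cutoff, so
every maximal window contains a *complete* exact run. The finders therefore
enumerate windows anchored on complete runs, pruned with the score bound
`m_l − id·(rs − a) + m_r − id·(b − re) ≥ −(1 − id)·runlen`, which is
exhaustive yet fast (sequences beyond 3 kb additionally use 12-mer seeding
to restrict the diagonals considered; this is complete for repeats whose
longest exact stretch reaches the seed length, a property that holds for
every repeat class retained here). Windows longer than `maxLen` (default
500 bp; real plastome repeats top out near 130 bp) are not considered.
Overlapping windows on one diagonal are merged to a single representative
(longest, then highest identity, then lowest start), emulating the manual
redundancy filtering traditionally applied to raw repeat-finder output. The
test suite checks the finders against independent brute-force window
enumerations on every small fixture.

`scanRepeats()` masks one IR copy before dispersed/palindromic scanning so
the genome-scale IR does not flood the inventory (repeats inside the IR are
still seen once through IRb), applies tandem-over-dispersed priority for
doubly-detected regions, and reclassifies motifs whose two copies lie in
two distinct tRNAs or in a known paralogous pair (default *psaA*/*psaB*) as
"similarity" repeats — sequence similarity due to shared gene function, not
repeat structure. Each motif gets a location class (coding / noncoding /
both, with spanning repeats counted in both) and a feature context.

Cross-genome repeat characters use a strict definition: two repeats are the
same character iff they share type, exact unit length and feature context
(the operationalization of "homologous region"; genomes of different
lengths cannot be matched by coordinates). Similarity repeats are excluded.
`repeatBinaryMatrix()` yields the presence/absence matrix for parsimony
analysis.

# Parsimony

`fitchLength()` is a bitmask-vectorized Fitch bottom-up pass; `?`, `-` and
`N` are wildcards; the length is invariant to rooting and taxon order.
`exhaustiveSearch()` scores every unrooted binary topology (105 at six
taxa; capped at nine taxa, 135,135 topologies) and returns all co-optimal
trees; `heuristicSearch()` (stepwise addition with random-order restarts
plus NNI hill-climbing) covers larger matrices and is deliberately outside
the acceptance surface. Ensemble indices follow the classic definitions:
CI = m/s and RI = (g − s)/(g − m) with m and g summed over *all*
characters, including parsimony-uninformative ones — the convention of the
standard parsimony programs, and required to reproduce published CI/RI
values. Nonparametric bootstrap resamples characters with replacement;
a bipartition scores a replicate iff it appears in the strict consensus of
that replicate's co-optimal trees, and support is reported as a percentage.
The seed is mandatory, making support vectors bit-reproducible.

`mapCharacter()` counts the independent origins of a binary character on a
fixed tree (its single-character Fitch length), calls it synapomorphic iff
there is exactly one origin, and polarizes it against the outgroup, which
is assumed ancestral. For indel characters the convention is state 1 = gap
present, so a derived gap is a deletion (−) and a derived non-gap against a
gapped outgroup is an insertion (+).

# Divergence, markers, indels, inversions

`pDistance()` is the uncorrected proportion of differing sites with
pairwise deletion of columns holding a gap, N or other ambiguity in either
row (the default of the classic distance software); group summaries are
plain means of the relevant pairs, so the overall mean is exactly the
weighted mean of within- and between-group values. `identityProfile()`
computes VISTA-style per-window identities on reference-anchored
coordinates (reference gap columns collapsed; a gap in the other row counts
as a mismatch), default window 100, step 25.

`regionVariability()` counts, per region alignment of length L: NS, the
substitution events, with each variable column contributing (number of
distinct non-gap states − 1) — the minimal-change count, chosen because
"number of substitutions" is otherwise ill-defined for more than two taxa;
ID, the indel events, as distinct maximal gap runs where runs with
identical start *and* end collapse to one event and same-start
different-length runs stay separate; and the proportion of mutation events
variation% = 100·(NS + ID)/L, plus variable and parsimony-informative site
counts (PI: ≥ 2 states each in ≥ 2 taxa). Substitutions-only mode
(`countIndels = FALSE`) serves cross-subfamily comparisons where alignments
differ too much for indel counts to be comparable. `rankMarkers()` sorts
noncoding regions by variation% (ties by PI%, then name) and reports how
many exceed the conventional marker thresholds (variation% > 4, PI% > 3
among those). `fitLinear()` is ordinary least squares via `lm()`.

`extractExonIndels()` turns maximal identical-boundary gap runs in exon
alignments into candidate events (simple indel coding), keeps those whose
state varies within the ingroup (autapomorphies included), and polarizes
against the outgroup; partial outgroup overlap leaves polarity undetermined
rather than guessed. `codeAndAppend()` adds one binary character per event
to a matrix; `classifyEvents()` maps them on a reference topology.

`detectSmallInversions()` anchors on palindromic arm pairs found on the
ungapped reference row and calls a taxon inverted when the
reverse-complemented segment matches the reference at ≥ 0.9 identity while
the direct comparison stays below 0.5 — thresholds far enough apart that
the call is unambiguous at plastome divergence levels. Arms are located at
exact identity by default, which pins segment boundaries precisely;
`armIdentity` can be relaxed when the reference itself carries
substitutions in the arms. `normalizeInversions()` either drops the
segment columns ("exclude", the conservative treatment before phylogenetic
analysis) or reverse-complements the minority orientation ("reorient");
reorientation is idempotent.

# The simulator and what it does (not) show

`simulatePlastomes()` evolves a quadripartite root genome along a tree with
branch lengths in expected substitutions per site. The defaults *are* the
study conditions of the six-genome bamboo comparison and were fixed before
any downstream measurement:

* architecture LSC 83,000 / SSC 12,800 / IR 21,800 bp (≈ 139.4 kb), GC
  38.9%, a realistic grass gene layout with *ndhH* crossing the SSC/IRa
  junction by 183 nt (midpoint of the published 172–195 nt range) and the
  classic hotspot spacers laid out wide enough to pass the 350 bp filter;
* the reference topologies `bambooTree(6)` and `bambooTree(8)` with branch
  lengths calibrated to p ≈ 0.002 within Arundinarieae, 0.003 within
  Bambuseae and 0.014 between tribes;
* substitution model JC by default (K2P and GTR available); relative rate
  factors 0.55 (coding), 1.34 (noncoding) and 0.3 (IR), normalized so the
  genome-wide mean rate is one per unit branch length — branch lengths thus
  stay on the p-distance scale. IR substitutions are mirrored into both
  arms (concerted evolution), so the IR stays detectable exactly and IR
  sites diverge at the same per-site rate as sampled;
* indels only in single-copy DNA (rate 0.15 per substitution in noncoding,
  a fifth of that in exons; geometric lengths, mean 4 bp, exon lengths in
  multiples of 3); the IR receives no indels, which keeps the arm mirror
  map exact;
* 14 repeats planted at the root (the number shared by all six bamboo
  genomes) and repeat-gain duplications inserted into spacers along
  branches at a rate chosen to produce a repeat matrix of the published
  size; `simulateRepeatHistory()` is the lightweight binary-character
  counterpart (65 characters, 3% second-flip homoplasy, matching the
  published consistency index of ≈ 0.97). Gain branches are sampled
  proportionally to branch length by default; topology-recovery experiments
  instead use equal edge weights and 120 characters, because on a tree with
  very short internal branches length-weighted gains almost never produce
  the ≥ 30 parsimony-informative characters the recovery condition
  requires;
* one planted small inversion construct (22 bp palindromic arms around a 30
  bp segment in the `rpl32-trnL(UAG)` spacer), flipped on a configurable or
  randomly chosen branch.

The true alignment is maintained column-by-column as events happen —
insertions create new columns keyed between their neighbours, deletions
remove columns — and is never recomputed by alignment software, so NS/ID
ground truth is exact and each leaf genome equals its degapped alignment
row byte for byte. `plantMarkers()` multiplies regional rates to plant
divergence hotspots whose recovery by the ranking stage is then testable.

What passing these tests shows: the algorithms recover planted structure
exactly or at the stated rates under a realistic divergence regime. What
they do not show: robustness to annotation error, assembly artefacts,
alignment error (the simulator's alignment is true by construction),
base-composition heterogeneity, codon structure, or recombination — real
data add all of these.

# Numerical choices and degenerate inputs

Identity comparisons use a 1e-12 slack so that thresholds like 27/30 ≥ 0.9
are decided exactly. Ties in tree search return *all* co-optimal
topologies; `strictConsensus()` summarizes them. RI is undefined (NA) when
g = m; CI is NA for an all-constant matrix (s = 0). A pair of sequences
with no comparable sites yields an NA distance with a warning. Empty
repeat sets, empty region sets and zero-event simulations are legal
everywhere. Exhaustive search refuses more than nine taxa and points to the
heuristic. All randomness (simulator, bootstrap, heuristic restarts) is
routed through mandatory seeds and restores the caller's RNG state.

Problem sizes in the shipped tests and acceptance script are chosen to keep
a full run in a few minutes on one core: oracle comparisons use 250–600 bp
fixtures (the window-enumeration oracles are quadratic), mini-architecture
genomes (~15 kb) exercise the simulator-driven paths, and two study-scale
(~139.4 kb) simulations back the acceptance quantities; topology-recovery
rates use 100 seeded replicates of the binary repeat-history simulator.

# Known limitations

GenBank parsing covers the feature subset the pipeline consumes (gene, CDS,
tRNA, rRNA, intron, repeat_region keys; `join`/`complement` locations);
qualifiers beyond `/gene` and `/label` are ignored. The repeat finders do
not model indels within a repeat copy (ungapped identity only), matching
the mismatch mode of the classic repeat software. Cross-genome repeat
matching requires exact unit-length equality, so heavily eroded repeats
fragment into taxon-specific characters (these are parsimony-uninformative
singletons and do not distort the tree, but they deflate shared counts).
Small-inversion detection presumes the flanking arms are recognizable in
the reference genome. The heuristic tree search is a convenience, not a
guarantee of optimality.
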