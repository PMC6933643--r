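---
title: "Reconstructing local strains at HGT sites: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing local strains at HGT sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Horizontal gene transfer (HGT) moves DNA segments between bacterial
species. In a gut metagenome, a receptor genome that has acquired donor
segments exists as a *local strain*: the receptor sequence with donor
intervals spliced in at insertion sites, possibly several segments from
several donors, in either orientation. Given shotgun paired-end reads
aligned against a joint reference set, `hgtrecon` (i) locates the HGT
junctions at base resolution and (ii) reconstructs the local strain
sequences, i.e. the order and orientation of the reference segments each
strain traverses.

# Breakpoint detection

Two read classes carry the junction signal:

* **Junction pairs** — read pairs whose mates map to different references.
  A pair mapped to references $X$ and $Y$ becomes a point $(B_x, B_y)$ in
  the plane of that reference pair. Points of one junction scatter within
  roughly one insert size of the true coordinate, so we cluster them with
  DBSCAN under Euclidean distance, `eps` set to the average insert size
  (estimated as the median template length of concordant pairs) and
  `min_sample = 1`. With `min_sample = 1` DBSCAN reduces exactly to the
  connected components of the eps-neighbourhood graph — the package tests
  this equivalence against a union-find oracle.
* **Split reads** — single reads partitioned across the junction. The part
  on $R_1$ terminates exactly at the junction; the quality of the partner
  part on $R_2$ is $q_s = m/l$ (matched bases over part length, $m \ge 15$
  required). Each candidate position is scored $1 - \sum_s \log(1 - q_s)$
  (natural log; the base only rescales scores monotonically). The candidate
  pair with the highest summed score wins; ties break to the smallest
  coordinate pair. Since $q_s = 1$ would make $\log(1-q_s)$ infinite,
  perfect parts are clamped to $1 - 1/(2l)$ — finite, order-preserving, and
  scaled to the part's own resolution.

Clusters supported by junction pairs but no split read cannot be placed at
base resolution; they are reported as imprecise rather than dropped.

# The strain graph

Called breakpoints cut the involved references into segments. We model the
strain structure as a *bidirected* segment graph: every edge attaches to a
segment *end* (left or right), and a traversal enters a segment through
one end and leaves through the other — entering left means reading the
segment forward, entering right means reverse-complement. This makes the
$\pm$ strand bookkeeping of junction evidence explicit: a breakend whose
joined piece lies left of the coordinate attaches that segment's right
end, and vice versa.

Copy numbers are initialised from coverage: $c(v) = cov(v)/cov(r)$, where
$cov(r)$ is the length-weighted mean depth over the *retained* segments of
the parent reference. Using retained segments (rather than the whole
reference) makes the estimate correct both when reads come only from the
local strains (as in the benchmark protocols, where donor references are
covered only on the transferred interval) and when background reads from
the original references are present.

Receptors are recognised by their insertion loci — an L-direction and an
R-direction breakend at (nearly) the same position, i.e. a donor path that
leaves the reference and returns. The receptor's first and last segments
($b_i$, $t_i$) bound its strain. To turn the $k$ strain paths into one
closed traversal we insert a dummy back-edge $t_i \to b_i$ with copy
$c(b_i) - 1$ (omitted at copy 0) and chain edges $t_i \to b_{i+1}$,
$t_k \to b_1$ with copy 1. Segments unreachable from every receptor are
removed; a remaining segment end with no incident edge receives a single
copy-1 repair edge along its reference (or, failing that, to the nearest
receptor segment boundary) so every vertex lies on a $b \to t$ path.

# Balancing and traversal

Sequencing noise leaves the copy estimates unbalanced. We solve an integer
program: choose integer copies for every edge and segment such that at
each segment the copies attached to its left end, its right end, and the
segment copy coincide, minimising $\sum_u |c(u)-t(u)| + \sum_e |c(e)-t(e)|$
against the coverage-derived targets ($t \ge 1$). The solver is an exact
branch-and-bound with interval propagation, cross-checked in the test
suite against brute-force enumeration on random instances (up to 6
vertices, 10 edges, copies $\le 4$); past a configurable search-node cap a
greedy repair heuristic takes over and is flagged in the solver report.
Upper bounds on copies are $4\times$ the largest initial estimate — the
program needs finite bounds and coverage ratios in these data never
approach that ceiling.

One deliberate deviation from a literal reading of the model: structurally
inserted reference-adjacency edges with no read support get lower bound 0.
Forcing every adjacency edge to copy $\ge 1$ would thread a spurious
no-HGT pass of the receptor through every reconstruction; with lower bound
0 the optimiser keeps such an edge only when coverage demands it. Dummy
back-edges share this lower bound, as their copy $c(b_i)-1$ is legitimately
zero for single-copy strains.

A balanced bidirected graph admits a closed traversal using every edge
exactly its copy number of times. We build it by expanding edges to unit
multiplicity and growing a greedy trail from the first receptor's start
segment: at every exit port the unused unit of highest preference is taken
(observed junction edges before reference adjacency, repair, dummy and
chain edges; ties by partner coordinate), so the trail follows donor
excursions before falling back to the artificial circuit-closing edges.
The degree balance guarantees the trail can only terminate back at its
start; leftover balanced sub-curves are then spliced in at shared
segments (reversed when their reading direction disagrees with the
hosting visit). The preference order makes the output deterministic and
greedily concentrates HGT events within strains — the exact maximisation
of events per strain would require searching over all Eulerian
decompositions, which we deliberately do not do. Cutting the circuit at
chain and dummy edges yields the strain walks $b_i \to t_i$; emitted
sequences concatenate segment substrings, reverse-complemented for
reverse visits. Pieces that read $t_i \to b_i$ backwards are flipped; a
piece that cannot be oriented (possible only when one physical segment is
traversed in both orientations by different strains) is kept and flagged
as partial.

# Evaluation metrics

Reconstructions are scored at segment level. A reconstructed segment
matches a truth segment when both boundary positions agree within 20 bp
(same reference, same orientation; matching is 1-to-1, nearest first).
Matched segments share a token; the token sequences are aligned with a
Smith–Waterman local alignment (match 1, mismatch −1, gap 0) and

$$RA_i = \frac{SW(h_i, H_i)}{m_i \cdot match\_score},$$

0 for an empty reconstruction, 1 exactly when all $m_i$ truth segments are
recovered in order. The gap penalty of 0 is a design choice the printed
worked example pins down: a strain of 23 segments reconstructed with one
interior segment missing scores $22/23 = 0.9565$, which only a free-gap
alignment reproduces. The Detection Rate is the fraction of transferred
segments with both boundary junctions recovered within 20 bp; breakpoint
sensitivity and FDR use the same tolerance with 1-to-1 nearest-first
matching of called to true junction pairs. The mean RA over repetitions
divides each repetition's RA sum by its count of non-empty
reconstructions before averaging (the printed formula's inner index runs
over strains, not repetitions).

# The simulator and what it does (not) show

The built-in generator creates random nucleotide genomes, plants HGT
events (default 10 kb transferred segments, 1–5 per event, copied — not
excised — from donors, random orientation, distinct insertion loci by
default with chained segments as an option), simulates WGSIM-like
paired-end reads (uniform fragment placement, Gaussian insert truncated at
twice the read length, substitution-only errors) and writes ground-truth
alignments directly, bypassing an external aligner. Notable choices, each
fixed before any benchmark was run:

* **Insertion semantics.** An insertion at 0-based receptor position $p$
  places the donor sequence between $p-1$ and $p$; coordinates are 0-based
  half-open internally and 1-based inclusive in all reports.
* **Minimum reportable split.** A read part shorter than 30 bp is not
  reported as an alignment (the overhang is soft-clipped on the primary
  record only). This mirrors the minimum output score of BWA-MEM, the
  aligner the method is designed to consume; it is the binding constraint
  of low-coverage sensitivity, since a junction is only placed when some
  read straddles it with 30 bp on each side.
* **Donor intervals never overlap** across events (200 bp guard).
  In a realistically large reference set two random 10 kb intervals almost
  never collide; at desk scale (tens of genomes) collisions would
  otherwise split true segments at foreign breakpoints and misattribute
  reconstruction errors to the method.
* **Insertion loci keep 2 insert sizes of separation** so that distinct
  junction clusters cannot merge, and stay one insert size clear of genome
  ends.
* **Read sources.** The benchmark protocols generate reads from the true
  local strains only; a config flag adds background reads from the
  original references, and the copy-number normalisation handles both
  regimes.

Problem sizes used by the bundled benchmarks: the reconstruction benchmark
uses 5 genomes of 180–220 kb with one receptor carrying 2 events × 5
segments at 30X, 100 bp error-free reads — small enough to run in seconds
while exercising every pipeline stage. The coverage-series benchmark uses
20 genomes, 50 single-segment events (100 junction pairs) and the WGSIM
default read geometry (70 bp reads, 500 ± 50 insert, 2% substitution
error) over 4 seeds per depth. With this geometry the probability that a
junction acquires a reportable split read is
$1 - e^{-d(L - 2a + 1)/L}$ at depth $d$ (read length $L = 70$, minimum
part $a = 30$), i.e. ≈ 0.27, 0.54, 0.79 and ≈ 1.0 at 2X, 5X, 10X and 70X —
the shape of the published sensitivity curve. Synthetic random genomes
carry no homologous or repetitive sequence, so the mapping-ambiguity
losses that cap real-data sensitivity below 95% at high coverage (and the
non-zero FDR) are *not* reproduced here; passing benchmarks demonstrate
the geometric and algorithmic behaviour of the method, not its robustness
to reference-set homology.

# Degenerate inputs and numerical notes

Empty alignment sets, clusters without split support, references with zero
coverage, and graphs with no receptor all return empty results with
warnings rather than errors. Score comparisons use a $10^{-12}$ slack so
floating-point noise cannot flip a tie-break. The insert-size estimator
requires 100 concordant pairs before trusting the data and otherwise falls
back to a user-supplied value. Segments shorter than 50 bp are merged into
a neighbour; segment copy upper bounds, DBSCAN `eps`, and the unique-
mapping MAPQ threshold (default 20 — the method's "unique mapping" is
otherwise unspecified) are all exposed as parameters.

# Known limitations

* HGT between sequences absent from the reference set is invisible, and
  junctions inside repeats are lost with the multi-mapping reads that
  carry them.
* The greedy traversal preference does not guarantee the globally maximal
  number of HGT events per strain when several Eulerian decompositions
  exist.
* The evaluation is segment-token based; it does not award partial credit
  for nucleotide-level near-misses beyond the 20 bp boundary tolerance.
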