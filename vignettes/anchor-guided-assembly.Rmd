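---
title: "Anchor-guided assembly of ultra-high-depth read clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-guided assembly of ultra-high-depth read clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorasm)
```

## The problem

Synthetic long read (SLR) protocols such as LoopSeq Solo capture one molecule
per well, tag every short read derived from it with a shared molecular index,
and ligate known 12 bp *anchor* sequences to both ends of the molecule. A
*read cloud* — the reads sharing one index — therefore covers a single target
of a few hundred bp to a few kb at depths from tens to thousands of fold.
Conventional assemblers neither exploit the anchors nor cope gracefully with
the artifacts that ultra-high depth brings: read-throughs across the junction
of the circularized amplicon (which put cycles into the assembly graph),
PCR-mediated chimeras between similar molecules (spurious edges and extra
anchor copies), and internal repeats (tangles). `anchorasm` assembles one
molecule from one cloud by exploiting exactly these two properties: the
anchors pin the endpoints, and the depth makes the true sequence the
heaviest path.

## Molecule length from the N50 kmer frequency

With `N` reads of length `R` sampled uniformly from a repeat-free molecule of
unknown length `M`, every kmer of the molecule occurs
`F = N(R - k + 1)/M` times among the reads, so `M = N(R - k + 1)/F`. Mean,
median and mode of the observed kmer frequencies are all badly distorted by
the long tail of error kmers (the median of all kmer frequencies in a deep
cloud is typically 1). The estimator used here is the **N50 kmer frequency**:
the largest frequency `f*` such that kmers of frequency `f*` or higher
account for at least half of all kmer occurrences (`n50_frequency()`, with
"at least" implemented inclusively). Error kmers are many in kind but few in
occurrence mass, so the 50% crossing lands inside the true-kmer cluster.
Counting is canonical (a kmer and its reverse complement pool into one bin)
because mates and strands otherwise split the signal. The default `k = 33`
balances kmer uniqueness within the molecule against the error-free
probability of a window at SLR read lengths.

The point estimate is widened to an admissible interval
`[Ml, Mu] = [0.5 M, 2 M]` (both fractions tunable) which the path search
enforces; the point estimate itself breaks score ties.

Two systematic effects are worth knowing about. Sequencing errors inflate
the numerator (every window counts) but not the true-kmer frequency, biasing
`M` upward by roughly `1/(1 - e)^k` (about +18% at 0.5% error) — harmless for
the 0.5x–2x interval. Linear fragment sampling depletes coverage within a
fragment length of the molecule ends, biasing `M` downward by roughly one
fragment length — also harmless for the interval, but the *parameter
recovery* property of the estimator (within 15% of truth) is only claimed
under its stated assumption of uniform coverage. The simulator's
`layout = "uniform"` mode (uniform read starts with circular wrap-around,
the situation a circularized amplicon approximates) exists to test exactly
that regime.

## The assembly graph

Reads and their reverse complements are decomposed into kmers at `k_g = 31`
(below the read length, above the anchor length; capped at 31 so a kmer and
its edge witness fit in 64-bit codes). Kmers seen fewer than `min_count = 2`
times are dropped — at high depth, singletons are almost surely errors. A
directed edge requires both the (k-1)-overlap *and* a witnessed (k+1)-mer in
the reads, so kmers that merely overlap but were never adjacent do not
connect. Maximal non-branching paths are compacted into unitigs
(`build_cdbg()`); a unitig's weight is the arithmetic mean of its member
kmer counts, the conventional coverage summary. Inserting both strands
(rather than building a bidirected graph) guarantees the anchored
orientation of the target is a directed path, so anchors are searched in
their given orientation only. Perfect cycles — a circularized amplicon
collapses to one — are broken at an arbitrary member and kept as one unitig
with a self-edge.

## Anchor localization

Anchors are located by infix alignment: a unitig is a hit at tolerance `e`
if some substring lies within unit-cost Levenshtein distance `e` of the
anchor (`find_anchor_nodes()`). The search escalates `e = 0, 1, 2` and stops
at the first tolerance that yields an assembly; 2 edits suffice for 12 bp
anchors much shorter than the graph kmer. Per unitig the minimal-distance
occurrence is kept — leftmost for the start anchor, rightmost for the end
anchor, which maximizes the retained sequence. Anchors spanning a unitig
junction are not found; with anchors shorter than `k_g` this is rare, and a
known limitation.

One systematic effect needs special handling: coverage decays toward the
tips of a linear template (only fragments starting exactly at the tip cover
its first base), so the `min_count` filter routinely drops the outermost
kmers, leaving a unitig that begins a few bases *into* the start anchor.
Such a unitig is a graph tip — no in-edge — whose boundary carries an exact
remnant of the known synthetic anchor. `find_anchor_nodes()` therefore also
accepts, at tips only and when no within-tolerance infix occurrence exists,
an exact anchor remnant of at least `min_overlap = 6` bases at the unitig
boundary as an occurrence (reported at edit distance 0). The chance of a
random unitig boundary matching a 6+ base remnant exactly is a few in 10^5
per unitig, and such spurious hits still have to win the weight-based pair
scoring. Anchor restoration (below) then reconstructs the truncated bases
from the supplied anchor sequence.

## The length-constrained maximin path

Among all paths between a start and an end anchor node, the assembler wants
the one whose *smallest* node weight is largest — the true molecule is
covered end to end at full depth, while artifact branches are thin. The
dynamic program keeps, for each node and round `l`, a priority queue of up
to `c = 30` entries `(z, L)`: the best bottleneck scores achievable with at
most `l` edges, alongside the spelled length. Round `l` starts from the
round `l-1` queues (paths may stand still); expanding an edge `(u, v)`
updates `z' = min(z, w(v))` and `L' = L + length(v) - (k_g - 1)`, skips the
expansion if `L'` exceeds `Mu`, and inserts `(z', L')` if the queue has room
or `z'` strictly beats the smallest key (which is evicted). The DP stops at
the first round in which no queue changes; the length cap makes that happen
long before the worst-case `|E|` rounds even in cyclic graphs, because a
cycle lap adds length but never improves a bottleneck. At the end node,
entries shorter than `Ml` are discarded; the winner has maximal `z`, ties
going to the length closest to the point estimate `M`, then (optionally, on
by default) to the lexicographically larger sorted weight vector — the
printed recurrence optimizes the smallest weight only, so the
second-smallest-weight refinement is applied as a final tie-break among the
surviving candidates rather than inside the queues, a deliberate and
switchable deviation (`lex_refine`).

Two implementation economies are exact rather than heuristic: queues are
copied lazily (carry-over is by reference until modified), and each queue
entry is expanded along each out-edge exactly once, in the round after its
insertion. Re-expanding an old entry could only re-derive the identical
`(z, L)` via the identical route — either rejected, or a capacity-crowding
duplicate of one walk; duplicates arising from *different* routes are still
admitted, as they represent distinct tracebacks. Within a queue, evictions
among equal smallest keys remove the entry farthest from `M`, then the
oldest; capacity counts duplicates.

When several anchor pairs exist (chimeras and errors create extra anchor
nodes; at high depth the anchor also lies on many mutually overlapping
unitigs), every pair is scored and the best `(z, |L - M|)` wins. Two exact
prunes keep this affordable: the DP is run once per distinct start node
(it does not depend on the target), and a start is skipped when an upper
bound on its achievable bottleneck — its own weight, or a capacity-1
unconstrained maximin screen — cannot strictly beat the incumbent. Among
exact bottleneck ties the earliest-scanned pair supplies the candidates, so
the reported bottleneck is exact while tie-breaking on length is resolved
within the candidate pools actually computed.

## Readout, trimming, anchor restoration

The winning path is spelled with (k-1)-overlaps verified character by
character, then trimmed from the matched start-anchor span to the matched
end-anchor span, mapped through the concatenation (`read_out_sequence()`).
Candidates are tried in rank order until the anchor spans are consistently
ordered: in the read-through regime the amplicon cycle compacts into a
single unitig that is an arbitrary *rotation* of the molecule, where the
single-node path often wins the length tie-break but carries its anchors
out of order — the valid readout is the two-lap path through the self-edge,
which the fallback finds.

Because the anchors are synthetic constants supplied by the user, the
trimmed output's anchor spans are by default rewritten with the exact anchor
sequences (`restore_anchors = TRUE`). This corrects the one or two bases of
an anchor copy that sequencing errors — or, more commonly, the `min_count`
filter acting on the thinly covered first and last positions of a linear
template — would otherwise corrupt or truncate. It never touches anything
between the anchors, and it is switchable off.

## The simulator

`simulate_read_cloud()` emulates the study conditions end to end: a random
(or supplied) core flanked by the two 12 bp anchors; 110 bp paired-end reads
from fragments of Normal(250, 25) bp truncated to at least two read lengths;
i.i.d. substitution errors at 0.5% (indel errors are out of scope, matching
short-read error profiles); fragment count `ceil(depth * len(template) /
(2 * read_len))`. Artifact regimes: `read_through` draws reads from the
molecule self-concatenated 5 times, so reads span the end-start junction;
`repeat` copies a random contiguous 10% of the molecule and reinserts it at
a random interior position, the mutated molecule becoming the new ground
truth; `chimera` splices 1% of fragments onto a second template, emulating
inter-molecular PCR recombination. Depth applies to the template reads are
drawn from — in the read-through regime the concatemer — so per-base
coverage matches the nominal depth everywhere except linear template tips.

What the simulator does *not* emulate, and what passing tests therefore do
not establish for real data: quality-score structure and quality-dependent
errors, indel sequencing errors, PCR duplicates and coverage waves,
index-hopping contamination between clouds, and real 16S sequence
composition (cores are uniform random unless a reference is supplied).
The tips of a linear template receive vanishing coverage under fragment
sampling (only fragments starting exactly at the tip cover its first base);
this is a real property of linear libraries that makes low-depth (50x)
recovery of the outermost bases genuinely hard, and it is the reason the
anchor-restoration step exists.

## The evaluator

`align_and_score()` scores an assembly against its truth with a local
aligner (match +1, mismatch -2, gap open -4, gap extend -1 — conventional
short-alignment scoring at this scale) in both orientations: genome
fraction percentage (reference positions covered by the union of alignment
spans), largest alignment ratio (largest single alignment span over total
assembly length), mismatches per kb and indel events per 100 kb over
aligned columns. Contigs under 200 bp are dropped. This is a deliberately
simplified stand-in for a full assembly evaluator: it reports one best
local alignment per contig and orientation, so fragmented or rearranged
alignments of a single contig are summarized more coarsely; metric values
are comparable, not bit-identical, to heavyweight evaluators.
`alignment_identity()` is a global-alignment identity with terminal
overhangs counted in the denominator, so end truncation is penalized.

## Numerical and degenerate-input choices

Frequencies and counts are integers throughout; the N50 crossing uses an
inclusive comparison, so a bin holding exactly half the occurrence mass
qualifies. `estimate_length` signals structured errors on empty input or a
zero N50 frequency. The DP seeds with the full length of the start unitig
(anchor-offset trimming happens at readout, keeping DP lengths an upper
bound on the reported length; the slack is immaterial against the 0.5x–2x
interval) and returns an empty result when even the bare start node exceeds
`Mu`. A hard round cap (`max(|E|, Mu)` for finite `Mu`) guards termination;
reaching it raises an error rather than returning a truncated answer.
`s == t` is a valid zero-edge path. All randomness in the simulator flows
from a single seed; assembly itself is deterministic.

## Problem sizes used in the shipped checks

The end-to-end checks simulate molecules of 600–2000 bp: the clean regime
uses 20 molecules at depth 500x; the read-through regime 6 molecules at each
of 50x, 100x and 500x plus 2 molecules at 3000x; the repeat regime 10
molecules at 500x; estimator recovery 50 molecules of 500–3000 bp at 100x.
These replication levels keep a full run on a single desktop core while the
averages remain stable to a few percent.

## Known limitations

Anchors spanning unitig junctions are invisible to the node-level search.
Graph kmer sizes above 31 are not supported. A single cloud is assumed to
contain a single target molecule: multi-molecule clouds, demultiplexing and
quality trimming are upstream concerns. Repeats longer than the graph kmer
still tangle the graph; the length interval and weight objective usually,
but not always, resolve them — at depths below ~100x the thin molecule tips
are the dominant failure mode, and assemblies there may fail outright
rather than return a partial contig, a deliberate choice (a partial
molecule is indistinguishable from a wrong one without the anchors).
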