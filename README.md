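# anchorasm

Anchor-guided assembly of ultra-high-depth synthetic long read (SLR) clouds.

SLR protocols such as LoopSeq Solo capture one molecule per well, tag all of
its short reads with a molecular index, and ligate known 12 bp **anchor**
sequences to both ends of the molecule. A *read cloud* — the reads sharing
one index — covers a single target of a few hundred bp to a few kb at 50× to
3000× depth. `anchorasm` assembles the full-length molecule from one cloud
by using exactly those two properties: the anchors pin the endpoints, and
the depth makes the true sequence the heaviest path in the assembly graph.

The pipeline:

1. **Length estimation.** With N reads of length R uniformly covering a
   molecule of length M, every kmer occurs F = N·(R−k+1)/M times, so
   M = N·(R−k+1)/F. F is estimated by the *N50 kmer frequency*: the largest
   frequency f\* such that kmers of frequency ≥ f\* hold at least 50% of all
   kmer occurrences — robust against the long tail of error kmers. Bounds
   [Ml, Mu] = [0.5·M, 2·M] constrain the path search.
2. **Graph.** A node-centric de Bruijn graph (k = 31, strand-augmented,
   kmers with count < 2 dropped, edges only where a (k+1)-mer witnesses the
   junction) compacted into a weighted unitig graph G = (V, E, w), with
   w(v) the mean kmer coverage of unitig v.
3. **Anchors.** Each anchor is located by infix edit-distance search against
   the unitigs at escalating tolerance e = 0, 1, 2.
4. **Path search.** For each start/end anchor node pair, a bounded
   priority-queue dynamic program finds the s→t path maximizing the smallest
   node weight among the best c = 30 candidates per node, pruning any
   expansion whose spelled length exceeds Mu and discarding final candidates
   shorter than Ml; score ties break toward the length closest to M.
5. **Readout.** The winning path is spelled with (k−1)-overlaps, trimmed to
   the matched anchor spans, and the anchor spans rewritten with the known
   anchor sequences.

A simulator (clean, read-through, repeat-insertion and chimera regimes, with
ground truth) and an alignment-based evaluator (genome fraction, largest
alignment ratio, mismatch/indel rates) make every stage testable without
external data. See the methods vignette
(`vignettes/anchor-guided-assembly.Rmd`) for the model, parameter and design
discussion.

## Worked example

```r
library(anchorasm)

# simulate a read cloud from a 1.5 kb anchored molecule at 500x with 0.5% errors
cl <- simulate_read_cloud(core_len = 1500, cfg = sim_config(depth = 500), seed = 7)
reads <- c(cl$reads1, cl$reads2)

res <- assemble_molecule(reads)
res
#> Assembly: 1524 bp, z* = 12.7, L* = 1524, e = 0 (M_est = 1544)

alignment_identity(res$sequence, cl$truth$molecule)
#> [1] 100

align_and_score(res$sequence, cl$truth$molecule)
#> GFP 100.00%  LAR 100.00%  mismatches/kb 0.000  indels/100kb 0.000  (1 contig)
```

The header line reads: the assembled molecule is 1524 bp (1500 bp core plus
two 12 bp anchors); the path's bottleneck weight z\* is 12.7 (the thinnest
unitig on the chosen path — molecule tips are thin under fragment sampling);
L\* is the untrimmed path length; the anchors matched exactly (e = 0); and
the kmer-based length estimate was 1544 bp, well within 2% of truth. Against
the ground truth the assembly covers 100% of the reference (GFP), in one
continuous alignment (LAR), with no mismatches or indels.

A thin CLI over the same functions ships in `inst/scripts/anchorasm`
(subcommands `estimate-length`, `assemble`, `simulate`, `evaluate`).

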