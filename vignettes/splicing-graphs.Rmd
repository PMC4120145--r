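---
title: "Splicing graphs from de Bruijn graphs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing graphs from de Bruijn graphs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicegraphr)
```

## The problem

De novo transcriptome assembly from short RNA-Seq reads usually starts
from a de Bruijn graph: a vertex per k-mer observed in the reads, an
edge whenever two k-mers overlap by k−1 bases. Assemblers then emit
linear transcript predictions, which discards the very thing a
transcriptome is rich in — alternative splicing. `splicegraphr` keeps
the branching: it converts the intermediate graph into a collection of
small acyclic **splicing graphs**, one per gene, whose source-to-sink
paths spell the isoforms, and attaches a per-node, per-library
**de novo RPKM** expression estimate. No reference genome is used at
any point, which is what makes the approach applicable to non-model
organisms.

The package operates as a postprocessor: it can build the graph itself
from FASTA/FASTQ libraries, or import one from a Velvet-style
`LastGraph` file, and then cleans and decomposes it in a fixed stage
order:

1. **build / import** — double-stranded graph over canonical k-mers,
   compacted into unitigs;
2. **coverage cutoff** — drop nodes with mean k-mer coverage < `c`;
3. **tip clipping** — remove short dead-end spurs;
4. **SNP merging** — collapse equal-length split-then-merge bubbles
   into consensus nodes;
5. **decomposition** — extract cyclic regions (non-trivial strongly
   connected components) and forward–backward strand tangles as
   single-node assemblies; keep one orientation per remaining
   component;
6. **finalization** — de-overlap node sequences, make merge junctions
   base-precise, restore source prefixes, drop graphs with any
   source-to-sink path of length ≤ 2k−1;
7. **expression** — count reads per node (a read contributes to every
   node it shares a k-mer with) and report RPKM per library.

## The graph model

Both strands are assembled simultaneously. Each node pair is stored
once: node `id` spells a sequence, node `-id` its reverse complement,
and every edge `(u, v)` is mirrored by `(-v, -u)` (twin symmetry).
K-mers are stored under their canonical form (the lexicographically
smaller of the k-mer and its reverse complement); `k` is restricted to
odd values so no k-mer can equal its own reverse complement. Bases
outside `{A,C,G,T}` split reads into fragments rather than being
substituted, so no k-mer is ever fabricated.

Edges link k-mers that occur consecutively within some read. This is
the graph a de Bruijn assembler materialises. At the k-mer sizes used
in practice (21–35) it coincides with the textbook overlap definition;
at toy k the overlap definition would additionally connect k-mers that
happen to overlap by chance without ever co-occurring in a read, which
only obscures the structures of interest.

A unitig is a maximal branch-free chain; compaction replaces each chain
by one node spelling the concatenation (respecting the k−1 overlaps)
and is re-run after every cleaning step that removes nodes. A perfect
cycle compacts to a single node carrying a self-loop; such nodes are
guaranteed to be removed later as one-node strongly connected
components, so tandem-repeat circles never reach the output as loops.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `k` | — (user) | bases | k-mer length; larger k gives longer, more specific nodes but needs more coverage |
| `c` | 0 | mean k-mer coverage | node survival cutoff (`kmer_count / length_k < c` removes the node) |
| `tip_len` | `2k − 1` | bases | maximum spelled length of a clippable dead-end tip, the conventional "twice k" tip length of de Bruijn assemblers |
| `min_match` | `k` | bases | minimum exact-match run between mismatch columns of a SNP bubble |
| `max_mismatch_frac` | 0.02 | fraction | maximum fraction of mismatching columns in a SNP bubble |
| `max_mm` (evaluation) | 3 | mismatches | tolerance when matching 2k junction strings |

Tip clipping removes a dead-end node only when every branch node it
hangs off retains an alternative incoming path, so clipping can never
disconnect two surviving nodes; candidates are removed
weakest-coverage first and the search iterates to a fixed point.

## SNP bubbles

A heterozygous substitution (or a sequencing variant too frequent for
the coverage cutoff) appears as a split-then-merge bubble: the paths
re-converge after exactly k k-mers, so all parallel arms have the same
length, whereas alternative splicing bubbles almost never do. The
detector requires equal-length arms, clean topology (each arm has
in-degree and out-degree exactly 1, and the final node receives
nothing else; extra edges into the start node and out of the final
node are allowed), no node together with its own twin, and a mismatch
pattern compatible with isolated substitutions: runs of at least
`min_match` exact matches between mismatch columns and at most
`max(1, floor(max_mismatch_frac × L))` mismatching columns. The
`max(1, …)` floor matters: a single SNP in a bubble of length 2k−1 is
the canonical case the merge exists for, and a bare fractional
threshold of 0.02 would reject it at any practical k (1 > 0.02·(2k−1)
for k ≤ 25). Short indels produce arms of unequal length and are
deliberately left alone.

Successive bubbles sharing a start/end node are chained and the whole
chain is replaced by one node. The merged sequence is the per-column,
coverage-weighted majority; ties break toward the lexicographically
smaller base, in the orientation in which the structure was
enumerated, so the result is deterministic. The merged node's
`kmer_count` is the sum over all merged nodes — recomputing coverage
from reads would be more faithful but requires keeping the reads
around, which the postprocessing stage deliberately does not.

## Decomposition

Cycles cannot be interpreted as splicing, so every strongly connected
component with two or more nodes (or a self-loop) is extracted; each
extracted node is kept as a single-node assembly, discarding the
junction information inside these tangled regions. SCCs are computed
with `igraph` on the oriented graph; the test suite checks the
partition against a brute-force reachability oracle on hundreds of
random graphs.

After cycle removal a component may still contain a node together with
its twin — a forward–backward tangle, where the two strands of a
region are conflated (typically via palindromic sequence). The method
only states that such components must be split; which nodes to blame
is a design choice. We extract exactly the culprit set `{v : -v in
the same weak component}`: it is strand-closed, removing it provably
separates the strands, and it never touches nodes that are not
entangled. The remaining weak components come in strand-mirror pairs;
the retained orientation is the one whose lexicographically smallest
node sequence is smaller, an arbitrary but deterministic tie-break.

`largest_tangle` in the run report is the node-pair count of the
largest weakly connected component before any extraction, and
`largest_scc` the node-pair count of the largest non-trivial SCC
(an SCC and its strand mirror are counted once).

## Base-precise junctions

Adjacent nodes share k−1 bases, so junction coordinates in the raw
graph are ambiguous. Finalization first removes the first k−1 letters
of every node (after which path spellings lack only their global k−1
prefix), then makes merge junctions precise: where several paths meet
and none of the predecessors itself splits, the longest common suffix
of the predecessors moves onto the meeting node. When a split and a
merge sit on the two ends of one edge the situation is genuinely
ambiguous and nothing is done. Predecessors emptied by the move are
contracted (their in-edges reroute to the meeting node), except that a
*source* predecessor always keeps at least one letter — its sequence
carries the k−1 prefix that the restoration step must put back, and
contracting it would silently truncate one isoform's spelling. The
pass runs in topological order and each merge node is processed to a
local fixed point, which makes the whole operation idempotent; path
spellings are conserved exactly (this is asserted on every simulated
fixture).

Finally, in-degree-0 nodes regain their k−1 prefix and the length
filter keeps only graphs in which **every** source-to-sink path spells
more than 2k−1 bases. The filter runs after prefix restoration, i.e.
on the lengths a user actually sees in the output; single-node
assemblies extracted from tangles are held to the same floor. Repeats
spanning junctions can still shift a junction by up to the repeat
length — the longest-common-suffix rule resolves them
deterministically but cannot recover the true coordinate without read
paths, which is a known limitation.

## De novo expression

Without a reference there are no mapped reads and no exons, so the
RPKM here is *reads per kilobase of node per million assembled reads*:
for node of length `L` and library with `A` assembled reads,

    RPKM = count / ((L / 1000) · (A / 10^6))

where `count` is the number of reads of the library sharing at least
one canonical k-mer with the node (a read counts at most once per
node, but may count toward several nodes — no fractional assignment),
and `A` counts the reads sharing a k-mer with *any* retained node.
K-mers spanning an edge are attributed to the downstream node, a
deterministic convention that lets junction-spanning reads support
both sides of the junction. The denominator can be switched to total
library reads (`rpkm_denominator = "total"`), but assembled reads is
the default since it is the reference-free analogue of mapped reads.
Short nodes are systematically RPKM-inflated relative to long ones
(a read needs only one shared k-mer), which is why comparisons are
most meaningful within a node across libraries rather than across
nodes.

## The simulator

`generate_genes()` and `sample_reads()` emulate the validation design
of the method at desk scale: genes of 3–6 random exons of 100–400 bp,
a configurable fraction carrying a second isoform that skips one
internal exon, uniform read sampling to a target nucleotide coverage,
and independent per-base substitution errors at a configurable
percentage. Ground truth is the transcript set plus the 2k-mers
flanking every *alternative* exon boundary (a boundary present
identically in all isoforms compacts into a linear node and is not a
junction). Two deliberate simplifications:

* one read is anchored at each transcript end, because uniform random
  starts leave terminal k-mers uncovered with high probability at
  moderate coverage — end-anchoring emulates the fragment-end reads a
  real library contains without modelling fragmentation;
* the bases flanking an alternative boundary are forced to differ
  between the alternatives, so junctions are locally unambiguous and
  base-precise recovery is well defined. Real genomes violate this
  (repeats across junctions); the corresponding ambiguity is handled
  deterministically but counts against exact junction recovery there.

The simulator models neither indels, nor position-dependent error
rates, nor expression skew between isoforms (a weight vector would be
easy to add; uniform expression matches the validation design). A
heterozygous SNP can be planted at a chosen position with a chosen
allele fraction, which is how the SNP-merge path is exercised end to
end. All randomness flows from one seed; identical seeds reproduce
identical reads byte for byte.

Passing the bundled checks therefore shows that the algorithmic core —
compaction, cleaning, decomposition, junction arithmetic,
quantification — is exact under clean, moderately noisy conditions; it
does not show robustness to real library artefacts (adapter content,
coverage biases, indel errors, chimeric reads).

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on 20
simulated genes (≈25–30 transcripts, ≈6,000–7,000 reads of 75 bp at
20× coverage, k = 25) at 0%, 0.1% and 0.2% mismatches — small enough
to finish in well under a minute per run, large enough that every
stage (splits, merges, bubbles, tips, tangles) is exercised. Error-free
runs use `c = 0` (there is nothing to clean); error-bearing runs use
`c = 3`, the smallest cutoff used in the method's own validation
sweeps. The RPKM uniformity check uses 100× coverage, the coverage of
the validation simulations. All tie-breaks in the code (consensus
base, orientation retention, chain processing order, tip order) are
fixed and documented above, so every output — reports, FASTA, TSV — is
byte-identical across runs on identical input.

## Known limitations

* Paralogous gene families whose members differ by isolated
  substitutions look exactly like SNP bubbles and will be merged into
  a consensus; the `--no-snp-merge` escape hatch (or
  `snp_merge = FALSE`) is the current answer.
* Junction information inside extracted tangles and cyclic regions is
  discarded by design; the affected sequence survives only as
  single-node assemblies.
* Expression estimates are per node, not per isoform; isoform-level
  deconvolution is out of scope.
* The LastGraph importer targets the dialect with two sequence lines
  per `NODE` block; for nodes spelling fewer than k−1 k-mers that
  dialect does not record part of the interior sequence, and the
  importer fills the gap with `A` and warns.
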