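---
title: "Splicing-graph fusion detection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing-graph fusion detection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind SpliceFusion, every tunable
parameter with its default and rationale, the scope of the bundled
simulator, the numerical choices made where the method leaves room, and the
known limitations. Code chunks are illustrative and not evaluated when the
package is built.

## 1. The model

A fusion transcript concatenates a spliced 5′ fragment of one gene with a
spliced 3′ fragment of another. The central representation is the
**reference splicing graph**: a directed acyclic graph whose nodes are
annotated exons (deduplicated per gene, carrying sense-strand sequence) and
whose edges are annotated splice junctions. Edges never cross gene
boundaries, so each gene is a connected subgraph and every annotated
transcript is a path inside one subgraph.

Two graphs are built from the same annotation:

* the **comprehensive** graph (CRSG) over all transcripts — used for read
  alignment, because sensitivity matters there;
* the **protein-coding** graph (PRSG) over protein-coding transcripts only —
  used for validation, because fusion partners of interest are
  protein-coding genes and the smaller graph gives a stricter test.

On either graph, a read from a normal transcript aligns along a path within
one gene subgraph. A fusion read cannot: its best alignment is forced to
jump between two subgraphs. Detection therefore proceeds as a funnel:

1. align all reads to the CRSG;
2. keep reads whose path spans two or more genes;
3. filter those reads with five junction checks;
4. cluster surviving reads by gene pair, breakpoint proximity and exact
   graph path; build an error-corrected consensus per cluster;
5. validate each consensus twice — against the PRSG (are both fragments
   really from the claimed genes?) and against the linear genome (does the
   full-length consensus split into exactly two loci, with what splice
   motif?) — then refine breakpoints to annotated exon boundaries and
   assign a confidence tier.

The dual validation is the heart of the method: the two validators have
independent failure modes. Component validation on the PRSG catches
mis-assigned fragments and paralog confusion but is blind to genomic
context; structural validation on the genome catches multi-locus scatter
(a hallmark of chimeric artifacts) and reads the splice motif but knows
nothing about annotation. Agreement between the two breakpoint estimates is
itself evidence.

## 2. Parameters, defaults, and why

### Graph construction (`buildSpliceGraph`)

| parameter | default | rationale |
|---|---|---|
| `scope` | `"comprehensive"` | alignment wants every annotated exon; pass `"protein_coding"` for the validation graph |

Exons are deduplicated per gene by genomic interval; node identifiers are
`gene:chrom:start:end` with 0-based half-open coordinates, so graphs
serialize losslessly to GFA and GAF paths are self-describing.

### Graph alignment (`runGraphAlignment`)

| parameter | default | rationale |
|---|---|---|
| `k` | 15 | long-read error ~5–15% still leaves frequent exact 15-mers; shorter k explodes the candidate set |
| `min_kmers` | 3 | three co-diagonal seeds on one node chain separate signal from chance hits |
| `band` | 40 | indel drift tolerated around the median seed diagonal within a node |

The builtin aligner is a seed-and-chain heuristic: exact k-mer hits per
node, banded around the per-node median diagonal, chained along graph edges,
both read orientations scored. It is deliberately simple — the package's
contribution is everything downstream of the GAF, and any graph aligner
producing GAF can be swapped in (`align_backend = "external:<tool>"`). An
exact DP aligner (`toyGraphAlign`) is included for graphs up to ~30 nodes
and is used as the correctness oracle in the test suite.

### Candidate screening (`validateJunction`)

Five filters, each recorded per read so rejections are auditable:

| filter | default | rationale |
|---|---|---|
| structural | — | the two gene blocks must be contiguous, non-interleaved segments of the read |
| direction | — | within each block, node order must follow graph topology (splicing direction) |
| `min_block_length` | 30 bp | shorter flanks cannot anchor a junction against 10–15% error |
| junction re-alignment identity | 0.80 over ±50 bp | local identity around the junction on the implied chimeric template; 0.80 sits below the worst expected identity at 15% error but above random |
| anomaly | — | rejects reads whose two blocks re-align to overlapping query intervals (alignment artifacts) |

The junction re-alignment backend is builtin (vectorized banded
re-alignment) by default; `realign_backend = "external"` uses `minimap2 -x
splice -k 11 -w 3 -c` against a consolidated custom reference of candidate
pair templates, reading gap-compressed identity from the `de:f` tag.

### Clustering and consensus (`clusterCandidates`)

| parameter | default | rationale |
|---|---|---|
| `radius` | 100 bp | coarse single-linkage Manhattan radius on (bp5, bp3) within a gene pair; exon-level breakpoint scatter under 15% error stays well inside 100 bp, while distinct junction isoforms of the same pair lie exons apart |
| `min_support` (downstream) | 3 | three independent reads agreeing on a junction makes a chance artifact consensus improbable |

Coarse clusters are refined by exact graph-path signature, so two isoforms
sharing a breakpoint neighborhood but different exon paths become separate
events. The consensus is a star alignment against the longest member with
column-majority voting, computed per fragment (5′ and 3′); the full-length
consensus is the concatenation of the two fragment consensuses.

### Dual validation and tiering (`dualValidateClusters`)

| parameter | default | rationale |
|---|---|---|
| component identity | 0.80 | same error-rate argument as the junction filter |
| `k` (genome index) | 13 | exact 13-mers are specific in megabase-scale genomes yet frequent enough in a majority-vote consensus |
| `max_occ` | 10 | k-mers more frequent than this are repeats and dropped from the genome index |
| `max_gap` | 5000 bp | genomic anchor gaps below this are introns bridged within one locus block; above it, a separate locus |
| `min_cov` | 0.90 | the two primary blocks must jointly explain ≥ 90% of the consensus; scattered coverage means a multi-locus artifact |
| refinement `window` | 30 bp | breakpoints snap to the nearest annotated exon boundary within 30 bp; beyond that, the raw estimate is honest and kept |
| read-through gap | 100 kb | adjacent co-oriented genes within 100 kb and no intervening protein-coding gene are tiered as potential read-through |

Tier precedence is strict: artifact/read-through flags first, then **High**
(both validators pass and their breakpoints agree within the refinement
window, or the pair is genomically well-separated with one validator
passing), **Medium** (both pass, breakpoints disagree), **Low** (exactly one
passes), **Filtered** otherwise.

## 3. What the simulator emulates — and what it does not

`simulateBenchmark` generates a synthetic genome (default 4 chromosomes × 10
genes; exons 3–6 per gene, 80–300 bp; introns 150–600 bp with sense-strand
GT..AG motifs; 85% protein-coding), fusion transcripts of four types
(inter-chromosomal, intra-chromosomal, read-through of adjacent co-oriented
genes, mid-exon breakpoints), negative-control transcripts from unused
genes, and reads with an i.i.d. per-base error model (PacBio-like balanced
or ONT-like deletion-skewed mixes), random end trimming, ~50% reverse
complements, and optional template-switch chimeras that join random
transcript fragments without splice-site logic.

It deliberately does **not** emulate: homopolymer-dependent error,
base-quality correlation along a read, expression-level variation between
transcripts, genomic repeats and paralogous gene families, alternative
transcription start/end sites, or intron retention. Results on this
simulator therefore bound the method's behavior under clean conditions;
repeat-rich genomes and paralogs are where real data will be harder (see
limitations).

## 4. Numerical and design choices on open questions

Where the method description leaves room, these choices were made (each is
visible in the code and its tests):

* **Junction extrapolation by modal diagonal.** In structural validation a
  locus block can absorb an isolated off-diagonal anchor (a chance 13-mer
  hit within `max_gap` of the locus). The junction is therefore extrapolated
  from the modal anchor diagonal among anchors within 2k of the block's
  junction-side query extreme, not from block-wide coordinate extrema — a
  single spurious anchor is outvoted, and for clean blocks the formula is
  identical.
* **Breakpoint source.** When structural validation succeeds, the reported
  raw breakpoints are genome-derived (then refined); otherwise the
  graph-derived cluster breakpoints are used. The distance between the two
  estimates is reported as `breakpoint_agreement_bp` and feeds the tiering.
* **Refinement ties** resolve toward the smaller coordinate; refinement is
  idempotent (property-tested).
* **Gene-pair evaluation is unordered** — calling the partners in swapped
  roles counts as the same pair, and breakpoint scoring is role-swap aware.
* **Consensus concatenation.** The full-length consensus is the
  concatenation of the per-fragment consensuses rather than an independent
  full-read consensus; fragments are majority-corrected independently, so
  the concatenation is identical in the error regimes tested and halves the
  consensus cost.
* **Benchmark scoring** counts only reported tiers (High/Medium/Low):
  read-through-flagged and Filtered calls are what a user would discard.

## 5. Limitations

* Edges exist only within genes, so fusions whose partners fall entirely in
  unannotated loci are invisible; breakpoints inside exons are detected but
  refined only if an annotated boundary is within 30 bp.
* The builtin graph aligner is a heuristic tuned for exon-sized nodes; very
  short exons (< k) cannot seed and rely on neighboring nodes.
* The genome k-mer index drops repeats above `max_occ`; fusions whose
  junction-proximal sequence is entirely repetitive will fail structural
  validation and can reach at best the Low tier.
* Read-through flagging is positional, not biological: a genuine fusion
  between adjacent co-oriented genes is tiered `PotentialArtifact_ReadThrough`
  by design and needs orthogonal evidence.
* The simulator's i.i.d. error model understates structured long-read error;
  identity thresholds (0.80) have headroom at 15% error but were not stressed
  against homopolymer-concentrated error.
* All coordinates assume a single consistent annotation; graphs must be
  rebuilt when the annotation changes (the pipeline manifest records input
  checksums for exactly this reason).
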