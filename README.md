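# SpliceFusion

Gene fusion detection from noisy long-read RNA-seq, built on an exon-level
reference **splicing graph**.

## Why a splicing graph?

A fusion transcript is a chimera: its 5′ part is spliced from one gene and
its 3′ part from another. Aligning long reads to the linear genome makes
fusion detection fight two confounders at once — sequencing error (5–15% on
long reads) and splicing (introns appear as huge deletions). SpliceFusion
instead aligns reads to a graph whose nodes are annotated exons and whose
edges are annotated splice junctions. On this graph a normal read traces a
path inside one gene's subgraph, while a fusion read is forced to jump
between two gene subgraphs that share no edge. Fusion detection then reduces
to finding reads whose alignment path visits more than one gene, followed by
careful validation of the implied junction.

## Model and pipeline

1. **Graph construction** (`buildSpliceGraph`): from a GFF3 annotation and
   genome FASTA, build two directed acyclic graphs — the *comprehensive*
   graph (CRSG, all annotated transcripts) used for sensitive alignment, and
   the *protein-coding* graph (PRSG) used for validation. Nodes carry
   sense-strand exon sequence; edges exist only within genes. Graphs
   round-trip through GFA 1.0 (`writeGFA` / `readGFA`).
2. **Graph alignment** (`runGraphAlignment`): a k-mer seed-and-chain aligner
   places each read (either orientation) on node chains and emits GAF. An
   exact dynamic-programming oracle (`toyGraphAlign`) is included for small
   graphs, and external GAF from another aligner can be supplied instead.
3. **Candidate screening** (`findMultigeneReads`, `validateJunction`): reads
   whose path spans ≥ 2 genes pass five junction filters — structural
   consistency, path direction, minimum block length on both sides, local
   re-alignment identity around the junction (builtin vectorized
   re-aligner, or `minimap2` when available), and an anomaly filter against
   alignment artifacts.
4. **Clustering and consensus** (`clusterCandidates`): two-stage clustering
   — coarse single-linkage on breakpoint proximity (Manhattan distance
   ≤ 100 bp within a gene pair), then exact graph-path signature — followed
   by a star-alignment, column-majority consensus of the 5′ and 3′ fragments.
5. **Dual validation and tiering** (`dualValidateClusters`): each cluster
   consensus is re-validated twice, against the PRSG (component validation:
   do both fragments really come from the claimed genes?) and against the
   linear genome (structural validation: does the full-length consensus
   split into exactly two loci, and what splice motif flanks the junction?).
   Breakpoints are refined to annotated exon boundaries within 30 bp
   (`refineBreakpoint`), adjacent co-oriented pairs are flagged as potential
   transcriptional read-through, and calls are tiered
   High / Medium / Low / PotentialArtifact_ReadThrough / Filtered.

A one-call driver, `runPipeline`, runs all five stages, writes every
intermediate (GFA, GAF, candidate table, calls as TSV and JSON) plus a
manifest with input checksums and a read funnel. A command-line interface
with the same stages ships in `inst/scripts/splicefusion.R`.

The package also contains the full benchmark used to characterize accuracy:
a fusion transcriptome simulator (`simConfig`, `simulateBenchmark`,
`simulateReads`) with inter-/intra-chromosomal, read-through and mid-exon
fusion types, platform error profiles and template-switch chimera injection,
plus gene-pair and breakpoint-level scoring (`evaluateCalls`) and a
multi-condition grid driver (`runBenchmarkGrid`).

## Worked example

Simulate a small fusion transcriptome (2 chromosomes × 6 genes, 4 fusions
plus negative controls, 8× depth, 8% error) and run the full pipeline:

```r
library(SpliceFusion)

cfg <- simConfig(seed = 7, n_chromosomes = 2, genes_per_chromosome = 6,
                 n_fusions = 4, n_negative = 4, depth = 8, error_rate = 0.08,
                 fusion_mix = c(inter = 0.5, intra = 0.5,
                                readthrough = 0, midexon = 0))
bench <- simulateBenchmark(cfg)
reads <- simulateReads(c(bench$fusion_seqs, bench$neg_seqs),
                       depth = cfg$depth, error_rate = cfg$error_rate,
                       seed = 99)

res <- runPipeline(bench$genome, bench$gff3, reads,
                   workdir = tempfile("sfrun"),
                   config = pipelineConfig(seed = 5))
#> [1/5] building splicing graphs
#>       12 genes, 49 exon nodes
#> [2/5] aligning 64 reads to the graph
#>       96 records / 64 reads aligned
#> [3/5] screening multigene alignments
#>       32 candidate reads, 32 pass the junction filters
#> [4/5] clustering candidates
#>       4 clusters (4 with >= 3 reads)
#> [5/5] dual validation and confidence tiering
#>       4 fusion call(s)

cols <- c("gene5", "gene3", "chrom5", "bp5", "chrom3", "bp3",
          "n_supporting_reads", "splice_motif", "tier")
print(res$calls[, cols], row.names = FALSE)
#>  gene5 gene3 chrom5   bp5 chrom3   bp3 n_supporting_reads splice_motif tier
#>   G002  G006   chr1 11792   chr1 36924                  8        GT-AG High
#>   G002  G008   chr1 11792   chr2 10542                  8        GT-AG High
#>   G007  G011   chr2  5204   chr2 31892                  8        GT-AG High
#>   G012  G006   chr2 37669   chr1 36924                  8        GT-AG High

metrics <- evaluateCalls(res$calls, bench$truth)
cat(sprintf("gene-pair F1 = %.2f, strict breakpoint F1 = %.2f\n",
            metrics$gene_pair$f1, metrics$strict$f1))
#> gene-pair F1 = 1.00, strict breakpoint F1 = 1.00
```

All four simulated fusions are recovered with exact breakpoints and
canonical splice motifs at the refined junctions.

The same run from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/splicefusion.R", package="SpliceFusion"))') \
    run --genome genome.fa --gff3 annotation.gff3 --reads reads.fq --workdir out/
```

## Documentation

Every exported function carries roxygen documentation; the methods vignette
(`vignettes/splicing-graph-fusion-detection.Rmd`) describes the model, all
tunable parameters and their defaults, what the simulator does and does not
emulate, and known limitations.
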