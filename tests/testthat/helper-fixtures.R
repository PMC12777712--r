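# Shared fixtures, built lazily once per test run and memoized.

.fx <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# Small benchmark: 2 chromosomes x 6 genes, 4 exon-boundary fusions.
smallBench <- function() memo("smallBench", function() {
  cfg <- simConfig(seed = 7, n_fusions = 4, n_chromosomes = 2,
                   genes_per_chromosome = 6, depth = 8, error_rate = 0.08,
                   n_negative = 4,
                   fusion_mix = c(inter = 0.5, intra = 0.5,
                                  readthrough = 0, midexon = 0))
  b <- simulateBenchmark(cfg)
  b$cfg <- cfg
  b$genes_parsed <- parseAnnotation(b$gff3, b$genome)
  b$crsg <- buildSpliceGraph(b$genes_parsed, genome = b$genome)
  b$prsg <- buildSpliceGraph(b$genes_parsed, scope = "protein_coding",
                             genome = b$genome)
  b$reads <- simulateReads(c(b$fusion_seqs, b$neg_seqs), depth = cfg$depth,
                           error_rate = cfg$error_rate, seed = 99)
  b
})

# Candidate reads of the small benchmark after graph alignment + screening.
smallCandidates <- function() memo("smallCandidates", function() {
  b <- smallBench()
  gaf_path <- tempfile(fileext = ".gaf")
  runGraphAlignment(b$reads, b$crsg, out = gaf_path)
  list(gaf = parseGaf(gaf_path),
       cand = findMultigeneReads(parseGaf(gaf_path), b$crsg))
})

smallValidated <- function() memo("smallValidated", function() {
  b <- smallBench()
  sc <- smallCandidates()
  validateJunction(sc$cand, b$reads, b$crsg)
})

# A tiny hand-made two-gene annotation on one small genome, for precise
# structural assertions. Gene A (+ strand, 3 exons), gene B (- strand,
# 2 exons), placed far apart on one chromosome.
tinyTwoGene <- function() memo("tinyTwoGene", function() {
  withSeed(5, {
    rand <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
    # gene A exons at [100,200) [300,420) [500,560), introns GT..AG (+)
    # gene B exons at [7000,7150) [7400,7520), intron CT..AC (- strand)
    chr <- paste0(
      rand(100),                                    # 0..100
      rand(100),                                    # exon A1 100..200
      "GT", rand(96), "AG",                         # intron 200..300
      rand(120),                                    # exon A2 300..420
      "GT", rand(76), "AG",                         # intron 420..500
      rand(60),                                     # exon A3 500..560
      rand(6440),                                   # intergenic 560..7000
      rand(150),                                    # exon B2 7000..7150
      "CT", rand(246), "AC",                        # intron(-) 7150..7400
      rand(120),                                    # exon B1 7400..7520
      rand(80))                                     # tail 7520..7600
    genome <- Biostrings::DNAStringSet(c(chrT = chr))
    gff <- c(
      "##gff-version 3",
      "chrT\tx\tgene\t101\t560\t.\t+\t.\tID=GA;gene_type=protein_coding",
      "chrT\tx\ttranscript\t101\t560\t.\t+\t.\tID=GA.t1;Parent=GA",
      "chrT\tx\texon\t101\t200\t.\t+\t.\tParent=GA.t1",
      "chrT\tx\texon\t301\t420\t.\t+\t.\tParent=GA.t1",
      "chrT\tx\texon\t501\t560\t.\t+\t.\tParent=GA.t1",
      "chrT\tx\tgene\t7001\t7520\t.\t-\t.\tID=GB;gene_type=protein_coding",
      "chrT\tx\ttranscript\t7001\t7520\t.\t-\t.\tID=GB.t1;Parent=GB",
      "chrT\tx\texon\t7001\t7150\t.\t-\t.\tParent=GB.t1",
      "chrT\tx\texon\t7401\t7520\t.\t-\t.\tParent=GB.t1")
    gp <- tempfile(fileext = ".gff3")
    writeLines(gff, gp)
    genes <- parseAnnotation(gp, genome)
    list(genome = genome, gff3 = gp, genes = genes,
         graph = buildSpliceGraph(genes, genome = genome))
  })
})

# Pure-R brute-force oracle for the toy aligner: minimal semiglobal edit
# distance of a read (both orientations) over the concatenated sequence of
# every maximal path of the graph.
bruteForceBestDist <- function(read, graph) {
  paths <- SpliceFusion:::enumerateMaximalPaths(graph)
  seqs <- stats::setNames(graphNodes(graph)$seq, graphNodes(graph)$node_id)
  semiglobal <- function(q, s) {
    qn <- nchar(q); sn <- nchar(s)
    qc <- strsplit(q, "")[[1L]]
    sc <- strsplit(s, "")[[1L]]
    prev <- rep(0L, sn + 1L)              # free leading gaps on the subject
    for (i in seq_len(qn)) {
      cur <- integer(sn + 1L)
      cur[1L] <- i
      for (j in seq_len(sn)) {
        cur[j + 1L] <- min(prev[j] + (qc[i] != sc[j]),
                           prev[j + 1L] + 1L, cur[j] + 1L)
      }
      prev <- cur
    }
    min(prev)                             # free trailing gaps on the subject
  }
  best <- Inf
  for (p in paths) {
    s <- paste(seqs[p], collapse = "")
    best <- min(best, semiglobal(read, s), semiglobal(revComp(read), s))
  }
  best
}

# O(n^2) transitive-closure oracle for coarse clustering.
coarseOracle <- function(candidates, radius) {
  n <- nrow(candidates)
  if (!n) return(integer())
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (lab[i] == lab[j]) next
      if (candidates$gene5[i] != candidates$gene5[j] ||
          candidates$gene3[i] != candidates$gene3[j]) next
      d <- abs(candidates$bp5[i] - candidates$bp5[j]) +
        abs(candidates$bp3[i] - candidates$bp3[j])
      if (d <= radius) {
        m <- min(lab[i], lab[j])
        lab[lab == lab[i] | lab == lab[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# Compare two clusterings up to label renaming.
samePartition <- function(a, b) {
  length(a) == length(b) &&
    identical(match(a, unique(a)), match(b, unique(b)))
}

# Independent rule-table oracle for the confidence classifier.
classifyOracle <- function(ev, lay, artifact_hit, window = 30L,
                           rt_gap = 1e5) {
  rt <- isTRUE(lay$same_chrom) && isTRUE(lay$co_oriented) &&
    !isTRUE(lay$intervening_pc) && !is.na(lay$gap_bp) && lay$gap_bp <= rt_gap
  if (artifact_hit || rt) return("PotentialArtifact_ReadThrough")
  d_prsg <- isTRUE(ev$prsg_ok5) && isTRUE(ev$prsg_ok3)
  d_gen <- isTRUE(ev$genome_ok)
  dual <- d_prsg && d_gen
  agree <- !is.na(ev$agreement_bp) && ev$agreement_bp < window
  sep <- !isTRUE(lay$same_chrom) ||
    (!is.na(lay$gap_bp) && lay$gap_bp > rt_gap) || isTRUE(lay$intervening_pc)
  if (dual && agree) return("High")
  if (sep && (d_prsg || d_gen)) return("High")
  if (dual) return("Medium")
  if (xor(d_prsg, d_gen)) return("Low")
  "Filtered"
}
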