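test_that("P1 core: classifier matches the rule-table oracle exhaustively", {
  tf <- c(TRUE, FALSE)
  combos <- expand.grid(ok5 = tf, ok3 = tf, gok = tf,
                        agreement = c(0L, 29L, 30L, 120L, NA_integer_),
                        same = tf, co = tf, ipc = tf,
                        gap = c(NA, 0, 4648, 1e5, 2e5),
                        art = tf, stringsAsFactors = FALSE)
  # gap is NA exactly when the pair spans chromosomes
  combos <- combos[is.na(combos$gap) == !combos$same, ]
  expect_gt(nrow(combos), 500L)
  for (i in seq_len(nrow(combos))) {
    x <- combos[i, ]
    ev <- list(prsg_ok5 = x$ok5, prsg_ok3 = x$ok3, genome_ok = x$gok,
               agreement_bp = x$agreement)
    lay <- list(same_chrom = x$same, co_oriented = x$co,
                gap_bp = x$gap, intervening_pc = x$ipc)
    expect_identical(classifyConfidence(ev, lay, artifact_hit = x$art),
                     classifyOracle(ev, lay, x$art),
                     info = paste(unlist(x), collapse = "/"))
  }
})

test_that("P4 core: breakpoint refinement idempotence and window semantics", {
  withSeed(77, {
    for (rep in 1:50) {
      boundaries <- sort(sample.int(10000, sample(2:30, 1)))
      raw <- sample.int(10000, 1)
      window <- sample(c(0L, 5L, 30L, 100L), 1)
      r1 <- refineBreakpoint(raw, boundaries, window)
      # within-window snap lands on a boundary; otherwise raw is kept
      d <- min(abs(boundaries - raw))
      if (d <= window) {
        expect_true(r1$pos %in% boundaries)
        expect_lte(abs(r1$pos - raw), window)
        expect_identical(r1$shifted, d > 0L)
      } else {
        expect_identical(r1$pos, raw)
        expect_false(r1$shifted)
      }
      # idempotence
      r2 <- refineBreakpoint(r1$pos, boundaries, window)
      expect_identical(r2$pos, r1$pos)
      expect_false(r2$shifted)
    }
  })
  # equidistant tie resolves to the smaller coordinate
  expect_equal(refineBreakpoint(15L, c(10L, 20L), 30L)$pos, 10L)
  # empty boundary set is a no-op
  expect_equal(refineBreakpoint(5L, integer(), 30L)$pos, 5L)
})

test_that("exonBoundaries reports 1-based starts and ends", {
  tg <- tinyTwoGene()
  expect_equal(exonBoundaries(tg$graph, "GA"),
               c(101L, 200L, 301L, 420L, 501L, 560L))
})

test_that("component validation accepts true partners and rejects wrong ones", {
  tg <- tinyTwoGene()
  rp <- SpliceFusion:::refPaths(tg$graph)
  seqA <- as.character(rp$seqs[["GA.t1"]])
  seqB <- as.character(rp$seqs[["GB.t1"]])
  cv <- componentValidate(seqA, seqB, tg$graph, "GA", "GB")
  expect_true(cv$prsg_ok5)
  expect_true(cv$prsg_ok3)
  expect_identical(cv$matched5, "GA")
  # expecting the wrong gene fails even with a perfect sequence
  cw <- componentValidate(seqA, seqB, tg$graph, "GB", "GA")
  expect_false(cw$prsg_ok5)
  expect_false(cw$prsg_ok3)
  expect_error(componentValidate("", seqB, tg$graph, "GA", "GB"),
               "empty consensus")
})

test_that("structural validation locates a constructed chimera with GT-AG", {
  tg <- tinyTwoGene()
  nodes <- graphNodes(tg$graph)
  # 5' part: GA exons 1-2 (breakpoint at 420, donor GT at 421-422);
  # 3' part: GB exon GB:7000:7150 (sense; acceptor AG upstream on - strand)
  part5 <- paste(nodes$seq[match(c("GA:chrT:100:200", "GA:chrT:300:420"),
                                 nodes$node_id)], collapse = "")
  part3 <- nodes$seq[nodes$node_id == "GB:chrT:7000:7150"]
  sv <- structuralValidate(paste0(part5, part3), tg$genome)
  expect_true(sv$genome_ok)
  expect_identical(sv$chrom5, "chrT")
  expect_identical(sv$chrom3, "chrT")
  # the raw junction can be off by a few bases when flanking genomic
  # sequence happens to extend a block across the junction ...
  expect_lte(abs(sv$bp5 - 420L), 3L)
  expect_lte(abs(sv$bp3 - 7150L), 3L)
  # ... which is exactly what refinement recovers, after which the splice
  # motif is canonical
  bp5 <- refineBreakpoint(sv$bp5, exonBoundaries(tg$graph, "GA"), 30L)$pos
  bp3 <- refineBreakpoint(sv$bp3, exonBoundaries(tg$graph, "GB"), 30L)$pos
  expect_equal(bp5, 420L)
  expect_equal(bp3, 7150L)
  m <- spliceMotif(tg$genome, "chrT", bp5, sv$orient5, "chrT", bp3,
                   sv$orient3)
  expect_identical(m$motif, "GT-AG")
  expect_identical(m$canonical, "canonical")
})

test_that("structural validation rejects a single-locus sequence", {
  tg <- tinyTwoGene()
  nodes <- graphNodes(tg$graph)
  mono <- paste(nodes$seq[nodes$gene_id == "GA"], collapse = "")
  sv <- structuralValidate(mono, tg$genome)
  expect_false(sv$genome_ok)
})

test_that("dual validation tiers simulated fusions High with zero shift", {
  b <- smallBench()
  v <- smallValidated()
  cl <- clusterCandidates(v[v$pass, ], b$reads)
  calls <- dualValidateClusters(cl, b$prsg, b$crsg, b$genome)
  expect_equal(nrow(calls), nrow(b$truth))
  key <- function(a, b2) paste(pmin(a, b2), pmax(a, b2))
  m <- match(key(calls$gene5, calls$gene3), key(b$truth$gene5,
                                                b$truth$gene3))
  expect_false(anyNA(m))
  expect_true(all(calls$bp5 == b$truth$bp5[m]))
  expect_true(all(calls$bp3 == b$truth$bp3[m]))
  expect_true(all(calls$tier == "High"))
  expect_true(all(calls$n_supporting_reads >= 3))
})

test_that("min_support filters weak clusters", {
  b <- smallBench()
  v <- smallValidated()
  cl <- clusterCandidates(v[v$pass, ], b$reads)
  calls <- dualValidateClusters(cl, b$prsg, b$crsg, b$genome,
                                min_support = max(cl$n_reads) + 1L)
  expect_equal(nrow(calls), 0L)
  expect_true(all(c("gene5", "bp5", "tier") %in% names(calls)))
})

test_that("artifact list forces the artifact tier regardless of evidence", {
  b <- smallBench()
  v <- smallValidated()
  cl <- clusterCandidates(v[v$pass, ], b$reads)
  af <- tempfile()
  writeLines(paste(cl$gene3[1], cl$gene5[1], sep = "\t"), af)  # reversed!
  calls <- dualValidateClusters(cl, b$prsg, b$crsg, b$genome,
                                artifact_pairs = readArtifactList(af))
  hit <- calls$gene5 == cl$gene5[1] & calls$gene3 == cl$gene3[1]
  expect_true(all(calls$tier[hit] == "PotentialArtifact_ReadThrough"))
  expect_true(all(calls$artifact_db_hit[hit]))
})

test_that("simulated read-through pairs satisfy the read-through predicate", {
  cfg <- simConfig(seed = 31, n_fusions = 3,
                   fusion_mix = c(inter = 0, intra = 0, readthrough = 1,
                                  midexon = 0), depth = 4,
                   error_rate = 0.05, n_negative = 2)
  bench <- simulateBenchmark(cfg)
  genes <- parseAnnotation(bench$gff3, bench$genome)
  g <- buildSpliceGraph(genes, genome = bench$genome)
  for (i in seq_len(nrow(bench$truth))) {
    lay <- SpliceFusion:::geneLayout(geneMeta(g), bench$truth$gene5[i],
                                     bench$truth$gene3[i])
    tier <- classifyConfidence(
      list(prsg_ok5 = TRUE, prsg_ok3 = TRUE, genome_ok = TRUE,
           agreement_bp = 0L), lay)
    expect_identical(tier, "PotentialArtifact_ReadThrough")
  }
})

test_that("writeCalls produces ordered TSV and JSON with consensus", {
  b <- smallBench()
  v <- smallValidated()
  cl <- clusterCandidates(v[v$pass, ], b$reads)
  calls <- dualValidateClusters(cl, b$prsg, b$crsg, b$genome)
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  writeCalls(calls, tsv, js)
  tab <- utils::read.table(tsv, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expect_equal(nrow(tab), nrow(calls))
  expect_false(any(c("cons5", "cons3", "consFull") %in% names(tab)))
  j <- jsonlite::read_json(js)
  expect_equal(length(j), nrow(calls))
  expect_true(all(vapply(j, function(x)
    !is.null(x$consFull) && nzchar(x$consFull), logical(1))))
})
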