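test_that("P3 core: toy aligner equals brute force on the tiny graph", {
  tg <- tinyTwoGene()
  g1 <- buildSpliceGraph(tg$genes["GA"], genome = tg$genome)
  expect_lte(nrow(graphNodes(g1)), 12L)
  rp <- SpliceFusion:::refPaths(g1)
  tx <- rp$seqs[[1]]
  withSeed(31, {
    for (i in 1:5) {
      a <- sample.int(nchar(tx) - 60L, 1L)
      r <- substr(tx, a, a + 59L)
      if (i %% 2 == 0) r <- revComp(r)
      toy <- toyGraphAlign(r, g1)
      expect_identical(toy$edit_dist, as.integer(bruteForceBestDist(r, g1)))
    }
  })
})

test_that("toy aligner refuses oversized graphs with a clear error", {
  b <- smallBench()
  expect_error(toyGraphAlign("ACGT", b$crsg, max_nodes = 5L),
               "external graph-alignment backend")
})

test_that("builtin aligner recovers transcript paths from clean reads", {
  tg <- tinyTwoGene()
  rp <- SpliceFusion:::refPaths(tg$graph)
  reads <- stats::setNames(as.character(rp$seqs), names(rp$seqs))
  out <- tempfile(fileext = ".gaf")
  runGraphAlignment(reads, tg$graph, out = out)
  gaf <- parseGaf(out)
  expect_setequal(gaf$read_id, names(reads))
  for (i in seq_len(nrow(gaf))) {
    nodes <- gafPath(gaf$path[i])$node
    truthChain <- txPaths(tg$graph)$nodes[[
      which(txPaths(tg$graph)$tx_id == gaf$read_id[i])]]
    expect_identical(nodes, truthChain)
  }
})

test_that("builtin aligner handles reverse-complemented noisy reads", {
  tg <- tinyTwoGene()
  rp <- SpliceFusion:::refPaths(tg$graph)
  tx <- as.character(rp$seqs[["GA.t1"]])
  read <- withSeed(8, SpliceFusion:::.mutateSeq(revComp(tx), 0.1,
                                                c(sub = 1, ins = 1,
                                                  del = 1) / 3))
  out <- tempfile(fileext = ".gaf")
  runGraphAlignment(c(r1 = read), tg$graph, out = out)
  gaf <- parseGaf(out)
  expect_equal(nrow(gaf), 1L)
  expect_true(all(gafPath(gaf$path)$node %in%
                    graphNodes(tg$graph)$node_id[
                      graphNodes(tg$graph)$gene_id == "GA"]))
})

test_that("readReads handles FASTA, FASTQ, vectors and empty files", {
  v <- c(a = "ACGT", b = "GGCC")
  expect_identical(readReads(v), v)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a desc", "ACGT", ">b", "GGCC"), fa)
  expect_identical(readReads(fa), v)
  fq <- tempfile(fileext = ".fq")
  writeLines(c("@a", "ACGT", "+", "IIII", "@b", "GGCC", "+", "IIII"), fq)
  expect_identical(readReads(fq), v)
  ef <- tempfile()
  file.create(ef)
  expect_length(readReads(ef), 0L)
  expect_error(readReads(tempfile()), "not found")
})

test_that("missing external graph aligner gives an actionable error", {
  tg <- tinyTwoGene()
  expect_error(
    runGraphAlignment(c(r = "ACGTACGT"), tg$graph,
                      backend = "external:definitely-not-a-binary"),
    "not found on PATH")
})

test_that("exact backend writes valid GAF", {
  tg <- tinyTwoGene()
  g1 <- buildSpliceGraph(tg$genes["GA"], genome = tg$genome)
  rp <- SpliceFusion:::refPaths(g1)
  r <- substr(as.character(rp$seqs[[1]]), 10, 150)
  out <- tempfile(fileext = ".gaf")
  runGraphAlignment(c(q = r), g1, out = out, backend = "exact")
  gaf <- parseGaf(out)
  expect_equal(nrow(gaf), 1L)
  expect_equal(gaf$read_id, "q")
  expect_gt(nrow(gafPath(gaf$path)), 0L)
})
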