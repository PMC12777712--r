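test_that("tiny two-gene annotation builds the expected graph", {
  tg <- tinyTwoGene()
  g <- tg$graph
  nodes <- graphNodes(g)
  edges <- graphEdges(g)
  expect_s4_class(g, "SpliceGraph")
  expect_equal(nrow(nodes), 5L)        # 3 exons of GA + 2 of GB
  expect_equal(nrow(edges), 3L)        # 2 splice edges in GA + 1 in GB
  expect_setequal(unique(nodes$gene_id), c("GA", "GB"))
  # 0-based half-open coordinates preserved from the 1-based GFF3
  a1 <- nodes[nodes$node_id == "GA:chrT:100:200", ]
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$end - a1$start, 100L)
  expect_equal(nchar(a1$seq), 100L)
})

test_that("minus-strand node sequences are reverse-complemented", {
  tg <- tinyTwoGene()
  nodes <- graphNodes(tg$graph)
  b1 <- nodes[nodes$gene_id == "GB" & nodes$start == 7400, ]
  genomic <- extractSeq <- as.character(
    Biostrings::subseq(tg$genome[["chrT"]], 7401, 7520))
  expect_equal(b1$seq, revComp(genomic))
  # plus-strand nodes keep the genomic sequence
  a1 <- nodes[nodes$gene_id == "GA" & nodes$start == 100, ]
  expect_equal(a1$seq,
               as.character(Biostrings::subseq(tg$genome[["chrT"]], 101,
                                               200)))
})

test_that("minus-strand transcript paths run in transcription order", {
  tg <- tinyTwoGene()
  tx <- txPaths(tg$graph)
  chain <- tx$nodes[[which(tx$tx_id == "GB.t1")]]
  # transcription order on the minus strand: genomically last exon first
  expect_equal(chain, c("GB:chrT:7400:7520", "GB:chrT:7000:7150"))
  # concatenating path node sequences yields the spliced mRNA
  nodes <- graphNodes(tg$graph)
  mrna <- paste(nodes$seq[match(chain, nodes$node_id)], collapse = "")
  expected <- revComp(paste0(
    as.character(Biostrings::subseq(tg$genome[["chrT"]], 7001, 7150)),
    as.character(Biostrings::subseq(tg$genome[["chrT"]], 7401, 7520))))
  expect_equal(mrna, expected)
})

test_that("no edges cross genes and the graph is a DAG", {
  b <- smallBench()
  nodes <- graphNodes(b$crsg)
  edges <- graphEdges(b$crsg)
  gene_of <- stats::setNames(nodes$gene_id, nodes$node_id)
  expect_true(all(gene_of[edges$from] == gene_of[edges$to]))
  # DAG property is enforced by the class validity; constructing a cyclic
  # graph must fail
  cyc <- b$crsg
  expect_error({
    cyc@edges <- rbind(cyc@edges,
                       data.frame(from = cyc@edges$to[1],
                                  to = cyc@edges$from[1],
                                  stringsAsFactors = FALSE))
    methods::validObject(cyc)
  }, "cycle|acyclic|DAG")
})

test_that("protein_coding scope excludes non-coding genes", {
  b <- smallBench()
  bios <- vapply(b$genes_parsed, function(g) g$biotype, "")
  nc <- names(bios)[bios != "protein_coding"]
  if (length(nc)) {
    expect_false(any(graphNodes(b$prsg)$gene_id %in% nc))
    expect_true(any(graphNodes(b$crsg)$gene_id %in% nc))
  }
  expect_identical(graphScope(b$prsg), "protein_coding")
  expect_identical(graphScope(b$crsg), "comprehensive")
})

test_that("geneOfNode resolves ids and rejects unknown nodes", {
  tg <- tinyTwoGene()
  hit <- geneOfNode(tg$graph, "GA:chrT:100:200")
  expect_identical(hit$gene_id, "GA")
  expect_identical(hit$node$node_id, "GA:chrT:100:200")
  expect_error(geneOfNode(tg$graph, "nope"), "unknown node_id")
})

test_that("buildSpliceGraph rejects empty inputs", {
  tg <- tinyTwoGene()
  expect_error(buildSpliceGraph(list(), genome = tg$genome), "empty|no gene")
})

test_that("parseAnnotation flags missing chromosomes and skips orphans", {
  tg <- tinyTwoGene()
  bad <- sub("chrT", "chrX", readLines(tg$gff3))
  bp <- tempfile(fileext = ".gff3")
  writeLines(bad, bp)
  expect_error(parseAnnotation(bp, tg$genome), "absent from the genome")
  orphan <- c(readLines(tg$gff3),
              "chrT\tx\texon\t10\t20\t.\t+\t.\tParent=GHOST.t1")
  op <- tempfile(fileext = ".gff3")
  writeLines(orphan, op)
  expect_warning(genes <- parseAnnotation(op, tg$genome),
                 "unresolv|skip|orphan|parent")
  expect_setequal(names(genes), c("GA", "GB"))
})
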