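test_that("breakpoint max/min rule on the plus-strand partner", {
  tg <- tinyTwoGene()
  g <- tg$graph
  # GA (+): exons [100,200) [300,420) [500,560)
  fwd <- ">GA:chrT:100:200>GA:chrT:300:420"
  expect_equal(partnerBreakpoint(g, fwd, "5p"), 420L)  # max end, forward
  expect_equal(partnerBreakpoint(g, fwd, "3p"), 101L)  # min start, forward
  rev <- "<GA:chrT:300:420<GA:chrT:100:200"
  expect_equal(partnerBreakpoint(g, rev, "5p"), 101L)  # min start, reverse
  expect_equal(partnerBreakpoint(g, rev, "3p"), 420L)  # max end, reverse
})

test_that("breakpoint rule respects minus-strand transcription direction", {
  tg <- tinyTwoGene()
  g <- tg$graph
  # GB (-): transcription order GB:7400:7520 then GB:7000:7150. A '>'
  # traversal follows transcription, i.e. genomic descent -> not forward.
  sense <- ">GB:chrT:7400:7520>GB:chrT:7000:7150"
  expect_equal(partnerBreakpoint(g, sense, "5p"), 7001L)
  expect_equal(partnerBreakpoint(g, sense, "3p"), 7520L)
})

test_that("assignPartnerOrder handles sense and antisense reads", {
  tg <- tinyTwoGene()
  g <- tg$graph
  segs <- data.frame(
    gene = c("GA", "GB"),
    path = c(">GA:chrT:100:200>GA:chrT:300:420",
             ">GB:chrT:7400:7520"),
    query_start = c(0L, 220L), query_end = c(220L, 340L),
    orient = c(">", ">"), stringsAsFactors = FALSE)
  a <- assignPartnerOrder(g, segs, 340L)
  expect_identical(a$gene5, "GA")
  expect_identical(a$gene3, "GB")
  expect_identical(a$read_orient, "+")
  expect_true(a$dir_consistent)
  expect_equal(a$bp5, 420L)
  expect_equal(a$bp3, 7520L)
  # the same fusion read, reverse-complemented: segments swap on the read
  # and traverse the graph backwards
  segs_rc <- data.frame(
    gene = c("GB", "GA"),
    path = c("<GB:chrT:7400:7520",
             "<GA:chrT:300:420<GA:chrT:100:200"),
    query_start = c(0L, 120L), query_end = c(120L, 340L),
    orient = c("<", "<"), stringsAsFactors = FALSE)
  b <- assignPartnerOrder(g, segs_rc, 340L)
  expect_identical(b$gene5, "GA")
  expect_identical(b$gene3, "GB")
  expect_identical(b$read_orient, "-")
  expect_equal(b$bp5, 420L)
  expect_equal(b$bp3, 7520L)
  # sense-canonicalised paths match the forward representation
  expect_identical(b$path5, a$path5)
  expect_identical(b$path3, a$path3)
  # oriented query intervals flip onto the sense read
  expect_equal(unname(b$q5), c(0L, 220L))
  expect_equal(unname(b$q3), c(220L, 340L))
})

test_that("screening finds every simulated fusion pair", {
  b <- smallBench()
  sc <- smallCandidates()
  got <- unique(paste(sc$cand$gene5, sc$cand$gene3))
  want <- paste(b$truth$gene5, b$truth$gene3)
  expect_true(all(want %in% got))
  # graph-derived breakpoints agree with truth (exon-boundary fusions)
  key <- paste(sc$cand$gene5, sc$cand$gene3)
  for (i in seq_len(nrow(b$truth))) {
    rows <- sc$cand[key == want[i], ]
    expect_gt(nrow(rows), 0L)
    expect_true(any(rows$bp5 == b$truth$bp5[i] &
                      rows$bp3 == b$truth$bp3[i]))
  }
})

test_that("single-gene reads never become candidates", {
  b <- smallBench()
  sc <- smallCandidates()
  neg_ids <- names(b$reads)[grepl(paste0("^(",
    paste(sub("\\.t1$", "", names(b$neg_seqs)), collapse = "|"), ")"),
    names(b$reads))]
  expect_false(any(sc$cand$read_id %in% neg_ids))
})

test_that("junction filters enforce their thresholds", {
  b <- smallBench()
  sc <- smallCandidates()
  v <- validateJunction(sc$cand, b$reads, b$crsg)
  expect_true(all(c("f_structural", "f_direction", "f_min_block_length",
                    "f_junction", "f_anomaly", "pass",
                    "reject_reason") %in% names(v)))
  expect_true(all(v$pass == (v$f_structural & v$f_direction &
                               v$f_min_block_length & v$f_junction &
                               v$f_anomaly)))
  expect_true(all(is.na(v$reject_reason[v$pass])))
  # an absurd block-length threshold rejects everything with that label
  v2 <- validateJunction(sc$cand, b$reads, b$crsg, min_block_len = 10000L)
  expect_false(any(v2$pass))
  expect_true(all(v2$reject_reason %in%
                    c("structural", "direction", "min_block_length",
                      "junction", "anomaly")))
  expect_true(any(v2$reject_reason == "min_block_length"))
  # zero junction slack rejects junction-gapped candidates
  v3 <- validateJunction(sc$cand, b$reads, b$crsg, junction_slack = 0L)
  expect_lte(sum(v3$pass), sum(v$pass))
  # impossible identity threshold trips the anomaly filter
  v4 <- validateJunction(sc$cand, b$reads, b$crsg, min_identity = 1.01)
  expect_true(all(v4$reject_reason[!v4$pass] == "anomaly" |
                    v4$reject_reason[!v4$pass] %in%
                      c("structural", "direction", "min_block_length",
                        "junction")))
  expect_false(any(v4$pass))
})

test_that("external re-alignment backend agrees with the builtin", {
  b <- smallBench()
  sc <- smallCandidates()
  vb <- validateJunction(sc$cand, b$reads, b$crsg, backend = "builtin")
  ve <- validateJunction(sc$cand, b$reads, b$crsg, backend = "external",
                         genome = b$genome)
  expect_gte(sum(ve$pass), 0.8 * sum(vb$pass))
})

test_that("missing external re-aligner errors out usefully", {
  b <- smallBench()
  sc <- smallCandidates()
  expect_error(
    validateJunction(sc$cand[1, ], b$reads, b$crsg,
                     backend = "external:no-such-aligner",
                     genome = b$genome),
    "not found")
})

test_that("custom reference records encode pair, role and gene", {
  b <- smallBench()
  pairs <- unique(data.frame(gene5 = b$truth$gene5, gene3 = b$truth$gene3,
                             stringsAsFactors = FALSE))
  p <- buildCustomReference(pairs, b$genome, geneMeta(b$crsg),
                            path = tempfile(fileext = ".fa"))
  ref <- readReads(p)
  expect_equal(length(ref), 2L * nrow(pairs))
  expect_true(all(grepl("^pair[0-9]+\\|(5p|3p)\\|", names(ref))))
})

test_that("empty GAF input yields typed empty candidates", {
  b <- smallBench()
  empty <- parseGaf(character())
  cand <- findMultigeneReads(empty, b$crsg)
  expect_equal(nrow(cand), 0L)
  v <- validateJunction(cand, b$reads, b$crsg)
  expect_equal(nrow(v), 0L)
  expect_true(all(c("pass", "reject_reason") %in% names(v)))
})
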