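test_that("P2 core: coarse clustering matches the transitive-closure oracle", {
  withSeed(1234, {
    for (rep in 1:20) {
      n <- sample(2:40, 1)
      cand <- data.frame(
        gene5 = sample(c("A", "B", "C"), n, replace = TRUE),
        gene3 = sample(c("X", "Y"), n, replace = TRUE),
        bp5 = sample.int(2000, n, replace = TRUE),
        bp3 = sample.int(2000, n, replace = TRUE),
        stringsAsFactors = FALSE)
      radius <- sample(c(10L, 100L, 400L), 1)
      got <- coarseCluster(cand, radius)
      want <- coarseOracle(cand, radius)
      expect_true(samePartition(got, want),
                  info = sprintf("rep %d n %d radius %d", rep, n, radius))
    }
  })
})

test_that("coarse clustering never crosses gene pairs", {
  cand <- data.frame(gene5 = c("A", "A", "B"), gene3 = c("X", "X", "X"),
                     bp5 = c(100L, 100L, 100L), bp3 = c(50L, 50L, 50L),
                     stringsAsFactors = FALSE)
  cl <- coarseCluster(cand, radius = 100L)
  expect_equal(cl[1], cl[2])
  expect_false(cl[1] == cl[3])
})

test_that("fine clustering separates distinct isoform paths", {
  cand <- data.frame(
    gene5 = "A", gene3 = "X",
    path5 = c(">n1>n2", ">n1>n2", ">n1"),
    path3 = ">m1", bp5 = 100L, bp3 = 50L, stringsAsFactors = FALSE)
  coarse <- coarseCluster(cand, 100L)
  expect_true(all(coarse == coarse[1]))
  fine <- fineCluster(cand, coarse)
  expect_equal(length(unique(fine)), 2L)
  expect_equal(fine[1], fine[2])
  expect_false(fine[1] == fine[3])
})

test_that("star consensus corrects i.i.d. errors across cluster sizes", {
  truthSeq <- withSeed(2, paste(sample(c("A", "C", "G", "T"), 400,
                                       replace = TRUE), collapse = ""))
  for (m in c(3L, 5L, 10L)) {
    members <- withSeed(100 + m, vapply(seq_len(m), function(i)
      SpliceFusion:::.mutateSeq(truthSeq, 0.08,
                                c(sub = 1, ins = 1, del = 1) / 3),
      character(1)))
    cons <- starConsensus(members)
    raw <- mean(vapply(members, function(s)
      SpliceFusion:::editDistance(s, truthSeq), integer(1)))
    expect_lt(SpliceFusion:::editDistance(cons, truthSeq), raw)
  }
  # a single sequence is its own consensus
  expect_identical(starConsensus("ACGTACGT"), "ACGTACGT")
  expect_error(starConsensus(character()), "empty cluster")
})

test_that("buildConsensus splits members at the junction", {
  seqs <- c(paste0(strrep("A", 50), strrep("G", 50)),
            paste0(strrep("A", 50), strrep("G", 50)),
            paste0(strrep("A", 50), strrep("G", 50)))
  cons <- buildConsensus(seqs, junction_pos = c(50L, 50L, 50L))
  expect_identical(cons$five_prime, strrep("A", 50))
  expect_identical(cons$three_prime, strrep("G", 50))
  expect_identical(cons$full_length, paste0(strrep("A", 50),
                                            strrep("G", 50)))
})

test_that("clusterCandidates groups simulated fusion reads per event", {
  b <- smallBench()
  v <- smallValidated()
  cl <- clusterCandidates(v[v$pass, ], b$reads)
  expect_equal(nrow(cl), nrow(b$truth))
  key <- paste(cl$gene5, cl$gene3)
  expect_setequal(key, paste(b$truth$gene5, b$truth$gene3))
  expect_true(all(cl$n_reads >= 1))
  expect_true(all(nchar(cl$cons5) > 0 & nchar(cl$cons3) > 0))
  # trivially: 3 reads with paths P1,P1,P2 -> fine clusters of sizes 2 and 1
  cand <- data.frame(
    gene5 = "A", gene3 = "X", bp5 = 10L, bp3 = 20L,
    path5 = c("P1", "P1", "P2"), path3 = "Q", stringsAsFactors = FALSE)
  fine <- fineCluster(cand, coarseCluster(cand, 100L))
  expect_setequal(as.vector(table(fine)), c(2L, 1L))
})

test_that("empty candidate set clusters to a typed empty frame", {
  b <- smallBench()
  v <- smallValidated()
  out <- clusterCandidates(v[0, ], b$reads)
  expect_equal(nrow(out), 0L)
  expect_true(all(c("cluster_id", "gene5", "gene3", "n_reads", "cons5",
                    "cons3", "consFull") %in% names(out)))
})
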