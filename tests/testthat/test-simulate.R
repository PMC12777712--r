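test_that("simConfig validates its inputs", {
  expect_error(simConfig(error_rate = 0.5))
  expect_error(simConfig(unknown_option = 1), "unused argument")
  expect_identical(simConfig(platform = "ont")$platform, "ont")
})

test_that("genome/annotation generation is deterministic under a seed", {
  cfg <- simConfig(seed = 13, n_chromosomes = 1, genes_per_chromosome = 4,
                   n_fusions = 1)
  a <- makeGenomeAnnotation(cfg)
  b <- makeGenomeAnnotation(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(readLines(a$gff3), readLines(b$gff3))
})

test_that("all simulated introns are GT..AG on the transcript strand", {
  cfg <- simConfig(seed = 17, n_chromosomes = 2, genes_per_chromosome = 5,
                   n_fusions = 1)
  ga <- makeGenomeAnnotation(cfg)
  for (g in ga$genes) {
    ex <- g$transcripts[[1]]
    if (nrow(ex) < 2) next
    for (i in seq_len(nrow(ex) - 1)) {
      intron <- as.character(Biostrings::subseq(
        ga$genome[[g$chrom]], ex[i, 2] + 1L, ex[i + 1L, 1]))
      if (g$strand == "-") intron <- revComp(intron)
      expect_identical(substr(intron, 1, 2), "GT")
      expect_identical(substr(intron, nchar(intron) - 1, nchar(intron)),
                       "AG")
    }
  }
})

test_that("generated annotation builds valid graphs through parseAnnotation", {
  b <- smallBench()
  expect_true(methods::validObject(b$crsg))
  expect_true(methods::validObject(b$prsg))
  # PRSG genes are a subset of CRSG genes
  expect_true(all(geneMeta(b$prsg)$gene_id %in% geneMeta(b$crsg)$gene_id))
})

test_that("fusion transcripts are exact prefix+suffix of partner mRNAs", {
  b <- smallBench()
  mrna <- function(gid) {
    g <- b$genes[[gid]]
    ex <- SpliceFusion:::.senseExons(g)
    paste(vapply(seq_len(nrow(ex)), function(e)
      SpliceFusion:::.exonSeq(b$genome, g, ex[e, ]), character(1)),
      collapse = "")
  }
  for (i in seq_len(nrow(b$truth))) {
    fseq <- b$fusion_seqs[[b$truth$fusion_id[i]]]
    m5 <- mrna(b$truth$gene5[i])
    m3 <- mrna(b$truth$gene3[i])
    # exon-boundary fusions: 5' part is a prefix of gene5's mRNA and the
    # 3' part a suffix of gene3's mRNA
    split_at <- NA
    for (cut in seq_len(nchar(fseq) - 1)) {
      if (startsWith(m5, substr(fseq, 1, cut)) &&
          endsWith(m3, substr(fseq, cut + 1, nchar(fseq)))) {
        split_at <- cut
        break
      }
    }
    expect_false(is.na(split_at), info = b$truth$fusion_id[i])
  }
  expect_equal(nrow(b$truth), 4L)
  expect_equal(length(b$fusion_seqs), 4L)
})

test_that("error-free reads are exact subsequences of transcripts", {
  tx <- c(t1 = strrep("ACGTTGCA", 40))
  reads <- simulateReads(tx, depth = 10, error_rate = 0, seed = 4)
  expect_length(reads, 10L)
  for (r in reads) {
    expect_true(grepl(r, tx[[1]], fixed = TRUE) ||
                  grepl(revComp(r), tx[[1]], fixed = TRUE))
  }
})

test_that("read counts and names follow depth and transcripts", {
  tx <- c(a = strrep("ACGT", 100), b = strrep("TTGCA", 80))
  reads <- simulateReads(tx, depth = 10, error_rate = 0.05, seed = 4)
  expect_length(reads, 20L)
  expect_equal(sum(startsWith(names(reads), "a_")), 10L)
  expect_true(all(grepl("^(a|b)_r[0-9]+$", names(reads))))
})

test_that("empirical error rate matches the configured rate", {
  tx <- c(t1 = withSeed(9, paste(sample(c("A", "C", "G", "T"), 1000,
                                        replace = TRUE), collapse = "")))
  for (rate in c(0.05, 0.15)) {
    reads <- simulateReads(tx, depth = 100, error_rate = rate, seed = 5,
                           max_trim = 0L)
    ed <- vapply(reads, function(r) {
      min(SpliceFusion:::editDistance(r, tx[[1]]),
          SpliceFusion:::editDistance(revComp(r), tx[[1]]))
    }, integer(1))
    emp <- mean(ed / nchar(tx[[1]]))
    # alignment absorbs a few errors, so allow a generous band
    expect_gt(emp, rate * 0.6)
    expect_lt(emp, rate * 1.2)
  }
})

test_that("about half of the reads are reverse-complemented", {
  tx <- c(t1 = withSeed(10, paste(sample(c("A", "C", "G", "T"), 500,
                                         replace = TRUE), collapse = "")))
  reads <- simulateReads(tx, depth = 200, error_rate = 0, seed = 6,
                         max_trim = 0L)
  n_rc <- sum(vapply(reads, function(r) !grepl(r, tx[[1]], fixed = TRUE),
                     logical(1)))
  expect_gt(n_rc, 60)
  expect_lt(n_rc, 140)
})

test_that("chimera injection replaces the requested read fraction", {
  tx <- c(a = strrep("ACGGTTCA", 60), b = strrep("GATTACCA", 60))
  reads <- simulateReads(tx, depth = 50, error_rate = 0, seed = 11,
                         chimera_rate = 0.1)
  expect_length(reads, 100L)
  expect_equal(sum(startsWith(names(reads), "chimera")), 10L)
})

test_that("simulateReads writes valid FASTQ", {
  tx <- c(a = strrep("ACGT", 50))
  fq <- tempfile(fileext = ".fq")
  reads <- simulateReads(tx, depth = 3, error_rate = 0, seed = 2,
                         fastq = fq)
  back <- readReads(fq)
  expect_identical(back, reads)
})

test_that("benchmark truth breakpoints lie on annotated exon boundaries", {
  b <- smallBench()
  for (i in seq_len(nrow(b$truth))) {
    expect_true(b$truth$bp5[i] %in% exonBoundaries(b$crsg,
                                                   b$truth$gene5[i]))
    expect_true(b$truth$bp3[i] %in% exonBoundaries(b$crsg,
                                                   b$truth$gene3[i]))
  }
  # mid-exon fusions are flagged and (generically) off-boundary
  cfg <- simConfig(seed = 19, n_fusions = 2,
                   fusion_mix = c(inter = 0, intra = 0, readthrough = 0,
                                  midexon = 1), depth = 4, n_negative = 2)
  bm <- simulateBenchmark(cfg)
  expect_true(all(bm$truth$mid_exon))
})
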