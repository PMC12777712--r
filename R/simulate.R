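# Synthetic benchmark generator: a small multi-gene genome with GT..AG
# introns and GFF3 annotation, fusion transcripts joined at exon boundaries
# (or deliberately mid-exon), and error-bearing long reads with recorded
# truth. Everything is driven by a single seed and is byte-reproducible.

#' Simulation configuration
#'
#' Validated parameter bundle for the synthetic benchmark. Unknown names are
#' rejected. Defaults describe a desk-scale transcriptome: 4 chromosomes of
#' 10 multi-exon genes, 20 fusion events mixing inter-chromosomal,
#' intra-chromosomal (with an intervening gene), read-through-like and
#' mid-exon configurations, 30x reads per transcript at a 10% balanced error
#' rate (PacBio-like profile).
#'
#' @param n_chromosomes,genes_per_chromosome genome layout
#' @param exons_per_gene integer range \code{c(min, max)}
#' @param exon_len,intron_len,intergenic_gap bp ranges \code{c(min, max)}
#' @param pc_fraction fraction of genes labelled protein_coding
#' @param n_fusions number of fusion transcripts
#' @param fusion_mix named numeric: proportions of \code{inter},
#'   \code{intra}, \code{readthrough}, \code{midexon} fusion types
#' @param n_negative number of non-fusion transcripts in the negative control
#' @param depth reads per transcript
#' @param error_rate per-base error fraction in [0, 0.2]
#' @param platform \code{"pacbio"} (balanced substitution/insertion/deletion)
#'   or \code{"ont"} (deletion-skewed)
#' @param chimera_rate fraction of negative reads replaced by
#'   template-switch chimeras (random mid-transcript joins)
#' @param seed integer seed controlling every random draw
#' @return validated list of class \code{sim_config}
#' @export
simConfig <- function(n_chromosomes = 4L, genes_per_chromosome = 10L,
                      exons_per_gene = c(3L, 6L), exon_len = c(80L, 300L),
                      intron_len = c(150L, 600L),
                      intergenic_gap = c(3000L, 6000L),
                      pc_fraction = 0.85, n_fusions = 20L,
                      fusion_mix = c(inter = 0.35, intra = 0.35,
                                     readthrough = 0.2, midexon = 0.1),
                      n_negative = 20L, depth = 30L, error_rate = 0.10,
                      platform = c("pacbio", "ont"), chimera_rate = 0,
                      seed = 1L) {
  platform <- match.arg(platform)
  stopifnot(error_rate >= 0, error_rate <= 0.2, n_chromosomes >= 1,
            genes_per_chromosome >= 1, n_fusions >= 1, depth >= 1,
            all(c("inter", "intra", "readthrough", "midexon") %in%
                  names(fusion_mix)))
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              intergenic_gap = as.integer(intergenic_gap),
              pc_fraction = pc_fraction, n_fusions = as.integer(n_fusions),
              fusion_mix = fusion_mix / sum(fusion_mix),
              n_negative = as.integer(n_negative),
              depth = as.integer(depth), error_rate = error_rate,
              platform = platform, chimera_rate = chimera_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

#' Generate a synthetic genome and GFF3 annotation
#'
#' Genes of 2+ exons are laid along each chromosome with intergenic gaps;
#' every intron reads GT..AG on the transcript strand (so canonical
#' splice-motif checks are exercised), and a configurable fraction of genes
#' is labelled non-protein-coding (lncRNA). Genes with four or more exons get
#' a second, exon-skipping transcript so graphs contain alternative paths.
#' Deterministic for a fixed seed.
#'
#' @param cfg \code{\link{simConfig}}
#' @param dir output directory (created)
#' @return list with \code{genome_fa}, \code{gff3}, \code{genome}
#'   (DNAStringSet) and \code{genes} (gene models as from
#'   \code{\link{parseAnnotation}})
#' @export
makeGenomeAnnotation <- function(cfg, dir = tempfile("sim")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withSeed(cfg$seed, {
    rint <- function(rng) sample(rng[1]:rng[2], 1L)
    chroms <- character(cfg$n_chromosomes)
    names(chroms) <- paste0("chr", seq_len(cfg$n_chromosomes))
    genes <- list()
    gffLines <- c("##gff-version 3")
    gi <- 0L
    for (ci in seq_len(cfg$n_chromosomes)) {
      chrom <- names(chroms)[ci]
      pieces <- character()
      cursor <- 0L
      for (k in seq_len(cfg$genes_per_chromosome)) {
        gi <- gi + 1L
        gid <- sprintf("G%03d", gi)
        gap <- rint(cfg$intergenic_gap)
        pieces <- c(pieces, .randSeq(gap)); cursor <- cursor + gap
        strand <- sample(c("+", "-"), 1L)
        biotype <- if (stats::runif(1) < cfg$pc_fraction) "protein_coding"
                   else "lncRNA"
        nex <- rint(cfg$exons_per_gene)
        ex <- matrix(0L, nex, 2L, dimnames = list(NULL, c("start", "end")))
        for (e in seq_len(nex)) {
          if (e > 1L) {
            il <- rint(cfg$intron_len)
            mid <- .randSeq(il - 4L)
            intron <- if (strand == "+") paste0("GT", mid, "AG")
                      else paste0("CT", mid, "AC")
            pieces <- c(pieces, intron); cursor <- cursor + il
          }
          el <- rint(cfg$exon_len)
          pieces <- c(pieces, .randSeq(el))
          ex[e, ] <- c(cursor, cursor + el)
          cursor <- cursor + el
        }
        txl <- list()
        txl[[paste0(gid, ".t1")]] <- ex
        if (nex >= 4L)
          txl[[paste0(gid, ".t2")]] <- ex[-2L, , drop = FALSE]
        genes[[gid]] <- list(gene_id = gid, gene_name = gid, chrom = chrom,
                             strand = strand, biotype = biotype,
                             transcripts = txl)
        gffLines <- c(gffLines, sprintf(
          "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s;gene_name=%s;gene_type=%s",
          chrom, ex[1, 1] + 1L, ex[nex, 2], strand, gid, gid, gid, biotype))
        for (t in names(txl)) {
          m <- txl[[t]]
          gffLines <- c(gffLines, sprintf(
            "%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;gene_id=%s",
            chrom, m[1, 1] + 1L, m[nrow(m), 2], strand, t, gid, gid))
          for (e in seq_len(nrow(m)))
            gffLines <- c(gffLines, sprintf(
              "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s;gene_id=%s",
              chrom, m[e, 1] + 1L, m[e, 2], strand, t, e, t, gid))
        }
      }
      pieces <- c(pieces, .randSeq(rint(cfg$intergenic_gap)))
      chroms[[chrom]] <- paste(pieces, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(chroms)
    genome_fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome, genome_fa)
    gff3 <- file.path(dir, "annotation.gff3")
    writeLines(gffLines, gff3)
    list(genome_fa = genome_fa, gff3 = gff3, genome = genome, genes = genes)
  })
}

# Sense-ordered exon matrix of a gene's primary transcript.
.senseExons <- function(gene) {
  m <- gene$transcripts[[1L]]
  if (identical(gene$strand, "-")) m[rev(seq_len(nrow(m))), , drop = FALSE]
  else m
}

.exonSeq <- function(genome, gene, ex) {
  s <- extractSeq(genome, gene$chrom, ex[1L], ex[2L])
  if (identical(gene$strand, "-")) revComp(s) else s
}

#' Construct fusion transcripts with recorded truth
#'
#' Each fusion joins a 5' exon prefix of gene A to a 3' exon suffix of gene B
#' at annotated exon boundaries (or deliberately mid-exon for the
#' \code{midexon} type). Types: \code{inter} (different chromosomes),
#' \code{intra} (same chromosome with at least one intervening gene),
#' \code{readthrough} (adjacent co-oriented genes). Truth breakpoints follow
#' the reporting convention: the 5' partner's transcript-terminal exon
#' boundary and the 3' partner's transcript-initial one, 1-based.
#'
#' @param cfg \code{\link{simConfig}}
#' @param genes gene models from \code{\link{makeGenomeAnnotation}}
#' @param genome DNAStringSet
#' @return list with \code{truth} (data.frame) and \code{seqs} (named
#'   character of fusion transcript sequences)
#' @export
makeFusions <- function(cfg, genes, genome) {
  withSeed(cfg$seed + 1L, {
    pc <- Filter(function(g) g$biotype == "protein_coding", genes)
    ids <- names(pc)
    chromOf <- vapply(pc, `[[`, "", "chrom")
    strandOf <- vapply(pc, `[[`, "", "strand")
    counts <- round(cfg$fusion_mix * cfg$n_fusions)
    while (sum(counts) < cfg$n_fusions) counts[1L] <- counts[1L] + 1L
    while (sum(counts) > cfg$n_fusions)
      counts[which.max(counts)] <- counts[which.max(counts)] - 1L
    used <- character()
    # enumerate every ordered pc gene pair valid for a given fusion type
    validPairs <- function(type) {
      pairs <- list()
      if (type %in% c("inter", "midexon")) {
        for (a in ids) for (b in ids)
          if (a != b && chromOf[[a]] != chromOf[[b]])
            pairs[[length(pairs) + 1L]] <- c(a, b)
      } else if (type == "intra") {
        for (ch in unique(chromOf)) {
          onc <- ids[chromOf == ch]  # pc genes in genomic order
          if (length(onc) < 3L) next
          for (i in seq_along(onc)) for (j in seq_along(onc))
            if (abs(i - j) >= 2L)
              pairs[[length(pairs) + 1L]] <- c(onc[i], onc[j])
        }
      } else if (type == "readthrough") {
        for (ch in unique(chromOf)) {
          onc <- ids[chromOf == ch]
          if (length(onc) < 2L) next
          for (i in seq_len(length(onc) - 1L)) {
            a <- onc[i]; b <- onc[i + 1L]
            if (strandOf[[a]] != strandOf[[b]]) next
            # upstream gene (in transcription order) is the 5' partner
            if (strandOf[[a]] == "+")
              pairs[[length(pairs) + 1L]] <- c(a, b)
            else
              pairs[[length(pairs) + 1L]] <- c(b, a)
          }
        }
      }
      pairs
    }
    pickPair <- function(type) {
      pairs <- validPairs(type)
      if (!length(pairs))
        stop("could not place a fusion of type '", type,
             "': enlarge the genome or adjust fusion_mix")
      fresh <- Filter(function(p) !any(p %in% used), pairs)
      pool <- if (length(fresh)) fresh else pairs
      p <- pool[[sample.int(length(pool), 1L)]]
      used <<- c(used, p)
      p
    }
    truth <- list()
    seqs <- character()
    fi <- 0L
    for (type in names(counts)) {
      for (r in seq_len(counts[[type]])) {
        fi <- fi + 1L
        p <- pickPair(type)
        g5 <- pc[[p[1L]]]; g3 <- pc[[p[2L]]]
        ex5 <- .senseExons(g5); ex3 <- .senseExons(g3)
        j5 <- sample(seq_len(nrow(ex5) - 1L), 1L)
        k3 <- sample(2L:nrow(ex3), 1L)
        mid <- type == "midexon"
        part5 <- paste(vapply(seq_len(j5), function(e)
          .exonSeq(genome, g5, ex5[e, ]), character(1)), collapse = "")
        part3 <- paste(vapply(k3:nrow(ex3), function(e)
          .exonSeq(genome, g3, ex3[e, ]), character(1)), collapse = "")
        if (mid) {
          len5 <- ex5[j5, 2L] - ex5[j5, 1L]
          len3 <- ex3[k3, 2L] - ex3[k3, 1L]
          o5 <- sample(20L:(len5 - 20L), 1L)
          o3 <- sample(20L:(len3 - 20L), 1L)
          cut5 <- len5 - o5  # drop the last o5 sense-bases of exon j5
          part5 <- substr(part5, 1L, nchar(part5) - o5)
          part3 <- substr(part3, o3 + 1L, nchar(part3))
          bp5 <- if (g5$strand == "+") ex5[j5, 2L] - o5
                 else ex5[j5, 1L] + o5 + 1L
          bp3 <- if (g3$strand == "+") ex3[k3, 1L] + o3 + 1L
                 else ex3[k3, 2L] - o3
        } else {
          bp5 <- if (g5$strand == "+") ex5[j5, 2L] else ex5[j5, 1L] + 1L
          bp3 <- if (g3$strand == "+") ex3[k3, 1L] + 1L else ex3[k3, 2L]
        }
        fid <- sprintf("fusion%03d", fi)
        seqs[[fid]] <- paste0(part5, part3)
        truth[[fid]] <- data.frame(
          fusion_id = fid, gene5 = g5$gene_id, gene3 = g3$gene_id,
          chrom5 = g5$chrom, bp5 = as.integer(bp5),
          chrom3 = g3$chrom, bp3 = as.integer(bp3),
          type = type, mid_exon = mid, n_exons5 = j5,
          first_exon3 = k3, stringsAsFactors = FALSE)
      }
    }
    list(truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         seqs = seqs)
  })
}

# Inject i.i.d. substitution/insertion/deletion errors into one sequence.
.mutateSeq <- function(seq, rate, mix) {
  n <- nchar(seq)
  if (rate <= 0 || n == 0L) return(seq)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  types <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                  prob = mix)
  ins_after <- character(n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(hit)) {
    p <- hit[i]
    if (types[i] == "sub") {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    } else if (types[i] == "del") {
      chars[p] <- ""
    } else {
      ins_after[p] <- sample(bases, 1L)
    }
  }
  paste0(paste0(chars, ins_after), collapse = "")
}

#' Simulate error-bearing long reads from transcripts
#'
#' Produces \code{depth} reads per transcript. Each read is the transcript
#' with small random end truncations and i.i.d. per-base errors at
#' \code{error_rate}, with the substitution/insertion/deletion mix set by the
#' platform profile (PacBio-like balanced, ONT-like deletion-skewed). About
#' half of the reads are reverse-complemented. Read names encode the source
#' transcript (\code{<tx>_r<i>}). Optionally, a fraction of reads is replaced
#' by template-switch chimeras: two random transcripts joined at random
#' internal positions, emulating the reverse-transcription artifacts of
#' cDNA/Iso-seq libraries; their names start with \code{chimera}.
#'
#' @param transcripts named character vector of transcript sequences
#' @param depth reads per transcript
#' @param error_rate per-base error fraction
#' @param seed RNG seed
#' @param platform \code{"pacbio"} or \code{"ont"}
#' @param chimera_rate fraction of reads replaced by template-switch
#'   chimeras
#' @param max_trim maximal random truncation per read end in bp (default 20)
#' @param fastq optional FASTQ output path
#' @return named character vector of reads (invisibly also written to
#'   \code{fastq} when given)
#' @export
simulateReads <- function(transcripts, depth, error_rate, seed,
                          platform = c("pacbio", "ont"), chimera_rate = 0,
                          max_trim = 20L, fastq = NULL) {
  platform <- match.arg(platform)
  mix <- if (platform == "pacbio") c(sub = 1, ins = 1, del = 1) / 3
         else c(sub = 0.3, ins = 0.2, del = 0.5)
  withSeed(seed, {
    reads <- character()
    for (tx in names(transcripts)) {
      s <- transcripts[[tx]]
      for (i in seq_len(depth)) {
        lt <- sample(0:max_trim, 1L); rt <- sample(0:max_trim, 1L)
        r <- substr(s, lt + 1L, nchar(s) - rt)
        r <- .mutateSeq(r, error_rate, mix)
        if (stats::runif(1) < 0.5) r <- revComp(r)
        reads[[sprintf("%s_r%03d", tx, i)]] <- r
      }
    }
    nch <- round(chimera_rate * length(reads))
    if (nch > 0L && length(transcripts) >= 2L) {
      for (i in seq_len(nch)) {
        ab <- sample(names(transcripts), 2L)
        a <- transcripts[[ab[1L]]]; b <- transcripts[[ab[2L]]]
        ca <- sample(50L:(nchar(a) - 10L), 1L)
        cb <- sample(10L:(nchar(b) - 50L), 1L)
        r <- .mutateSeq(paste0(substr(a, 1L, ca),
                               substr(b, cb, nchar(b))), error_rate, mix)
        if (stats::runif(1) < 0.5) r <- revComp(r)
        reads[[sprintf("chimera%03d", i)]] <- r
        # chimeras replace negative reads rather than adding throughput
        reads <- reads[-i]
      }
    }
    if (!is.null(fastq)) {
      lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads), "+",
                               strrep("I", nchar(reads))))
      writeLines(lines, fastq)
    }
    reads
  })
}

#' Generate a complete synthetic fusion benchmark
#'
#' Convenience wrapper tying the generator together: genome + annotation,
#' fusion transcripts with truth, and the negative-control transcript set
#' (primary transcripts of genes not involved in any fusion, up to
#' \code{n_negative}).
#'
#' @param cfg \code{\link{simConfig}}
#' @param dir output directory
#' @return list with \code{genome_fa}, \code{gff3}, \code{genome},
#'   \code{genes}, \code{truth}, \code{fusion_seqs}, \code{neg_seqs},
#'   \code{dir}
#' @export
simulateBenchmark <- function(cfg, dir = tempfile("bench")) {
  ga <- makeGenomeAnnotation(cfg, dir)
  fus <- makeFusions(cfg, ga$genes, ga$genome)
  usedGenes <- unique(c(fus$truth$gene5, fus$truth$gene3))
  free <- setdiff(names(ga$genes), usedGenes)
  withSeed(cfg$seed + 2L, {
    negGenes <- if (length(free) > cfg$n_negative)
      sort(sample(free, cfg$n_negative)) else free
  })
  neg <- vapply(negGenes, function(g) {
    gene <- ga$genes[[g]]
    ex <- .senseExons(gene)
    paste(vapply(seq_len(nrow(ex)), function(e)
      .exonSeq(ga$genome, gene, ex[e, ]), character(1)), collapse = "")
  }, character(1))
  names(neg) <- paste0(negGenes, ".t1")
  truth_tsv <- file.path(dir, "truth.tsv")
  utils::write.table(fus$truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeFastaChr(fus$seqs, file.path(dir, "fusions.fa"))
  list(genome_fa = ga$genome_fa, gff3 = ga$gff3, genome = ga$genome,
       genes = ga$genes, truth = fus$truth, fusion_seqs = fus$seqs,
       neg_seqs = neg, dir = dir)
}
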