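# Dual re-alignment validation of cluster consensus sequences, splice-motif
# checks, breakpoint refinement to annotated exon boundaries, and hierarchical
# confidence classification.

# Quick gene assignment of a sequence against a graph's reference paths:
# k-mer vote for the best path, then a local alignment for identity.
bestGeneMatch <- function(seq, rp, idx, k = 13L) {
  if (!nzchar(seq)) stop("empty consensus sequence")
  km <- readKmers(stats::setNames(seq, "q"), k)
  if (!nrow(km)) return(NULL)
  hits <- idx[km, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) return(NULL)
  cnt <- hits[, .N, by = tx]
  data.table::setorder(cnt, -N, tx)
  best_tx <- cnt$tx[1L]
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq), Biostrings::DNAString(rp$seqs[[best_tx]]),
    type = "local", substitutionMatrix = .subMat,
    gapOpening = 4, gapExtension = 2)
  gene <- rp$layout[tx == best_tx]$gene_id[1L]
  list(gene = gene, tx = best_tx, identity = Biostrings::pid(aln) / 100,
       qspan = Biostrings::nchar(Biostrings::pattern(aln)))
}

#' Component validation of partner consensus fragments on the PRSG
#'
#' Re-aligns the 5' and 3' partner consensus fragments separately to the
#' protein-coding reference splicing graph. A fragment validates when its
#' best-matching gene equals the expected partner and the alignment identity
#' reaches \code{min_identity}; a partner absent from the protein-coding
#' graph (e.g. an lncRNA) can never validate on this dimension.
#'
#' @param cons5,cons3 partner consensus sequences
#' @param prsg protein-coding \linkS4class{SpliceGraph}
#' @param expected5,expected3 expected partner gene ids
#' @param min_identity minimum alignment identity (default 0.80)
#' @return list with \code{prsg_ok5}, \code{prsg_ok3}, \code{matched5},
#'   \code{matched3}, \code{id5}, \code{id3}
#' @export
componentValidate <- function(cons5, cons3, prsg, expected5, expected3,
                              min_identity = 0.80) {
  if (!nzchar(cons5) || !nzchar(cons3))
    stop("empty consensus sequence")
  rp <- refPaths(prsg)
  idx <- kmerTable(rp$seqs, 13L)
  data.table::setkey(idx, kmer)
  one <- function(seq, expected) {
    b <- bestGeneMatch(seq, rp, idx)
    if (is.null(b)) return(list(ok = FALSE, gene = NA_character_,
                                id = NA_real_))
    list(ok = identical(b$gene, expected) && b$identity >= min_identity,
         gene = b$gene, id = b$identity)
  }
  r5 <- one(cons5, expected5)
  r3 <- one(cons3, expected3)
  list(prsg_ok5 = r5$ok, prsg_ok3 = r3$ok,
       matched5 = r5$gene, matched3 = r3$gene,
       id5 = r5$id, id3 = r3$id)
}

#' Build a genome k-mer index for structural validation
#' @param genome named \code{DNAStringSet} or FASTA path
#' @param k k-mer size (default 13)
#' @param max_occ drop k-mers occurring more often than this (repeats)
#' @return keyed data.table (kmer, chrom, gpos)
#' @export
genomeKmerIndex <- function(genome, k = 13L, max_occ = 10L) {
  genome <- loadGenome(genome)
  idx <- kmerTable(stats::setNames(as.character(genome), names(genome)), k)
  data.table::setnames(idx, c("tx", "tpos"), c("chrom", "gpos"))
  occ <- idx[, .N, by = kmer]
  idx <- idx[occ[N <= max_occ], on = "kmer"]
  idx[, N := NULL]
  data.table::setkey(idx, kmer)
  idx
}

#' Structural validation of the full-length consensus on the linear genome
#'
#' Locates the consensus on the genome via exact k-mer anchors chained into
#' locus blocks (anchors on one chromosome and orientation belong to the same
#' block while consecutive genomic gaps stay below \code{max_gap}, the intron
#' span bridged within a locus). The consensus validates when exactly two
#' primary blocks, query-disjoint, jointly cover at least \code{min_cov} of
#' its length; three or more scattered blocks fail. Junction genomic
#' coordinates are extrapolated from the block anchors at the junction and
#' the flanking genomic dinucleotides are recorded as the donor-acceptor
#' motif (canonical GT-AG; GC-AG and AT-AC flagged as minor non-canonical).
#'
#' @param consensus full-length chimeric consensus sequence
#' @param genome named \code{DNAStringSet} or FASTA path
#' @param gidx genome index from \code{\link{genomeKmerIndex}} (built on the
#'   fly when NULL)
#' @param min_cov minimum joint query coverage (default 0.90)
#' @param k anchor k-mer size (must match \code{gidx})
#' @param max_gap maximum intra-locus genomic gap in bp (default 5000)
#' @return list with \code{genome_ok}, 1-based junction coordinates
#'   \code{bp5}, \code{bp3} with \code{chrom5}, \code{chrom3} and block
#'   orientations, \code{splice_motif}, \code{motif_canonical}
#'   (\code{"canonical"}, \code{"non-canonical-minor"} or
#'   \code{"non-canonical"}), and the block table
#' @export
structuralValidate <- function(consensus, genome, gidx = NULL,
                               min_cov = 0.90, k = 13L, max_gap = 5000L) {
  genome <- loadGenome(genome)
  if (is.null(gidx)) gidx <- genomeKmerIndex(genome, k)
  fail <- list(genome_ok = FALSE, bp5 = NA_integer_, bp3 = NA_integer_,
               chrom5 = NA_character_, chrom3 = NA_character_,
               orient5 = NA_character_, orient3 = NA_character_,
               splice_motif = NA_character_, motif_canonical = NA_character_,
               blocks = NULL)
  L <- nchar(consensus)
  if (L < k) return(fail)
  fk <- readKmers(stats::setNames(consensus, "q"), k)
  rk <- readKmers(stats::setNames(revComp(consensus), "q"), k)
  fk[, `:=`(orient = "+", qc = rpos)]
  rk[, `:=`(orient = "-", qc = L - rpos - k)]
  km <- data.table::rbindlist(list(fk, rk))
  hits <- gidx[km, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) return(fail)
  # An anchor counts toward a locus only when corroborated: anchors within
  # an exon share one diagonal (gpos - qc on "+", gpos + qc on "-"; a
  # consensus indel shifts it by a few bp, introns by >= the intron length),
  # so genuine anchors come in same-diagonal runs of >= 3 while chance k-mer
  # hits are isolated. Uncorroborated anchors would otherwise merge into a
  # nearby block (any genomic gap < max_gap) and corrupt its extrema and
  # junction extrapolation.
  hits[, diag := ifelse(orient == "+", gpos - qc, gpos + qc)]
  data.table::setorder(hits, chrom, orient, diag)
  hits[, dgrp := cumsum(c(1L, diff(diag) > 5L)), by = .(chrom, orient)]
  hits[, dn := .N, by = .(chrom, orient, dgrp)]
  hits <- hits[dn >= 3L]
  if (!nrow(hits)) return(fail)
  data.table::setorder(hits, chrom, orient, gpos)
  hits[, block := cumsum(c(1L, (diff(gpos) > max_gap))),
       by = .(chrom, orient)]
  blocks <- hits[, .(n = .N, q_lo = min(qc), q_hi = max(qc) + k,
                     g_lo = min(gpos), g_hi = max(gpos) + k),
                 by = .(chrom, orient, block)]
  blocks <- blocks[n >= 3L & q_hi - q_lo >= 30L]
  if (!nrow(blocks)) return(fail)
  data.table::setorder(blocks, -n, chrom, g_lo)
  keep <- logical(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(blocks$q_hi[i], blocks$q_hi[j]) -
        max(blocks$q_lo[i], blocks$q_lo[j])
      if (ov > 0.2 * (blocks$q_hi[i] - blocks$q_lo[i])) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  primary <- blocks[keep]
  fail$blocks <- as.data.frame(primary)
  if (nrow(primary) != 2L) return(fail)
  cov <- sum(primary$q_hi - primary$q_lo) / L
  if (cov < min_cov) return(fail)
  data.table::setorder(primary, q_lo)
  A <- primary[1L]; B <- primary[2L]
  jq <- as.integer(floor((A$q_hi + B$q_lo) / 2))
  # Junction extrapolation uses the modal anchor diagonal among the anchors
  # adjacent to the junction in query space (within 2k of the block's
  # junction-side extreme), not the block-wide coordinate extrema: a merged
  # block can absorb an isolated off-diagonal anchor (a chance k-mer hit
  # within max_gap of the locus) whose g extreme would otherwise be paired
  # with an unrelated anchor's q extreme.
  junctionDiag <- function(blk, side) {
    a <- hits[chrom == blk$chrom & orient == blk$orient & block == blk$block]
    qx <- if (side == "5p") max(a$qc) else min(a$qc)
    a <- a[abs(qc - qx) <= 2L * k]
    diag <- if (blk$orient == "+") a$gpos - a$qc else a$gpos + a$qc
    tab <- sort(table(diag), decreasing = TRUE)
    as.integer(names(tab)[1L])
  }
  dA <- junctionDiag(A, "5p")
  dB <- junctionDiag(B, "3p")
  bpA <- if (A$orient == "+") dA + jq
         else dA + k + 1L - jq
  bpB <- if (B$orient == "+") dB + jq + 1L
         else dB + k - jq
  sm <- spliceMotif(genome, A$chrom, bpA, A$orient, B$chrom, bpB, B$orient)
  motif <- sm$motif
  canon <- sm$canonical
  list(genome_ok = TRUE, bp5 = as.integer(bpA), bp3 = as.integer(bpB),
       chrom5 = A$chrom, chrom3 = B$chrom,
       orient5 = A$orient, orient3 = B$orient,
       splice_motif = motif, motif_canonical = canon,
       blocks = as.data.frame(primary))
}

#' Donor-acceptor splice motif at a genomic junction
#'
#' Reads the donor dinucleotide immediately downstream of the 5' breakpoint
#' and the acceptor dinucleotide immediately upstream of the 3' breakpoint,
#' each on the strand of the corresponding consensus block (GT-AG is
#' canonical; GC-AG and AT-AC are minor non-canonical).
#'
#' @param genome named \code{DNAStringSet}
#' @param chrom5,bp5,orient5 5' junction chromosome, 1-based position and
#'   block orientation
#' @param chrom3,bp3,orient3 3' junction counterparts
#' @return list with \code{motif} (e.g. \code{"GT-AG"}) and \code{canonical}
#' @export
spliceMotif <- function(genome, chrom5, bp5, orient5,
                        chrom3, bp3, orient3) {
  genome <- loadGenome(genome)
  dinuc <- function(chrom, from1, to1, rc = FALSE) {
    chr <- genome[[chrom]]
    if (from1 < 1L || to1 > length(chr)) return("NN")
    s <- as.character(Biostrings::subseq(chr, from1, to1))
    if (rc) revComp(s) else s
  }
  donor <- if (orient5 == "+") dinuc(chrom5, bp5 + 1L, bp5 + 2L)
           else dinuc(chrom5, bp5 - 2L, bp5 - 1L, rc = TRUE)
  acceptor <- if (orient3 == "+") dinuc(chrom3, bp3 - 2L, bp3 - 1L)
              else dinuc(chrom3, bp3 + 1L, bp3 + 2L, rc = TRUE)
  motif <- paste(donor, acceptor, sep = "-")
  canonical <- if (motif == "GT-AG") "canonical"
               else if (motif %in% c("GC-AG", "AT-AC")) "non-canonical-minor"
               else "non-canonical"
  list(motif = motif, canonical = canonical)
}

#' Snap a breakpoint to a nearby annotated exon boundary
#'
#' Returns the nearest exon boundary within \code{window} bp of the raw
#' position, or the raw position unchanged when none is close enough. An
#' equidistant tie is resolved toward the smaller coordinate. Idempotent:
#' refining an already refined position is a no-op.
#'
#' @param raw_bp raw 1-based breakpoint position
#' @param boundaries exon boundary positions (1-based) of the partner gene
#' @param window snap window in bp (default 30)
#' @return list with \code{pos} (refined position) and \code{shifted}
#' @export
refineBreakpoint <- function(raw_bp, boundaries, window = 30L) {
  stopifnot(window >= 0L)
  if (!length(boundaries) || is.na(raw_bp))
    return(list(pos = raw_bp, shifted = FALSE))
  boundaries <- sort(unique(boundaries))
  d <- abs(boundaries - raw_bp)
  i <- which(d == min(d))[1L]  # sorted, so the tie picks the smaller one
  if (d[i] <= window) list(pos = boundaries[i], shifted = d[i] > 0L)
  else list(pos = raw_bp, shifted = FALSE)
}

#' Exon boundaries of a gene (1-based starts and ends)
#' @param graph \linkS4class{SpliceGraph}
#' @param gene_id gene identifier
#' @return sorted integer vector of boundary positions
#' @export
exonBoundaries <- function(graph, gene_id) {
  n <- graph@nodes[graph@nodes$gene_id == gene_id, , drop = FALSE]
  sort(unique(c(n$start + 1L, n$end)))
}

# Positional relationship of a gene pair from annotation metadata.
geneLayout <- function(meta, gene5, gene3) {
  m5 <- meta[meta$gene_id == gene5, , drop = FALSE]
  m3 <- meta[meta$gene_id == gene3, , drop = FALSE]
  same <- nrow(m5) && nrow(m3) && m5$chrom == m3$chrom
  if (!same)
    return(list(same_chrom = FALSE, co_oriented = FALSE, gap_bp = NA_real_,
                intervening_pc = FALSE))
  gapLo <- min(m5$end, m3$end)
  gapHi <- max(m5$start, m3$start)
  gap <- max(0, gapHi - gapLo)
  others <- meta[meta$gene_id != gene5 & meta$gene_id != gene3 &
                   meta$chrom == m5$chrom &
                   meta$biotype == "protein_coding", , drop = FALSE]
  intervening <- gap > 0 && nrow(others) &&
    any(others$end > gapLo & others$start < gapHi)
  list(same_chrom = TRUE,
       co_oriented = identical(m5$strand, m3$strand),
       gap_bp = gap, intervening_pc = isTRUE(intervening))
}

#' Hierarchical confidence classification of a fusion call
#'
#' A pure function of the validation evidence, the annotation layout of the
#' gene pair and the known-artifact list, applied in strict precedence:
#' \enumerate{
#'   \item \strong{PotentialArtifact_ReadThrough} -- the pair is on the
#'     artifact list, or is a read-through suspect: same chromosome,
#'     co-oriented, no intervening protein-coding gene and a gap of at most
#'     \code{readthrough_gap} (100 kbp).
#'   \item \strong{High} -- dually validated (protein-coding graph and
#'     linear genome) with breakpoints agreeing within 30 bp; or the genes
#'     are unambiguously separated (different chromosomes, more than 100 kbp
#'     apart, or with an intervening protein-coding gene) and at least one
#'     validation dimension passes.
#'   \item \strong{Medium} -- dually validated but with breakpoint
#'     disagreement of 30 bp or more (or no comparable breakpoints).
#'   \item \strong{Low} -- exactly one validation dimension passes.
#'   \item \strong{Filtered} -- neither dimension passes; such events are
#'     excluded from reported calls.
#' }
#' The protein-coding-graph dimension passes when both partner fragments
#' validate (\code{prsg_ok5} and \code{prsg_ok3}).
#'
#' @param evidence list with \code{prsg_ok5}, \code{prsg_ok3},
#'   \code{genome_ok} and \code{agreement_bp} (NA when either side lacks
#'   breakpoints)
#' @param layout list from the annotation: \code{same_chrom},
#'   \code{co_oriented}, \code{gap_bp}, \code{intervening_pc}
#' @param artifact_hit TRUE when the pair is on the known-artifact list
#' @param agreement_window breakpoint agreement threshold in bp (default 30)
#' @param readthrough_gap adjacency bound in bp (default 1e5)
#' @return one of \code{"High"}, \code{"Medium"}, \code{"Low"},
#'   \code{"PotentialArtifact_ReadThrough"}, \code{"Filtered"}
#' @export
classifyConfidence <- function(evidence, layout, artifact_hit = FALSE,
                               agreement_window = 30L,
                               readthrough_gap = 1e5) {
  readthrough <- isTRUE(layout$same_chrom) && isTRUE(layout$co_oriented) &&
    !isTRUE(layout$intervening_pc) && !is.na(layout$gap_bp) &&
    layout$gap_bp <= readthrough_gap
  if (isTRUE(artifact_hit) || readthrough)
    return("PotentialArtifact_ReadThrough")
  prsg_dim <- isTRUE(evidence$prsg_ok5) && isTRUE(evidence$prsg_ok3)
  genome_dim <- isTRUE(evidence$genome_ok)
  ndim <- prsg_dim + genome_dim
  dual <- prsg_dim && genome_dim
  agree <- !is.null(evidence$agreement_bp) && !is.na(evidence$agreement_bp) &&
    evidence$agreement_bp < agreement_window
  separated <- !isTRUE(layout$same_chrom) ||
    (!is.na(layout$gap_bp) && layout$gap_bp > readthrough_gap) ||
    isTRUE(layout$intervening_pc)
  if ((dual && agree) || (separated && ndim >= 1L)) return("High")
  if (dual) return("Medium")
  if (ndim == 1L) return("Low")
  "Filtered"
}

#' Read a known-artifact gene-pair list
#'
#' Two-column TSV of gene symbols or ids; matching is order-insensitive.
#' @param path TSV path (no header required; extra columns ignored)
#' @return character vector of canonical (sorted, tab-joined) pair keys
#' @export
readArtifactList <- function(path) {
  if (is.null(path) || !nzchar(path)) return(character())
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  apply(tab[, 1:2, drop = FALSE], 1L, function(r)
    paste(sort(as.character(r)), collapse = "\t"))
}

.pairKey <- function(a, b) {
  vapply(seq_along(a), function(i)
    paste(sort(c(a[i], b[i])), collapse = "\t"), character(1))
}

.tierOrder <- c("High", "Medium", "Low", "PotentialArtifact_ReadThrough",
                "Filtered")

#' Validate, refine and classify fusion clusters into final calls
#'
#' For every cluster with at least \code{min_support} member reads, runs the
#' two parallel validations (partner fragments on the protein-coding graph;
#' full-length consensus on the linear genome), measures the agreement
#' between graph-derived and genome-derived breakpoints, snaps the reported
#' breakpoints to annotated exon boundaries within \code{refine_window}, and
#' assigns a confidence tier. Genome-derived breakpoints are reported when
#' structural validation succeeds, otherwise the graph-derived ones; both
#' pass through refinement.
#'
#' @param clusters output of \code{\link{clusterCandidates}}
#' @param prsg protein-coding \linkS4class{SpliceGraph}
#' @param crsg comprehensive \linkS4class{SpliceGraph} (exon boundaries,
#'   gene names, layout)
#' @param genome named \code{DNAStringSet} or FASTA path
#' @param min_support minimum supporting reads per reported event (default 3)
#' @param refine_window breakpoint snap window in bp (default 30)
#' @param min_identity identity threshold for component validation
#' @param min_cov coverage threshold for structural validation (default 0.90)
#' @param artifact_pairs canonical pair keys from
#'   \code{\link{readArtifactList}}
#' @param gidx optional prebuilt \code{\link{genomeKmerIndex}}
#' @return data.frame of fusion calls (one row per cluster passing support)
#' @export
dualValidateClusters <- function(clusters, prsg, crsg, genome,
                                 min_support = 3L, refine_window = 30L,
                                 min_identity = 0.80, min_cov = 0.90,
                                 artifact_pairs = character(),
                                 gidx = NULL) {
  genome <- loadGenome(genome)
  if (is.null(gidx)) gidx <- genomeKmerIndex(genome)
  meta <- crsg@geneMeta
  keep <- clusters[clusters$n_reads >= min_support, , drop = FALSE]
  out <- vector("list", nrow(keep))
  if (nrow(keep)) {
    prp <- refPaths(prsg)
    pidx <- kmerTable(prp$seqs, 13L)
    data.table::setkey(pidx, kmer)
  }
  for (i in seq_len(nrow(keep))) {
    cl <- keep[i, ]
    one <- function(seq, expected) {
      b <- bestGeneMatch(seq, prp, pidx)
      if (is.null(b)) return(FALSE)
      identical(b$gene, expected) && b$identity >= min_identity
    }
    prsg_ok5 <- one(cl$cons5, cl$gene5)
    prsg_ok3 <- one(cl$cons3, cl$gene3)
    sv <- structuralValidate(cl$consFull, genome, gidx, min_cov = min_cov)
    agreement <- if (sv$genome_ok)
      max(abs(cl$bp5 - sv$bp5), abs(cl$bp3 - sv$bp3)) else NA_integer_
    raw5 <- if (sv$genome_ok) sv$bp5 else cl$bp5
    raw3 <- if (sv$genome_ok) sv$bp3 else cl$bp3
    r5 <- refineBreakpoint(raw5, exonBoundaries(crsg, cl$gene5),
                           refine_window)
    r3 <- refineBreakpoint(raw3, exonBoundaries(crsg, cl$gene3),
                           refine_window)
    # the raw genome-derived junction can be off by a few bases when the
    # flanking genomic sequence happens to extend a block across the
    # junction; read the splice motif at the refined positions
    motif <- if (sv$genome_ok)
      spliceMotif(genome, sv$chrom5, r5$pos, sv$orient5,
                  sv$chrom3, r3$pos, sv$orient3)
    else list(motif = sv$splice_motif, canonical = sv$motif_canonical)
    lay <- geneLayout(meta, cl$gene5, cl$gene3)
    hit <- .pairKey(cl$gene5, cl$gene3) %in% artifact_pairs ||
      .pairKey(meta$gene_name[match(cl$gene5, meta$gene_id)],
               meta$gene_name[match(cl$gene3, meta$gene_id)]) %in%
        artifact_pairs
    tier <- classifyConfidence(
      list(prsg_ok5 = prsg_ok5, prsg_ok3 = prsg_ok3,
           genome_ok = sv$genome_ok, agreement_bp = agreement),
      lay, artifact_hit = hit, agreement_window = refine_window)
    ftype <- if (!lay$same_chrom) "inter-chromosomal"
             else if (tier == "PotentialArtifact_ReadThrough" && !hit)
               "read-through-suspect"
             else if (lay$same_chrom) "intra-chromosomal" else "other"
    out[[i]] <- data.frame(
      gene5 = cl$gene5, gene3 = cl$gene3,
      name5 = meta$gene_name[match(cl$gene5, meta$gene_id)],
      name3 = meta$gene_name[match(cl$gene3, meta$gene_id)],
      chrom5 = cl$chrom5, bp5 = r5$pos,
      strand5 = meta$strand[match(cl$gene5, meta$gene_id)],
      chrom3 = cl$chrom3, bp3 = r3$pos,
      strand3 = meta$strand[match(cl$gene3, meta$gene_id)],
      n_supporting_reads = cl$n_reads, fusion_type = ftype, tier = tier,
      prsg_ok5 = prsg_ok5, prsg_ok3 = prsg_ok3, genome_ok = sv$genome_ok,
      splice_motif = motif$motif,
      motif_canonical = motif$canonical,
      breakpoint_agreement_bp = agreement,
      bp5_shifted = r5$shifted, bp3_shifted = r3$shifted,
      same_chrom = lay$same_chrom, co_oriented = lay$co_oriented,
      gap_bp = lay$gap_bp, intervening_pc = lay$intervening_pc,
      artifact_db_hit = hit, cluster_id = cl$cluster_id,
      path_signature = cl$path_signature,
      cons5 = cl$cons5, cons3 = cl$cons3, consFull = cl$consFull,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(
      gene5 = character(), gene3 = character(), name5 = character(),
      name3 = character(), chrom5 = character(), bp5 = integer(),
      strand5 = character(), chrom3 = character(), bp3 = integer(),
      strand3 = character(), n_supporting_reads = integer(),
      fusion_type = character(), tier = character(), prsg_ok5 = logical(),
      prsg_ok3 = logical(), genome_ok = logical(),
      splice_motif = character(), motif_canonical = character(),
      breakpoint_agreement_bp = integer(), bp5_shifted = logical(),
      bp3_shifted = logical(), same_chrom = logical(),
      co_oriented = logical(), gap_bp = integer(),
      intervening_pc = logical(), artifact_db_hit = logical(),
      cluster_id = integer(), path_signature = character(),
      cons5 = character(), cons3 = character(), consFull = character(),
      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$tier, .tierOrder), -res$n_supporting_reads,
                   res$gene5, res$gene3), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write fusion calls as TSV and JSON
#'
#' Deterministic ordering (tier, then supporting reads descending, then gene
#' pair). The TSV holds the tabular columns; the JSON mirrors them with the
#' consensus sequences embedded.
#'
#' @param calls data.frame from \code{\link{dualValidateClusters}}
#' @param tsv_path,json_path output paths (either may be NULL to skip)
#' @return list of written paths, invisibly
#' @export
writeCalls <- function(calls, tsv_path = NULL, json_path = NULL) {
  if (nrow(calls))
    calls <- calls[order(match(calls$tier, .tierOrder),
                         -calls$n_supporting_reads, calls$gene5,
                         calls$gene3), , drop = FALSE]
  tabcols <- setdiff(names(calls), c("cons5", "cons3", "consFull"))
  if (!is.null(tsv_path))
    utils::write.table(calls[, tabcols, drop = FALSE], tsv_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(calls, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  invisible(list(tsv = tsv_path, json = json_path))
}
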