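#' Parse a GFF3 gene annotation into gene models
#'
#' Reads a GENCODE-style GFF3 (gene / transcript-or-mRNA / exon hierarchy,
#' linked by \code{ID}/\code{Parent}, with a \code{gene_type} or
#' \code{gene_biotype} attribute) and returns one gene model per gene
#' feature. Coordinates are converted from GFF3 1-based closed intervals to
#' the package-internal 0-based half-open convention; exons within each
#' transcript are stored sorted by genomic coordinate.
#'
#' Exons or transcripts whose \code{Parent} cannot be resolved are skipped
#' with a warning; genes that end up with no exon-bearing transcript are
#' dropped with a warning. A gene on a chromosome missing from the genome is
#' an error, because node sequences could never be extracted for it.
#'
#' @param gff3_path path to the GFF3 annotation
#' @param genome genome as a named \code{DNAStringSet} or FASTA path; used to
#'   check chromosome presence
#' @return named list of gene models; each is a list with fields
#'   \code{gene_id}, \code{gene_name}, \code{chrom}, \code{strand},
#'   \code{biotype} and \code{transcripts} (a named list of two-column
#'   integer matrices \code{start}/\code{end}, 0-based half-open, sorted by
#'   genomic coordinate)
#' @export
parseAnnotation <- function(gff3_path, genome) {
  genome <- loadGenome(genome)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(mc)) {
    vapply(as.list(mc$Parent), function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  isGene <- type == "gene"
  isTx   <- type %in% c("transcript", "mRNA")
  isExon <- type == "exon"

  geneIdx <- which(isGene)
  geneIds <- ids[geneIdx]
  names(geneIdx) <- geneIds

  biotype <- rep(NA_character_, length(gr))
  for (col in c("gene_type", "gene_biotype", "biotype")) {
    if (col %in% names(mc)) {
      v <- as.character(mc[[col]])
      biotype[is.na(biotype) & !is.na(v)] <- v[is.na(biotype) & !is.na(v)]
    }
  }
  gname <- if ("gene_name" %in% names(mc)) as.character(mc$gene_name) else ids

  # transcript -> gene resolution
  txIdx <- which(isTx)
  txIds <- ids[txIdx]
  txGene <- parents[txIdx]
  bad <- is.na(txGene) | !(txGene %in% geneIds)
  if (any(bad)) {
    warning(sum(bad), " transcript record(s) with unresolvable Parent skipped")
    txIdx <- txIdx[!bad]; txIds <- txIds[!bad]; txGene <- txGene[!bad]
  }
  names(txGene) <- txIds

  exIdx <- which(isExon)
  exTx <- parents[exIdx]
  bad <- is.na(exTx) | !(exTx %in% txIds)
  if (any(bad)) {
    warning(sum(bad), " exon record(s) with unresolvable Parent skipped")
    exIdx <- exIdx[!bad]; exTx <- exTx[!bad]
  }

  exStart <- GenomicRanges::start(gr)[exIdx] - 1L  # to 0-based half-open
  exEnd   <- GenomicRanges::end(gr)[exIdx]
  exByTx  <- split(seq_along(exIdx), exTx)

  models <- list()
  for (g in seq_along(geneIdx)) {
    i <- geneIdx[[g]]
    gid <- geneIds[[g]]
    chrom <- as.character(GenomicRanges::seqnames(gr))[i]
    if (!chrom %in% names(genome))
      stop("chromosome '", chrom, "' referenced by gene '", gid,
           "' is absent from the genome")
    txs <- txIds[txGene == gid]
    txl <- list()
    for (t in txs) {
      rows <- exByTx[[t]]
      if (is.null(rows) || !length(rows)) next
      m <- cbind(start = exStart[rows], end = exEnd[rows])
      m <- m[order(m[, "start"]), , drop = FALSE]
      txl[[t]] <- m
    }
    if (!length(txl)) {
      warning("gene '", gid, "' has no exon features; dropped")
      next
    }
    models[[gid]] <- list(
      gene_id = gid,
      gene_name = if (!is.na(gname[i])) gname[i] else gid,
      chrom = chrom,
      strand = as.character(GenomicRanges::strand(gr))[i],
      biotype = if (!is.na(biotype[i])) biotype[i] else "unknown",
      transcripts = txl
    )
  }
  models
}
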