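# Shared low-level helpers: coordinate conventions and sequence access.
#
# All internal coordinates are 0-based half-open [start, end); GFF3 I/O
# converts from/to 1-based closed, and every breakpoint reported to the user
# is a 1-based genomic position.

#' Reverse-complement a character vector of DNA sequences
#' @param x character vector over the alphabet {A,C,G,T,N}
#' @return character vector of reverse complements
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Load a genome as a named DNAStringSet
#'
#' Accepts an in-memory \code{DNAStringSet} or a FASTA file path. Sequence
#' names are truncated at the first whitespace, matching common FASTA usage.
#' @param genome DNAStringSet or path to a FASTA file
#' @return named DNAStringSet
#' @export
loadGenome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    gs <- genome
  } else if (is.character(genome) && length(genome) == 1L) {
    gs <- Biostrings::readDNAStringSet(genome)
  } else {
    stop("genome must be a DNAStringSet or a FASTA file path")
  }
  names(gs) <- sub("\\s.*$", "", names(gs))
  gs
}

# Extract [start, end) (0-based half-open) from one chromosome as character.
extractSeq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' absent from genome")
  chr <- genome[[chrom]]
  if (start < 0L || end > length(chr))
    stop("interval [", start, ",", end, ") outside chromosome '", chrom, "'")
  as.character(Biostrings::subseq(chr, start + 1L, end))
}

# Deterministic RNG scope: run expr under a seed without disturbing the
# caller's RNG stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Edit distance between two sequences (full global Levenshtein).
editDistance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

# Write a simple FASTA file from a named character vector.
writeFastaChr <- function(seqs, path) {
  if (length(seqs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
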