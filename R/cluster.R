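# Two-stage clustering of validated fusion candidates (breakpoint-based
# coarse, exact-path fine) and star-alignment consensus generation.

#' Coarse clustering of candidates by breakpoint proximity
#'
#' Within each (gene5, gene3) pair, single-linkage groups candidates whose
#' breakpoint pairs are connected by a chain of Manhattan distances
#' \code{|x_i - x_j| + |y_i - y_j| <= radius}, where (x, y) are the 5' and 3'
#' partner breakpoint coordinates. Clustering never crosses gene pairs.
#'
#' @param candidates data.frame with columns \code{gene5}, \code{gene3},
#'   \code{bp5}, \code{bp3}
#' @param radius linkage radius in bp (default 100)
#' @return integer vector of coarse cluster ids, one per candidate row
#' @export
coarseCluster <- function(candidates, radius = 100L) {
  n <- nrow(candidates)
  if (!n) return(integer())
  key <- paste(candidates$gene5, candidates$gene3, sep = "\r")
  out <- character(n)
  for (k in unique(key)) {
    rows <- which(key == k)
    if (length(rows) == 1L) {
      out[rows] <- paste0(k, "\r1")
      next
    }
    d <- stats::dist(cbind(candidates$bp5[rows], candidates$bp3[rows]),
                     method = "manhattan")
    hc <- stats::hclust(d, method = "single")
    out[rows] <- paste0(k, "\r", stats::cutree(hc, h = radius))
  }
  as.integer(factor(out, levels = unique(out)))
}

#' Fine clustering by exact graph path identity
#'
#' Within each coarse cluster, reads are assigned to the same final cluster
#' only when their full ordered node path across both partners is identical,
#' so every final cluster carries a unique breakpoint-path identifier and
#' represents one fusion isoform. Cluster ids are ordered deterministically
#' by (coarse cluster, path signature).
#'
#' @param candidates data.frame with \code{path5}, \code{path3}
#' @param coarse integer vector from \code{\link{coarseCluster}}
#' @return integer vector of final cluster ids
#' @export
fineCluster <- function(candidates, coarse) {
  if (!nrow(candidates)) return(integer())
  sig <- paste(candidates$path5, candidates$path3, sep = "|")
  key <- paste(formatC(coarse, width = 9, flag = "0"), sig, sep = "\r")
  as.integer(factor(key, levels = sort(unique(key))))
}

# --- consensus ---------------------------------------------------------------

#' Consensus of noisy long-read sequences by star alignment
#'
#' Builds an error-corrected consensus by globally aligning every member to a
#' center read (the member of median length) and voting per center position:
#' the majority base wins (a majority deletion removes the position) and an
#' insertion is emitted only when more than half of the members carry the
#' identical inserted string at the same position. A single sequence is its
#' own consensus.
#'
#' @param seqs character vector of member sequences (same orientation)
#' @param max_members cap on members used (deterministic prefix; default 30)
#' @return consensus sequence (character scalar)
#' @export
starConsensus <- function(seqs, max_members = 30L) {
  seqs <- seqs[nzchar(seqs)]
  if (!length(seqs)) stop("empty cluster: no sequences for consensus")
  if (length(seqs) > max_members) seqs <- seqs[seq_len(max_members)]
  m <- length(seqs)
  if (m == 1L) return(unname(seqs))
  ci <- order(nchar(seqs))[ceiling(m / 2)]
  center <- seqs[[ci]]
  others <- seqs[-ci]
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(others), Biostrings::DNAString(center),
    type = "global", substitutionMatrix = .subMat,
    gapOpening = 4, gapExtension = 2)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  L <- nchar(center)
  baseVotes <- vector("list", m)
  insVotes <- vector("list", m)
  cc <- strsplit(center, "")[[1L]]
  baseVotes[[1L]] <- data.table::data.table(pos = seq_len(L), base = cc)
  for (i in seq_along(others)) {
    pc <- strsplit(p[i], "")[[1L]]
    sc <- strsplit(s[i], "")[[1L]]
    cpos <- cumsum(sc != "-")
    nonins <- sc != "-"
    baseVotes[[i + 1L]] <- data.table::data.table(
      pos = cpos[nonins], base = pc[nonins])
    if (any(!nonins)) {
      r <- rle(nonins)
      ends <- cumsum(r$lengths)
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      gapruns <- which(!r$values)
      insVotes[[i + 1L]] <- data.table::data.table(
        pos = cpos[starts[gapruns]],
        ins = vapply(gapruns, function(g)
          paste(pc[starts[g]:ends[g]], collapse = ""), character(1)))
    }
  }
  bv <- data.table::rbindlist(baseVotes)
  cnt <- bv[, .N, by = .(pos, base)]
  cnt[, center_base := cc[pos]]
  data.table::setorder(cnt, pos, -N, base)
  # prefer center's base on ties
  cnt[, tie_rank := ifelse(base == center_base, 0L, 1L)]
  data.table::setorder(cnt, pos, -N, tie_rank, base)
  win <- cnt[, .SD[1L], by = pos]
  chosen <- stats::setNames(win$base, win$pos)
  iv <- data.table::rbindlist(insVotes)
  insAt <- stats::setNames(character(L + 1L), 0:L)
  if (!is.null(iv) && nrow(iv)) {
    ic <- iv[, .N, by = .(pos, ins)]
    ic <- ic[N > m / 2]
    if (nrow(ic)) {
      data.table::setorder(ic, pos, -N, ins)
      ic <- ic[, .SD[1L], by = pos]
      insAt[as.character(ic$pos)] <- ic$ins
    }
  }
  parts <- character(L + 1L)
  parts[1L] <- insAt[["0"]]
  for (pos in seq_len(L)) {
    b <- chosen[[as.character(pos)]]
    parts[pos + 1L] <- paste0(if (identical(b, "-")) "" else b,
                              insAt[[as.character(pos)]])
  }
  paste(parts, collapse = "")
}

#' Build the three consensus sequences of a fusion cluster
#'
#' Splits each sense-oriented member read at its junction position into the
#' 5' partner fragment and the 3' partner fragment, then derives three
#' consensus sequences: the 5' fragment and the 3' fragment via
#' \code{\link{starConsensus}}, and the full-length chimeric transcript as
#' their concatenation (the fragments partition each read exactly at the
#' junction, so the concatenated consensus spans the junction without a
#' third, more expensive full-length alignment). A single-member cluster
#' returns the read itself.
#'
#' @param seqs sense-oriented member read sequences (character)
#' @param junction_pos per-read junction position (0-based offset on the
#'   sense-oriented read: the 5' fragment is \code{[1, junction]})
#' @param max_members consensus member cap (default 30)
#' @return list with \code{five_prime}, \code{three_prime},
#'   \code{full_length}
#' @export
buildConsensus <- function(seqs, junction_pos, max_members = 30L) {
  if (!length(seqs)) stop("empty cluster: no member reads")
  stopifnot(length(seqs) == length(junction_pos))
  L <- nchar(seqs)
  j <- pmin(pmax(as.integer(junction_pos), 1L), L - 1L)
  five <- substr(seqs, 1L, j)
  three <- substr(seqs, j + 1L, L)
  cons5 <- starConsensus(five, max_members)
  cons3 <- starConsensus(three, max_members)
  list(five_prime = cons5, three_prime = cons3,
       full_length = paste0(cons5, cons3))
}

#' Cluster validated candidates and generate cluster consensus sequences
#'
#' Runs coarse (breakpoint Manhattan) then fine (exact path) clustering and
#' assembles one record per final cluster with its breakpoint-path identity,
#' member reads and the three consensus sequences.
#'
#' @param validated passing candidates from \code{\link{validateJunction}}
#' @param reads named character vector of read sequences
#' @param radius coarse clustering radius in bp (default 100)
#' @param max_members consensus member cap per cluster
#' @return data.frame with one row per cluster: \code{cluster_id},
#'   \code{gene5}, \code{gene3}, \code{chrom5}, \code{chrom3}, \code{bp5},
#'   \code{bp3}, \code{path_signature}, \code{n_reads}, list column
#'   \code{members}, and consensus columns \code{cons5}, \code{cons3},
#'   \code{consFull}
#' @export
clusterCandidates <- function(validated, reads, radius = 100L,
                              max_members = 30L) {
  empty <- data.frame(cluster_id = integer(), gene5 = character(),
                      gene3 = character(), chrom5 = character(),
                      chrom3 = character(), bp5 = integer(), bp3 = integer(),
                      path_signature = character(), n_reads = integer(),
                      cons5 = character(), cons3 = character(),
                      consFull = character(), stringsAsFactors = FALSE)
  empty$members <- list()
  if (!nrow(validated)) return(empty)
  coarse <- coarseCluster(validated, radius)
  fine <- fineCluster(validated, coarse)
  out <- vector("list", max(fine))
  for (cl in sort(unique(fine))) {
    rows <- validated[fine == cl, , drop = FALSE]
    sense <- vapply(seq_len(nrow(rows)), function(i) {
      s <- reads[[rows$read_id[i]]]
      if (rows$read_orient[i] == "-") revComp(s) else s
    }, character(1))
    cons <- buildConsensus(sense, rows$junction_read_pos, max_members)
    rec <- data.frame(
      cluster_id = cl, gene5 = rows$gene5[1L], gene3 = rows$gene3[1L],
      chrom5 = rows$chrom5[1L], chrom3 = rows$chrom3[1L],
      bp5 = rows$bp5[1L], bp3 = rows$bp3[1L],
      path_signature = paste(rows$path5[1L], rows$path3[1L], sep = "|"),
      n_reads = nrow(rows), cons5 = cons$five_prime,
      cons3 = cons$three_prime, consFull = cons$full_length,
      stringsAsFactors = FALSE)
    rec$members <- list(rows$read_id)
    out[[cl]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
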