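# Candidate fusion screening: reads whose graph alignment path touches two or
# more gene subgraphs are decomposed into per-gene segments, assigned 5'/3'
# partner roles, given graph-derived breakpoints via the exon max/min rule,
# and validated by spliced re-alignment against a dual-gene custom reference
# under five filter criteria.

#' Graph-rule breakpoint for one partner's signed node path
#'
#' Implements the exon max/min rule. A partner path is traversed "forward"
#' when its genomic coordinates ascend, i.e. when the node orientation sign
#' agrees with the gene strand ('>' on a plus-strand gene or '<' on a
#' minus-strand gene). The 5' partner's breakpoint is the maximum exon
#' coordinate in the path under forward traversal and the minimum under
#' reverse traversal; the 3' partner uses the opposite ends. Positions are
#' reported 1-based.
#'
#' @param graph \linkS4class{SpliceGraph}
#' @param path signed node path string for one partner (e.g. \code{">a>b"})
#' @param role \code{"5p"} or \code{"3p"}
#' @return 1-based genomic breakpoint position (integer)
#' @export
partnerBreakpoint <- function(graph, path, role = c("5p", "3p")) {
  role <- match.arg(role)
  pp <- gafPath(path)
  rows <- graph@nodes[vapply(pp$node, function(n) {
    i <- graph@index[[n]]
    if (is.null(i)) stop("unknown node_id '", n, "'") else i
  }, integer(1)), , drop = FALSE]
  strand <- graph@geneMeta$strand[match(rows$gene_id[1L],
                                        graph@geneMeta$gene_id)]
  forward <- (pp$orient[1L] == ">") == (strand != "-")
  starts1 <- rows$start + 1L
  ends1 <- rows$end
  if (role == "5p") {
    if (forward) max(ends1) else min(starts1)
  } else {
    if (forward) min(starts1) else max(ends1)
  }
}

# Flip a signed path to transcript-sense order ('<' path reversed to '>').
senseOrientPath <- function(path) {
  pp <- gafPath(path)
  if (all(pp$orient == "<"))
    pathString(rev(pp$node), rep(">", nrow(pp)))
  else path
}

#' Assign 5'/3' partner roles to two alignment segments of one read
#'
#' Orients the read to transcript sense (a read whose segments traverse the
#' graph in reverse is reverse-complemented conceptually), fixes which
#' partner contributes the upstream portion, canonicalises both partner paths
#' to sense order, and computes graph-derived breakpoints with
#' \code{\link{partnerBreakpoint}}.
#'
#' @param graph \linkS4class{SpliceGraph}
#' @param segs data.frame of exactly two segments with columns \code{gene},
#'   \code{path}, \code{query_start}, \code{query_end}, \code{orient}
#' @param read_len read length in bp
#' @return list with \code{gene5}, \code{gene3}, \code{path5}, \code{path3}
#'   (sense order), 1-based breakpoints \code{bp5}, \code{bp3},
#'   \code{read_orient} and oriented query intervals \code{q5}, \code{q3};
#'   \code{dir_consistent} is FALSE when the two segments disagree in
#'   traversal orientation
#' @export
assignPartnerOrder <- function(graph, segs, read_len) {
  stopifnot(nrow(segs) == 2L)
  o <- order(segs$query_start)
  segs <- segs[o, , drop = FALSE]
  or1 <- gafPath(segs$path[1L])$orient[1L]
  or2 <- gafPath(segs$path[2L])$orient[1L]
  dir_consistent <- or1 == or2
  read_orient <- if (or1 == "<" && or2 == "<") "-" else "+"
  flipQ <- function(qs, qe) c(read_len - qe, read_len - qs)
  if (read_orient == "-") {
    i5 <- 2L; i3 <- 1L
    q5 <- flipQ(segs$query_start[i5], segs$query_end[i5])
    q3 <- flipQ(segs$query_start[i3], segs$query_end[i3])
  } else {
    i5 <- 1L; i3 <- 2L
    q5 <- c(segs$query_start[i5], segs$query_end[i5])
    q3 <- c(segs$query_start[i3], segs$query_end[i3])
  }
  path5 <- senseOrientPath(segs$path[i5])
  path3 <- senseOrientPath(segs$path[i3])
  list(gene5 = segs$gene[i5], gene3 = segs$gene[i3],
       path5 = path5, path3 = path3,
       bp5 = partnerBreakpoint(graph, path5, "5p"),
       bp3 = partnerBreakpoint(graph, path3, "3p"),
       read_orient = read_orient, q5 = q5, q3 = q3,
       dir_consistent = dir_consistent)
}

# Decompose one GAF record into per-gene segments with apportioned query
# intervals (external aligners may emit one record spanning both genes).
.recordSegments <- function(rec, graph) {
  pp <- gafPath(rec$path)
  genes <- genesOfNodes(graph, pp$node)
  r <- rle(genes)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lens <- nchar(graph@nodes$seq[vapply(pp$node, function(n)
    graph@index[[n]], integer(1))])
  cum <- cumsum(lens)
  total <- cum[length(cum)]
  span <- rec$query_end - rec$query_start
  out <- vector("list", length(r$values))
  for (i in seq_along(r$values)) {
    sel <- starts[i]:ends[i]
    frac0 <- if (starts[i] == 1L) 0 else cum[starts[i] - 1L] / total
    frac1 <- cum[ends[i]] / total
    out[[i]] <- data.frame(
      gene = r$values[i],
      path = pathString(pp$node[sel], pp$orient[sel]),
      query_start = as.integer(rec$query_start + round(frac0 * span)),
      query_end = as.integer(rec$query_start + round(frac1 * span)),
      orient = pp$orient[sel][1L], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Identify candidate fusion reads from graph alignments
#'
#' Groups GAF records per read, decomposes paths into per-gene segments, and
#' emits one candidate per adjacent gene pair along the read. Reads confined
#' to a single gene produce nothing; reads touching three or more genes are
#' decomposed into adjacent pairs and flagged \code{multi_partner}.
#'
#' @param gaf data.frame of GAF records (see \code{\link{parseGaf}})
#' @param graph \linkS4class{SpliceGraph} used for the alignment
#' @return data.frame of candidates (one row per read and gene pair) with
#'   partner roles, sense-ordered paths, graph-derived 1-based breakpoints,
#'   oriented query intervals and a preliminary junction position
#' @export
findMultigeneReads <- function(gaf, graph) {
  empty <- data.frame(
    read_id = character(), gene5 = character(), gene3 = character(),
    chrom5 = character(), chrom3 = character(), bp5 = integer(),
    bp3 = integer(), path5 = character(), path3 = character(),
    q5_start = integer(), q5_end = integer(), q3_start = integer(),
    q3_end = integer(), read_len = integer(), read_orient = character(),
    junction_read_pos = integer(), n_records = integer(),
    multi_partner = logical(), dir_consistent = logical(),
    stringsAsFactors = FALSE)
  if (!nrow(gaf)) return(empty)
  meta <- graph@geneMeta
  chromOf <- stats::setNames(meta$chrom, meta$gene_id)
  out <- list()
  for (rid in unique(gaf$read_id)) {
    recs <- gaf[gaf$read_id == rid, , drop = FALSE]
    segs <- do.call(rbind, lapply(seq_len(nrow(recs)), function(i)
      .recordSegments(recs[i, ], graph)))
    segs <- segs[order(segs$query_start), , drop = FALSE]
    # merge duplicate adjacent same-gene segments, keeping the longer path
    keep <- rep(TRUE, nrow(segs))
    for (i in seq_len(nrow(segs) - 1L)) {
      if (!keep[i]) next
      j <- i + 1L
      if (segs$gene[j] == segs$gene[i]) {
        longer <- if (nchar(segs$path[j]) > nchar(segs$path[i])) j else i
        segs$path[i] <- segs$path[longer]
        segs$query_end[i] <- max(segs$query_end[i], segs$query_end[j])
        keep[j] <- FALSE
      }
    }
    segs <- segs[keep, , drop = FALSE]
    if (length(unique(segs$gene)) < 2L) next
    rl <- recs$read_len[1L]
    multi <- length(unique(segs$gene)) > 2L
    for (i in seq_len(nrow(segs) - 1L)) {
      if (segs$gene[i] == segs$gene[i + 1L]) next
      a <- assignPartnerOrder(graph, segs[i:(i + 1L), , drop = FALSE], rl)
      out[[length(out) + 1L]] <- data.frame(
        read_id = rid, gene5 = a$gene5, gene3 = a$gene3,
        chrom5 = chromOf[[a$gene5]], chrom3 = chromOf[[a$gene3]],
        bp5 = a$bp5, bp3 = a$bp3, path5 = a$path5, path3 = a$path3,
        q5_start = a$q5[1L], q5_end = a$q5[2L],
        q3_start = a$q3[1L], q3_end = a$q3[2L],
        read_len = rl, read_orient = a$read_orient,
        junction_read_pos = as.integer(floor((a$q5[2L] + a$q3[1L]) / 2)),
        n_records = nrow(recs), multi_partner = multi,
        dir_consistent = a$dir_consistent, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a consolidated dual-gene custom reference
#'
#' For every candidate gene pair, writes the full genomic span of each
#' partner (plus a flank, clipped at chromosome ends) as one FASTA record per
#' gene per pair, all consolidated into a single file so candidate reads can
#' be re-mapped in one pass. Record ids encode pair index, partner role and
#' gene id as \code{pair<i>|5p|<gene_id>}.
#'
#' @param pairs data.frame with columns \code{gene5}, \code{gene3}
#' @param genome named \code{DNAStringSet} or FASTA path
#' @param meta gene metadata (\code{geneMeta} of a graph)
#' @param flank flank size in bp on each side (default 1000)
#' @param path output FASTA path
#' @return the path, invisibly
#' @export
buildCustomReference <- function(pairs, genome, meta,
                                 flank = 1000L,
                                 path = tempfile(fileext = ".fa")) {
  genome <- loadGenome(genome)
  if (!nrow(pairs)) {
    file.create(path)
    return(invisible(path))
  }
  seqs <- character()
  for (i in seq_len(nrow(pairs))) {
    for (role in c("5p", "3p")) {
      g <- if (role == "5p") pairs$gene5[i] else pairs$gene3[i]
      m <- meta[meta$gene_id == g, , drop = FALSE]
      if (!nrow(m)) stop("gene '", g, "' missing from metadata")
      chrLen <- nchar(as.character(genome[[m$chrom]]))
      s <- max(0L, m$start - flank)
      e <- min(chrLen, m$end + flank)
      if (m$start < 0L || m$end > chrLen)
        stop("gene span of '", g, "' outside genome bounds")
      seqs[sprintf("pair%d|%s|%s", i, role, g)] <-
        extractSeq(genome, m$chrom, s, e)
    }
  }
  writeFastaChr(seqs, path)
  invisible(path)
}

# Builtin spliced re-alignment of candidate read segments against partner
# transcript paths; local alignment, vectorised per (gene, transcript).
# Returns one row per candidate with per-partner intervals and identities.
.subMat <- local({
  m <- matrix(-4, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                        c("A", "C", "G", "T", "N")))
  diag(m) <- 2
  m["N", ] <- -1; m[, "N"] <- -1; m["N", "N"] <- -1
  m
})

realignBuiltin <- function(candidates, reads, graph, pad = 50L) {
  n <- nrow(candidates)
  res <- data.frame(re5_qs = rep(NA_integer_, n), re5_qe = NA_integer_,
                    re3_qs = NA_integer_, re3_qe = NA_integer_,
                    id5 = NA_real_, id3 = NA_real_)
  if (!n) return(res)
  rp <- refPaths(graph)
  txByGene <- split(unique(rp$layout[, .(tx, gene_id)])$tx,
                    unique(rp$layout[, .(tx, gene_id)])$gene_id)
  senseRead <- function(i) {
    s <- reads[[candidates$read_id[i]]]
    if (candidates$read_orient[i] == "-") revComp(s) else s
  }
  # one task per candidate x partner role
  tasks <- data.table::data.table(
    cand = rep(seq_len(n), 2L),
    role = rep(c("5p", "3p"), each = n),
    gene = c(candidates$gene5, candidates$gene3),
    qs = c(candidates$q5_start, candidates$q3_start),
    qe = c(candidates$q5_end, candidates$q3_end))
  tasks[, seg_start := pmax(0L, qs - pad)]
  tasks[, seg_end := pmin(candidates$read_len[cand], qe + pad)]
  tasks <- tasks[seg_end - seg_start >= 10L]
  if (!nrow(tasks)) return(res)
  sense <- vapply(seq_len(n), senseRead, character(1))
  tasks[, pattern := substr(sense[cand], seg_start + 1L, seg_end)]
  best <- vector("list", nrow(tasks))
  for (g in unique(tasks$gene)) {
    rows <- which(tasks$gene == g)
    for (tx in txByGene[[g]]) {
      subj <- Biostrings::DNAString(rp$seqs[[tx]])
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(tasks$pattern[rows]), subj,
        type = "local", substitutionMatrix = .subMat,
        gapOpening = 4, gapExtension = 2)
      sc <- Biostrings::score(aln)
      idv <- Biostrings::pid(aln) / 100
      ps <- Biostrings::start(Biostrings::pattern(aln))
      pe <- Biostrings::end(Biostrings::pattern(aln))
      for (j in seq_along(rows)) {
        r <- rows[j]
        if (is.null(best[[r]]) || sc[j] > best[[r]]$score)
          best[[r]] <- list(score = sc[j], id = idv[j],
                            qs = tasks$seg_start[r] + ps[j] - 1L,
                            qe = tasks$seg_start[r] + pe[j])
      }
    }
  }
  for (j in seq_len(nrow(tasks))) {
    b <- best[[j]]
    if (is.null(b)) next
    i <- tasks$cand[j]
    if (tasks$role[j] == "5p") {
      res$re5_qs[i] <- b$qs; res$re5_qe[i] <- b$qe; res$id5[i] <- b$id
    } else {
      res$re3_qs[i] <- b$qs; res$re3_qe[i] <- b$qe; res$id3[i] <- b$id
    }
  }
  res
}

# Parse a PAF file (12 mandatory columns + tags).
parsePaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(qname = character(), qlen = integer(),
                      qstart = integer(), qend = integer(),
                      strand = character(), tname = character(),
                      tlen = integer(), tstart = integer(), tend = integer(),
                      nmatch = integer(), alen = integer(), mapq = integer(),
                      de = numeric(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  col <- function(i) vapply(f, `[[`, "", i)
  de <- vapply(f, function(x) {
    hit <- grep("^de:f:", x, value = TRUE)
    if (length(hit)) as.numeric(sub("^de:f:", "", hit[1L])) else NA_real_
  }, numeric(1))
  data.frame(qname = col(1L), qlen = as.integer(col(2L)),
             qstart = as.integer(col(3L)), qend = as.integer(col(4L)),
             strand = col(5L), tname = col(6L), tlen = as.integer(col(7L)),
             tstart = as.integer(col(8L)), tend = as.integer(col(9L)),
             nmatch = as.integer(col(10L)), alen = as.integer(col(11L)),
             mapq = as.integer(col(12L)), de = de, stringsAsFactors = FALSE)
}

# External spliced re-alignment (minimap2-class) of candidate reads against
# the consolidated custom reference; fills the same columns as
# realignBuiltin. Candidate pair index i must match the pair<i>|role|gene
# record ids produced by buildCustomReference for `pairs`.
realignExternal <- function(candidates, pairs, reads, customRef,
                            bin = "minimap2",
                            opts = c("-x", "splice", "-k", "11", "-w", "3",
                                     "-c", "--secondary=no")) {
  if (Sys.which(bin) == "")
    stop("external spliced aligner '", bin, "' not found on PATH")
  rf <- tempfile(fileext = ".fa")
  writeFastaChr(reads[unique(candidates$read_id)], rf)
  paf <- tempfile(fileext = ".paf")
  status <- system2(bin, c(opts, customRef, rf), stdout = paf,
                    stderr = FALSE)
  if (!identical(status, 0L)) stop("external aligner '", bin, "' failed")
  hits <- parsePaf(paf)
  n <- nrow(candidates)
  res <- data.frame(re5_qs = rep(NA_integer_, n), re5_qe = NA_integer_,
                    re3_qs = NA_integer_, re3_qe = NA_integer_,
                    id5 = NA_real_, id3 = NA_real_)
  pairKey <- paste(pairs$gene5, pairs$gene3)
  for (i in seq_len(n)) {
    pi <- match(paste(candidates$gene5[i], candidates$gene3[i]), pairKey)
    if (is.na(pi)) next
    for (role in c("5p", "3p")) {
      g <- if (role == "5p") candidates$gene5[i] else candidates$gene3[i]
      # a gene region may be present under several pair records; minimap2
      # reports only one of the duplicates, so match by the gene suffix
      h <- hits[hits$qname == candidates$read_id[i] &
                  endsWith(hits$tname, paste0("|", g)), , drop = FALSE]
      if (!nrow(h)) next
      h <- h[which.max(h$nmatch), , drop = FALSE]
      # convert to sense-oriented read coordinates
      qs <- h$qstart; qe <- h$qend
      if (candidates$read_orient[i] == "-") {
        tmp <- qs; qs <- h$qlen - qe; qe <- h$qlen - tmp
      }
      # gap-compressed divergence (de tag) excludes introns of the spliced
      # alignment; fall back to matches over the query span
      idv <- if (!is.na(h$de)) 1 - h$de
             else h$nmatch / max(1L, h$qend - h$qstart)
      if (role == "5p") {
        res$re5_qs[i] <- qs; res$re5_qe[i] <- qe; res$id5[i] <- idv
      } else {
        res$re3_qs[i] <- qs; res$re3_qe[i] <- qe; res$id3[i] <- idv
      }
    }
  }
  res
}

#' Validate candidate fusion junctions with five filter criteria
#'
#' Re-aligns each candidate read's partner segments (builtin spliced
#' re-alignment against partner transcript paths, or an external
#' minimap2-class aligner against the dual-gene custom reference) and retains
#' a candidate only if all five criteria hold: (1) structural consistency --
#' the re-alignment reproduces the graph alignment's gene order and read
#' intervals within the junction slack; (2) transcriptional direction
#' consistency -- both partners support one coherent chimeric transcript;
#' (3) minimum block length per partner; (4) junction validation -- the
#' read-coordinate gap or overlap between the partner blocks does not exceed
#' the slack; (5) anomaly removal -- bounded alignment fragmentation and a
#' minimum per-partner identity. Rejections carry the first failed filter's
#' label.
#'
#' @param candidates output of \code{\link{findMultigeneReads}}
#' @param reads named character vector of read sequences
#' @param graph \linkS4class{SpliceGraph}
#' @param min_block_len minimum partner block length in bp (default 30)
#' @param junction_slack max junction gap/overlap in bp (default 50)
#' @param min_identity minimum partner alignment identity (default 0.80)
#' @param max_fragments max alignment records per read (default 4)
#' @param backend \code{"builtin"} or \code{"external:<binary>"}
#' @param genome genome, required by the external backend to build the
#'   custom reference
#' @param flank custom-reference flank in bp (external backend)
#' @return candidates with re-alignment columns, per-filter logicals
#'   (\code{f_structural}, \code{f_direction}, \code{f_min_block_length},
#'   \code{f_junction}, \code{f_anomaly}), \code{pass} and
#'   \code{reject_reason}; \code{junction_read_pos} is refined to the
#'   midpoint of the re-aligned junction for retained reads
#' @export
validateJunction <- function(candidates, reads, graph,
                             min_block_len = 30L, junction_slack = 50L,
                             min_identity = 0.80, max_fragments = 4L,
                             backend = "builtin", genome = NULL,
                             flank = 1000L) {
  if (!nrow(candidates)) {
    candidates$f_structural <- logical()
    candidates$f_direction <- logical()
    candidates$f_min_block_length <- logical()
    candidates$f_junction <- logical()
    candidates$f_anomaly <- logical()
    candidates$pass <- logical()
    candidates$reject_reason <- character()
    return(candidates)
  }
  if (identical(backend, "external")) backend <- "external:minimap2"
  re <- if (identical(backend, "builtin")) {
    realignBuiltin(candidates, reads, graph)
  } else if (startsWith(backend, "external:")) {
    pairs <- unique(candidates[, c("gene5", "gene3")])
    ref <- buildCustomReference(pairs, genome, graph@geneMeta, flank)
    realignExternal(candidates, pairs, reads, ref,
                    bin = sub("^external:", "", backend))
  } else stop("unknown re-alignment backend '", backend, "'")
  x <- cbind(candidates, re)
  got <- !is.na(x$re5_qs) & !is.na(x$re3_qs)
  ord_ok <- got & (x$re5_qs + x$re5_qe) < (x$re3_qs + x$re3_qe)
  x$f_structural <- ord_ok &
    abs(x$re5_qe - x$q5_end) <= junction_slack &
    abs(x$re3_qs - x$q3_start) <= junction_slack
  x$f_direction <- got & x$dir_consistent
  x$f_min_block_length <- got &
    (x$re5_qe - x$re5_qs) >= min_block_len &
    (x$re3_qe - x$re3_qs) >= min_block_len
  x$f_junction <- got & abs(x$re3_qs - x$re5_qe) <= junction_slack
  x$f_anomaly <- got & x$n_records <= max_fragments &
    !is.na(x$id5) & !is.na(x$id3) &
    x$id5 >= min_identity & x$id3 >= min_identity
  flags <- c("structural", "direction", "min_block_length", "junction",
             "anomaly")
  x$pass <- x$f_structural & x$f_direction & x$f_min_block_length &
    x$f_junction & x$f_anomaly
  x$reject_reason <- NA_character_
  for (f in rev(flags)) {
    failed <- !x[[paste0("f_", f)]]
    x$reject_reason[failed] <- f
  }
  refine <- x$pass & got
  x$junction_read_pos[refine] <-
    as.integer(floor((x$re5_qe[refine] + x$re3_qs[refine]) / 2))
  x
}
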