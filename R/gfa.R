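#' Serialize a splicing graph to GFA1
#'
#' Writes one S-line per exon node (sequence included) and one L-line per
#' splice edge with a 0M overlap CIGAR. Node metadata travels in optional
#' tags: \code{gn:Z} (gene id), \code{ch:Z} (chromosome), \code{st:i} /
#' \code{en:i} (0-based half-open genomic interval). The graph scope is kept
#' in a \code{sc:Z} tag on the header so a round trip preserves it.
#'
#' @param graph a \linkS4class{SpliceGraph}
#' @param path output file path
#' @return the path, invisibly
#' @export
writeGFA <- function(graph, path) {
  n <- graph@nodes
  e <- graph@edges
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("H\tVN:Z:1.0\tsc:Z:", graph@scope), con)
  if (nrow(n))
    writeLines(sprintf("S\t%s\t%s\tgn:Z:%s\tch:Z:%s\tst:i:%d\ten:i:%d",
                       n$node_id, n$seq, n$gene_id, n$chrom, n$start, n$end),
               con)
  if (nrow(e))
    writeLines(sprintf("L\t%s\t+\t%s\t+\t0M", e$from, e$to), con)
  invisible(path)
}

#' Read a GFA1 splicing graph
#'
#' Inverse of \code{\link{writeGFA}} for graphs this package wrote: node set,
#' edge set, gene index and scope are reconstructed exactly. Transcript paths
#' are not part of GFA1 S/L records, so \code{txPaths} of the result is
#' empty; per-gene metadata is summarised from the node table (strand and
#' biotype are unknown at this level).
#'
#' @param path GFA1 file path
#' @return a \linkS4class{SpliceGraph}
#' @export
readGFA <- function(path) {
  lines <- readLines(path)
  rtype <- substr(lines, 1L, 1L)
  scope <- "comprehensive"
  h <- lines[rtype == "H"]
  if (length(h)) {
    m <- regmatches(h[1L], regexpr("sc:Z:[A-Za-z_]+", h[1L]))
    if (length(m)) scope <- sub("^sc:Z:", "", m)
  }
  sl <- strsplit(lines[rtype == "S"], "\t", fixed = TRUE)
  tagOf <- function(fields, tag) {
    hit <- grep(paste0("^", tag, ":"), fields, value = TRUE)
    if (length(hit)) sub("^[a-z]{2}:[ZiA]:", "", hit[1L]) else NA_character_
  }
  nodes <- if (length(sl)) {
    data.frame(
      node_id = vapply(sl, `[[`, "", 2L),
      gene_id = vapply(sl, tagOf, "", tag = "gn"),
      chrom = vapply(sl, tagOf, "", tag = "ch"),
      start = as.integer(vapply(sl, tagOf, "", tag = "st")),
      end = as.integer(vapply(sl, tagOf, "", tag = "en")),
      seq = vapply(sl, `[[`, "", 3L),
      stringsAsFactors = FALSE)
  } else data.frame(node_id = character(), gene_id = character(),
                    chrom = character(), start = integer(), end = integer(),
                    seq = character(), stringsAsFactors = FALSE)
  ll <- strsplit(lines[rtype == "L"], "\t", fixed = TRUE)
  edges <- if (length(ll)) {
    data.frame(from = vapply(ll, `[[`, "", 2L),
               to = vapply(ll, `[[`, "", 4L), stringsAsFactors = FALSE)
  } else data.frame(from = character(), to = character(),
                    stringsAsFactors = FALSE)
  meta <- if (nrow(nodes)) {
    sp <- split(seq_len(nrow(nodes)), nodes$gene_id)
    do.call(rbind, lapply(names(sp), function(g) {
      i <- sp[[g]]
      data.frame(gene_id = g, gene_name = g, chrom = nodes$chrom[i[1L]],
                 strand = "*", start = min(nodes$start[i]),
                 end = max(nodes$end[i]), biotype = "unknown",
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(gene_id = character(), gene_name = character(),
                    chrom = character(), strand = character(),
                    start = integer(), end = integer(),
                    biotype = character(), stringsAsFactors = FALSE)
  idx <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(1L, nrow(nodes)))
  for (i in seq_len(nrow(nodes))) assign(nodes$node_id[i], i, envir = idx)
  tx <- data.frame(tx_id = character(), gene_id = character(),
                   stringsAsFactors = FALSE)
  tx$nodes <- list()
  methods::new("SpliceGraph", nodes = nodes, edges = edges, geneMeta = meta,
               transcripts = tx, scope = scope, index = idx)
}
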