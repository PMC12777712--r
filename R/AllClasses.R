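#' SpliceGraph: an exon-level reference splicing graph
#'
#' A directed acyclic graph whose vertices are annotated exons and whose
#' edges are splice junctions observed in at least one annotated transcript.
#' Each exon node is the four-tuple (gene_id, chrom, start, end) plus its
#' nucleotide sequence normalised to the transcript sense strand, so that
#' concatenating node sequences along a transcript path yields the spliced
#' mRNA. Gene subgraphs are disjoint: no reference edge ever joins two genes,
#' which is exactly what lets a multi-gene alignment path flag a candidate
#' fusion read.
#'
#' Two scopes are supported: \code{"comprehensive"} (every annotated gene;
#' used for the initial sensitive alignment) and \code{"protein_coding"}
#' (protein-coding genes only; used for high-precision re-validation). The
#' protein-coding graph is always a subgraph of the comprehensive one built
#' from the same annotation.
#'
#' @slot nodes data.frame with columns \code{node_id}, \code{gene_id},
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open) and
#'   \code{seq} (sense-strand nucleotides, length \code{end - start}).
#' @slot edges data.frame with columns \code{from}, \code{to} (node ids);
#'   both endpoints always belong to the same gene.
#' @slot geneMeta data.frame with one row per gene: \code{gene_id},
#'   \code{gene_name}, \code{chrom}, \code{strand}, \code{start}, \code{end}
#'   (gene span, 0-based half-open), \code{biotype}.
#' @slot transcripts data.frame with columns \code{tx_id}, \code{gene_id}
#'   and a list column \code{nodes} holding each transcript's exon chain
#'   (node ids in 5'-to-3' transcript order). Empty when the graph was read
#'   back from GFA, which does not carry transcript paths.
#' @slot scope either \code{"comprehensive"} or \code{"protein_coding"}.
#' @slot index environment hashing \code{node_id} to the row number in
#'   \code{nodes}, giving O(1) expected-time gene lookup per aligned node.
#' @export
setClass("SpliceGraph",
  representation(
    nodes       = "data.frame",
    edges       = "data.frame",
    geneMeta    = "data.frame",
    transcripts = "data.frame",
    scope       = "character",
    index       = "environment"
  )
)

# Kahn topological sort; returns TRUE iff the edge set is acyclic.
.isDag <- function(node_ids, edges) {
  if (nrow(edges) == 0L) return(TRUE)
  indeg <- stats::setNames(integer(length(node_ids)), node_ids)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  out <- split(edges$to, edges$from)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (w in out[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  seen == length(node_ids)
}

setValidity("SpliceGraph", function(object) {
  n <- object@nodes
  e <- object@edges
  msgs <- character()
  need <- c("node_id", "gene_id", "chrom", "start", "end", "seq")
  if (!all(need %in% names(n)))
    return(paste("nodes must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(n$node_id)) msgs <- c(msgs, "duplicated node_id")
  if (nrow(n) && any(n$start >= n$end))
    msgs <- c(msgs, "node start must be < end (0-based half-open)")
  if (nrow(n) && any(nchar(n$seq) != n$end - n$start))
    msgs <- c(msgs, "node sequence length must equal end - start")
  if (nrow(n) && any(grepl("[^ACGTN]", n$seq)))
    msgs <- c(msgs, "node sequences restricted to A,C,G,T,N")
  if (!object@scope %in% c("comprehensive", "protein_coding"))
    msgs <- c(msgs, "scope must be 'comprehensive' or 'protein_coding'")
  if (nrow(e)) {
    if (!all(c(e$from, e$to) %in% n$node_id))
      msgs <- c(msgs, "edge endpoint not a known node")
    else {
      gid <- stats::setNames(n$gene_id, n$node_id)
      if (any(gid[e$from] != gid[e$to]))
        msgs <- c(msgs, "reference edges may not join two genes")
    }
    if (!.isDag(n$node_id, e)) msgs <- c(msgs, "graph contains a cycle")
  }
  idx <- object@index
  if (nrow(n) && length(ls(idx)) != nrow(n))
    msgs <- c(msgs, "index size disagrees with node count")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn SpliceGraph compact summary
#' @param object a SpliceGraph
#' @export
setMethod("show", "SpliceGraph", function(object) {
  cat(sprintf(
    "SpliceGraph (%s): %d exon nodes, %d splice edges, %d genes, %d transcripts\n",
    object@scope, nrow(object@nodes), nrow(object@edges),
    nrow(object@geneMeta), nrow(object@transcripts)))
})

#' Accessors for SpliceGraph components
#'
#' \code{graphNodes}, \code{graphEdges}, \code{geneMeta}, \code{txPaths} and
#' \code{graphScope} expose the exon node table, splice edge table, per-gene
#' metadata, annotated transcript node chains and graph scope.
#'
#' @param x a \linkS4class{SpliceGraph}
#' @return the corresponding data.frame (or scope string)
#' @export
graphNodes <- function(x) x@nodes

#' @rdname graphNodes
#' @export
graphEdges <- function(x) x@edges

#' @rdname graphNodes
#' @export
geneMeta <- function(x) x@geneMeta

#' @rdname graphNodes
#' @export
txPaths <- function(x) x@transcripts

#' @rdname graphNodes
#' @export
graphScope <- function(x) x@scope
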