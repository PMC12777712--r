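#' Build one gene's exon subgraph
#'
#' Creates one exon node per distinct (gene_id, chrom, start, end) across the
#' gene's transcripts and one splice edge per consecutive exon pair in any
#' transcript (deduplicated). Node sequences are extracted from the genome
#' and, for minus-strand genes, reverse-complemented, so that a stored node
#' sequence always reads in transcript sense and concatenation along a
#' transcript path reproduces the spliced mRNA. Exons that overlap but differ
#' in either boundary (cassette exons, alternative donors/acceptors) remain
#' distinct nodes.
#'
#' @param gene one gene model from \code{\link{parseAnnotation}}
#' @param genome named \code{DNAStringSet} or FASTA path
#' @return list with \code{nodes} and \code{edges} data.frames and
#'   \code{txnodes}, the per-transcript node-id chains in 5'-to-3' order
#' @export
buildGeneSubgraph <- function(gene, genome) {
  genome <- loadGenome(genome)
  minus <- identical(gene$strand, "-")
  txnodes <- list()
  nodeKey <- character()
  nodeRows <- list()
  edges <- character()
  for (t in names(gene$transcripts)) {
    m <- gene$transcripts[[t]]
    # transcript (5'->3') order: ascending genomic for '+', descending for '-'
    ord <- if (minus) rev(seq_len(nrow(m))) else seq_len(nrow(m))
    chain <- character(length(ord))
    for (k in seq_along(ord)) {
      s <- m[ord[k], "start"]; e <- m[ord[k], "end"]
      nid <- paste(gene$gene_id, gene$chrom, s, e, sep = ":")
      chain[k] <- nid
      if (!nid %in% nodeKey) {
        sq <- extractSeq(genome, gene$chrom, s, e)
        if (minus) sq <- revComp(sq)
        nodeKey <- c(nodeKey, nid)
        nodeRows[[nid]] <- data.frame(
          node_id = nid, gene_id = gene$gene_id, chrom = gene$chrom,
          start = as.integer(s), end = as.integer(e), seq = sq,
          stringsAsFactors = FALSE)
      }
    }
    if (length(chain) > 1L)
      edges <- c(edges, paste(chain[-length(chain)], chain[-1L], sep = "\t"))
    txnodes[[t]] <- chain
  }
  edges <- unique(edges)
  edf <- if (length(edges)) {
    parts <- strsplit(edges, "\t", fixed = TRUE)
    data.frame(from = vapply(parts, `[[`, "", 1L),
               to = vapply(parts, `[[`, "", 2L), stringsAsFactors = FALSE)
  } else data.frame(from = character(), to = character(),
                    stringsAsFactors = FALSE)
  list(nodes = do.call(rbind, c(nodeRows, list(make.row.names = FALSE))),
       edges = edf, txnodes = txnodes)
}

#' Build a reference splicing graph from gene models
#'
#' Unions per-gene exon subgraphs into a single DAG. With
#' \code{scope = "comprehensive"} every annotated gene contributes its
#' subgraph; with \code{scope = "protein_coding"} only genes whose biotype is
#' \code{protein_coding} do, so the protein-coding graph is always a subgraph
#' of the comprehensive one. A hash index from node id to node row supports
#' O(1) expected-time gene lookup during alignment parsing.
#'
#' @param genes gene model list from \code{\link{parseAnnotation}}
#' @param scope \code{"comprehensive"} or \code{"protein_coding"}
#' @param genome named \code{DNAStringSet} or FASTA path
#' @return a \linkS4class{SpliceGraph}
#' @examples
#' sim <- simulateBenchmark(simConfig(seed = 7, n_fusions = 2))
#' genes <- parseAnnotation(sim$gff3, sim$genome)
#' buildSpliceGraph(genes, "comprehensive", sim$genome)
#' @export
buildSpliceGraph <- function(genes,
                             scope = c("comprehensive", "protein_coding"),
                             genome) {
  scope <- match.arg(scope)
  if (!length(genes)) stop("empty gene set")
  genome <- loadGenome(genome)
  if (scope == "protein_coding")
    genes <- Filter(function(g) identical(g$biotype, "protein_coding"), genes)
  if (!length(genes))
    stop("no genes in scope '", scope, "'")
  nodeL <- vector("list", length(genes))
  edgeL <- vector("list", length(genes))
  txL <- vector("list", length(genes))
  metaL <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    sub <- buildGeneSubgraph(g, genome)
    nodeL[[i]] <- sub$nodes
    edgeL[[i]] <- sub$edges
    txL[[i]] <- data.frame(tx_id = names(sub$txnodes),
                           gene_id = g$gene_id, stringsAsFactors = FALSE)
    txL[[i]]$nodes <- unname(sub$txnodes)
    allex <- do.call(rbind, lapply(g$transcripts, identity))
    metaL[[i]] <- data.frame(
      gene_id = g$gene_id, gene_name = g$gene_name, chrom = g$chrom,
      strand = g$strand, start = as.integer(min(allex[, "start"])),
      end = as.integer(max(allex[, "end"])), biotype = g$biotype,
      stringsAsFactors = FALSE)
  }
  nodes <- do.call(rbind, c(nodeL, list(make.row.names = FALSE)))
  edges <- do.call(rbind, c(edgeL, list(make.row.names = FALSE)))
  txs <- do.call(rbind, c(txL, list(make.row.names = FALSE)))
  meta <- do.call(rbind, c(metaL, list(make.row.names = FALSE)))
  idx <- new.env(hash = TRUE, parent = emptyenv(), size = nrow(nodes))
  for (i in seq_len(nrow(nodes))) assign(nodes$node_id[i], i, envir = idx)
  methods::new("SpliceGraph", nodes = nodes, edges = edges, geneMeta = meta,
               transcripts = txs, scope = scope, index = idx)
}

#' Resolve an aligned node to its gene
#'
#' Hash lookup of a node id, returning the owning gene and the full exon node
#' record; the workhorse behind multi-gene path screening.
#'
#' @param graph a \linkS4class{SpliceGraph}
#' @param node_id node identifier as found in alignment paths
#' @return list with \code{gene_id} and \code{node} (one-row data.frame)
#' @export
geneOfNode <- function(graph, node_id) {
  i <- graph@index[[node_id]]
  if (is.null(i)) stop("unknown node_id '", node_id, "'")
  list(gene_id = graph@nodes$gene_id[i], node = graph@nodes[i, , drop = FALSE])
}

# Vectorised node -> gene lookup (internal fast path).
genesOfNodes <- function(graph, node_ids) {
  idx <- vapply(node_ids, function(n) {
    i <- graph@index[[n]]
    if (is.null(i)) stop("unknown node_id '", n, "'") else i
  }, integer(1), USE.NAMES = FALSE)
  graph@nodes$gene_id[idx]
}
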