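#' SpliceFusion: gene fusion detection from long-read RNA-seq via splicing
#' graphs
#'
#' Builds annotation-derived splicing graphs, aligns long reads to them,
#' screens multigene alignment paths into fusion candidates, clusters and
#' error-corrects supporting reads, and dual-validates each event against
#' the protein-coding graph and the genome before assigning a confidence
#' tier. Includes a seeded benchmark simulator and evaluation utilities.
#'
#' @import data.table
#' @import methods
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", ".SD", "N", "kmer", "tx", "tpos", "rpos", "read", "orient",
  "gene_id", "node_id", "off_start", "off_end", "diag", "q_lo", "q_hi",
  "t_lo", "t_hi", "score", "gpos", "chrom", "pos", "base", "center_base",
  "tie_rank", "ins", "qc", "block", "q_span", "nmatch", "alen", "target",
  "pid", "cand", "role", "gene", "i.gene_id", "dgrp", "dn"))
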