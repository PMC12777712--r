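# End-to-end fusion detection pipeline: graph construction, read-to-graph
# alignment, multigene screening with junction filters, clustering +
# consensus, and dual validation with confidence tiering. A manifest records
# the candidate funnel at every stage.

#' Pipeline configuration
#'
#' Validated option bundle for \code{\link{runPipeline}}. Unknown option
#' names are rejected and numeric thresholds must be non-negative.
#'
#' @param align_backend \code{"builtin"} (the package's k-mer seed-and-chain
#'   mapper), \code{"exact"} (exhaustive toy aligner; tiny graphs only) or
#'   \code{"external:<binary>"} for an installed GFA/GAF graph aligner
#' @param realign_backend \code{"builtin"} junction re-alignment or
#'   \code{"external"} (minimap2 against a consolidated fusion reference)
#' @param min_support minimal supporting reads per reported fusion
#' @param min_block_len minimal aligned block length per partner (bp)
#' @param junction_slack maximal gap/overlap between partner segments on the
#'   read (bp)
#' @param min_identity minimal re-alignment / validation identity
#' @param min_cov minimal genome-block query coverage in structural
#'   validation
#' @param cluster_radius coarse clustering Manhattan radius (bp)
#' @param max_members consensus member cap per cluster
#' @param refine_window exon-boundary breakpoint snap window (bp)
#' @param max_fragments maximal alignment records per read before it is
#'   discarded as anomalous
#' @param flank custom-reference flank size (bp)
#' @param artifact_list optional path to a two-column TSV of known artifact
#'   gene pairs
#' @param seed integer seed for any stochastic step
#' @return validated list of class \code{pipeline_config}
#' @export
pipelineConfig <- function(align_backend = "builtin",
                           realign_backend = "builtin",
                           min_support = 3L, min_block_len = 30L,
                           junction_slack = 50L, min_identity = 0.80,
                           min_cov = 0.90, cluster_radius = 100L,
                           max_members = 30L, refine_window = 30L,
                           max_fragments = 4L, flank = 1000L,
                           artifact_list = NULL, seed = 1L) {
  nums <- c(min_support = min_support, min_block_len = min_block_len,
            junction_slack = junction_slack, min_identity = min_identity,
            min_cov = min_cov, cluster_radius = cluster_radius,
            max_members = max_members, refine_window = refine_window,
            max_fragments = max_fragments, flank = flank)
  bad <- names(nums)[!is.finite(nums) | nums < 0]
  if (length(bad))
    stop("pipeline options must be non-negative numbers: ",
         paste(bad, collapse = ", "))
  if (!identical(realign_backend, "builtin") &&
      !identical(realign_backend, "external"))
    stop("realign_backend must be 'builtin' or 'external'")
  if (!identical(align_backend, "builtin") &&
      !identical(align_backend, "exact") &&
      !startsWith(align_backend, "external:"))
    stop("align_backend must be 'builtin', 'exact' or 'external:<binary>'")
  cfg <- list(align_backend = align_backend,
              realign_backend = realign_backend,
              min_support = as.integer(min_support),
              min_block_len = as.integer(min_block_len),
              junction_slack = as.integer(junction_slack),
              min_identity = min_identity, min_cov = min_cov,
              cluster_radius = as.integer(cluster_radius),
              max_members = as.integer(max_members),
              refine_window = as.integer(refine_window),
              max_fragments = as.integer(max_fragments),
              flank = as.integer(flank), artifact_list = artifact_list,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the complete fusion detection pipeline
#'
#' Five stages: (1) build the comprehensive and protein-coding splicing
#' graphs from the annotation, (2) align reads to the comprehensive graph,
#' (3) screen multigene alignments into junction-filtered candidates,
#' (4) cluster candidates and build consensus sequences, (5) dual-validate
#' clusters (component identity against the protein-coding graph, structural
#' consistency against the genome), refine breakpoints to exon boundaries
#' and assign confidence tiers. Intermediate files (GFA graphs, GAF
#' alignments, candidate tables, calls TSV/JSON, JSON manifest) are written
#' under \code{workdir}. Deterministic for fixed inputs and config.
#'
#' @param genome genome FASTA path or DNAStringSet
#' @param gff3 GFF3 annotation path
#' @param reads FASTA/FASTQ path or named character vector of read sequences
#' @param workdir output directory (created)
#' @param config \code{\link{pipelineConfig}}
#' @return list with \code{calls} (data.frame of tiered fusion calls),
#'   \code{manifest} (stage counts), \code{crsg}, \code{prsg} and file paths
#'   \code{calls_tsv}, \code{calls_json}, \code{manifest_json}
#' @export
runPipeline <- function(genome, gff3, reads, workdir = tempfile("sfrun"),
                        config = pipelineConfig()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  checksum <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
      unname(tools::md5sum(x)) else NA_character_
  }
  manifest <- list(
    config = unclass(config),
    versions = list(r = as.character(getRversion()),
                    package = as.character(utils::packageVersion(
                      "SpliceFusion"))),
    input_checksums = list(genome = checksum(genome), gff3 = checksum(gff3),
                           reads = checksum(reads)))
  genome <- stage("input", loadGenome(genome))
  reads <- stage("input", readReads(reads))
  manifest$n_reads <- length(reads)

  # 1. splicing graphs
  message("[1/5] building splicing graphs")
  crsg <- stage("graph_build", {
    genes <- parseAnnotation(gff3, genome)
    buildSpliceGraph(genes, scope = "comprehensive", genome = genome)
  })
  prsg <- stage("graph_build",
                buildSpliceGraph(genes, scope = "protein_coding",
                                 genome = genome))
  writeGFA(crsg, file.path(workdir, "crsg.gfa"))
  writeGFA(prsg, file.path(workdir, "prsg.gfa"))
  manifest$n_genes <- nrow(geneMeta(crsg))
  manifest$n_nodes <- nrow(graphNodes(crsg))
  message("      ", manifest$n_genes, " genes, ", manifest$n_nodes,
          " exon nodes")

  # 2. read-to-graph alignment
  message("[2/5] aligning ", length(reads), " reads to the graph")
  gaf_path <- file.path(workdir, "alignments.gaf")
  gaf <- stage("graph_align", {
    withSeed(config$seed, runGraphAlignment(reads, crsg, out = gaf_path,
                                            backend = config$align_backend))
    parseGaf(gaf_path)
  })
  manifest$n_alignment_records <- nrow(gaf)
  manifest$n_aligned_reads <- length(unique(gaf$read_id))
  message("      ", manifest$n_alignment_records, " records / ",
          manifest$n_aligned_reads, " reads aligned")

  # 3. multigene screening + junction filters
  message("[3/5] screening multigene alignments")
  cand <- stage("candidate_screen", findMultigeneReads(gaf, crsg))
  manifest$n_multigene_candidates <- nrow(cand)
  validated <- stage("candidate_screen", {
    validateJunction(
      cand, reads, crsg, min_block_len = config$min_block_len,
      junction_slack = config$junction_slack,
      min_identity = config$min_identity,
      max_fragments = config$max_fragments,
      backend = config$realign_backend, genome = genome,
      flank = config$flank)
  })
  utils::write.table(
    validated[, setdiff(names(validated), "path_nodes"), drop = FALSE],
    file.path(workdir, "candidates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  passing <- validated[validated$pass, , drop = FALSE]
  manifest$n_filtered_candidates <- nrow(passing)
  manifest$filter_rejections <- as.list(table(
    validated$reject_reason[!validated$pass]))
  message("      ", manifest$n_multigene_candidates, " candidate reads, ",
          manifest$n_filtered_candidates, " pass the junction filters")

  # 4. clustering + consensus
  message("[4/5] clustering candidates")
  clusters <- stage("fusion_cluster",
                    clusterCandidates(passing, reads,
                                      radius = config$cluster_radius,
                                      max_members = config$max_members))
  manifest$n_clusters <- nrow(clusters)
  manifest$n_clustered_reads <- sum(clusters$n_reads)
  manifest$n_supported_clusters <- sum(clusters$n_reads >=
                                         config$min_support)
  message("      ", manifest$n_clusters, " clusters (",
          manifest$n_supported_clusters, " with >= ", config$min_support,
          " reads)")

  # 5. dual validation, refinement, tiering
  message("[5/5] dual validation and confidence tiering")
  calls <- stage("dual_validate", {
    artifact_pairs <- readArtifactList(config$artifact_list)
    dualValidateClusters(
      clusters, prsg = prsg, crsg = crsg, genome = genome,
      min_support = config$min_support,
      refine_window = config$refine_window,
      min_identity = config$min_identity, min_cov = config$min_cov,
      artifact_pairs = artifact_pairs)
  })
  manifest$n_calls <- nrow(calls)
  manifest$tiers <- as.list(table(calls$tier))
  message("      ", manifest$n_calls, " fusion call(s)")

  calls_tsv <- file.path(workdir, "calls.tsv")
  calls_json <- file.path(workdir, "calls.json")
  writeCalls(calls, calls_tsv, calls_json)
  manifest_json <- file.path(workdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_json, auto_unbox = TRUE,
                       pretty = TRUE)
  list(calls = calls, manifest = manifest, crsg = crsg, prsg = prsg,
       calls_tsv = calls_tsv, calls_json = calls_json,
       manifest_json = manifest_json)
}
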