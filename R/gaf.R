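#' Parse a GAF (graph alignment format) file
#'
#' Reads the 12 mandatory tab-separated GAF columns plus the optional
#' \code{cg:Z} CIGAR tag. Records with fewer than 12 columns are skipped with
#' a warning, as are unaligned records whose path is \code{"*"}.
#'
#' @param path GAF file path
#' @return data.frame with one row per alignment record: \code{read_id},
#'   \code{read_len}, \code{query_start}, \code{query_end}, \code{strand},
#'   \code{path} (signed node string such as \code{">g1:...<g2:..."}),
#'   \code{path_len}, \code{path_start}, \code{path_end}, \code{matches},
#'   \code{block_len}, \code{mapq}, \code{cigar} (NA when absent)
#' @seealso \code{\link{gafPath}} to split a path string into signed nodes
#' @export
parseGaf <- function(path) {
  lines <- if (is.character(path) && length(path) == 1L && file.exists(path))
    readLines(path) else as.character(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(
    read_id = character(), read_len = integer(), query_start = integer(),
    query_end = integer(), strand = character(), path = character(),
    path_len = integer(), path_start = integer(), path_end = integer(),
    matches = integer(), block_len = integer(), mapq = integer(),
    cigar = character(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    warning(sum(nf < 12L), " GAF record(s) with <12 columns skipped")
    fields <- fields[nf >= 12L]
  }
  if (!length(fields)) return(empty)
  col <- function(i) vapply(fields, `[[`, "", i)
  cg <- vapply(fields, function(f) {
    hit <- grep("^cg:Z:", f, value = TRUE)
    if (length(hit)) sub("^cg:Z:", "", hit[1L]) else NA_character_
  }, character(1))
  out <- data.frame(
    read_id = col(1L), read_len = as.integer(col(2L)),
    query_start = as.integer(col(3L)), query_end = as.integer(col(4L)),
    strand = col(5L), path = col(6L), path_len = as.integer(col(7L)),
    path_start = as.integer(col(8L)), path_end = as.integer(col(9L)),
    matches = as.integer(col(10L)), block_len = as.integer(col(11L)),
    mapq = as.integer(col(12L)), cigar = cg, stringsAsFactors = FALSE)
  star <- out$path == "*"
  if (any(star)) out <- out[!star, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a GAF path string into signed nodes
#' @param path a single path string, e.g. \code{">A>B<C"}
#' @return data.frame with columns \code{node} and \code{orient}
#'   (\code{">"} forward traversal, \code{"<"} reverse)
#' @export
gafPath <- function(path) {
  toks <- regmatches(path, gregexpr("[><][^><]+", path))[[1L]]
  data.frame(node = substring(toks, 2L),
             orient = substring(toks, 1L, 1L), stringsAsFactors = FALSE)
}

# Inverse of gafPath.
pathString <- function(nodes, orients) paste0(orients, nodes, collapse = "")

#' Write alignment records as GAF
#' @param gaf data.frame in the layout returned by \code{\link{parseGaf}}
#' @param path output file
#' @return the path, invisibly
#' @export
writeGaf <- function(gaf, path) {
  if (!nrow(gaf)) {
    file.create(path)
    return(invisible(path))
  }
  base <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                  gaf$read_id, gaf$read_len, gaf$query_start, gaf$query_end,
                  gaf$strand, gaf$path, gaf$path_len, gaf$path_start,
                  gaf$path_end, gaf$matches, gaf$block_len, gaf$mapq)
  has_cg <- !is.na(gaf$cigar)
  base[has_cg] <- paste0(base[has_cg], "\tcg:Z:", gaf$cigar[has_cg])
  writeLines(base, path)
  invisible(path)
}
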