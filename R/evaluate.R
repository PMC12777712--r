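# Benchmark evaluation: gene-pair and breakpoint-level precision/recall/F1
# against a simulated truth set, plus breakpoint-shift statistics.

.f1 <- function(p, r) {
  if (is.na(p) || is.na(r) || (p + r) == 0) 0 else 2 * p * r / (p + r)
}

# Unordered gene-pair key (role-insensitive match at the gene-pair level).
.unorderedKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Evaluate fusion calls against a simulated truth set
#'
#' Computes detection metrics at two levels. Gene-pair level: a unique
#' unordered gene pair counts as a true positive when it appears in the truth
#' set, regardless of breakpoint coordinates. Breakpoint level: a unique
#' predicted event (gene pair plus breakpoint pair) is a true positive when a
#' truth record with the same gene pair has both breakpoints within the
#' window -- \code{strict} uses +/-1 bp, \code{fuzzy} +/-5 bp; role mapping is
#' orientation-aware (if the predicted 5'/3' roles are swapped relative to
#' truth, breakpoints are compared swapped). Recall counts truth records
#' matched by at least one prediction. Breakpoint shifts (absolute distance
#' from the nearest role-mapped truth breakpoint, per partner) are returned
#' for all gene-pair-matched predictions.
#'
#' @param calls data.frame of fusion calls with columns \code{gene5},
#'   \code{gene3}, \code{bp5}, \code{bp3} (e.g. from
#'   \code{\link{dualValidateClusters}}; filter confidence tiers first if
#'   desired)
#' @param truth data.frame with \code{gene5}, \code{gene3}, \code{bp5},
#'   \code{bp3} (as from \code{\link{makeFusions}})
#' @param strict_window strict breakpoint tolerance in bp (default 1)
#' @param fuzzy_window fuzzy breakpoint tolerance in bp (default 5)
#' @return list with elements \code{gene_pair}, \code{strict}, \code{fuzzy}
#'   (each a list \code{precision}, \code{recall}, \code{f1}, \code{tp},
#'   \code{fp}, \code{fn}) and \code{shifts}, an integer vector of per-partner
#'   breakpoint shifts for gene-pair-matched predictions
#' @export
evaluateCalls <- function(calls, truth, strict_window = 1L,
                          fuzzy_window = 5L) {
  if (is.null(truth) || !nrow(truth))
    stop("empty truth set: nothing to evaluate against")
  need <- c("gene5", "gene3", "bp5", "bp3")
  stopifnot(all(need %in% names(truth)))
  if (is.null(calls)) calls <- data.frame()
  if (!nrow(calls)) {
    calls <- data.frame(gene5 = character(), gene3 = character(),
                        bp5 = integer(), bp3 = integer(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(need %in% names(calls)))

  # --- gene-pair level ---
  predPairs <- unique(.unorderedKey(calls$gene5, calls$gene3))
  truthPairs <- unique(.unorderedKey(truth$gene5, truth$gene3))
  tp <- length(intersect(predPairs, truthPairs))
  gp <- list(precision = if (length(predPairs)) tp / length(predPairs)
                         else NA_real_,
             recall = tp / length(truthPairs),
             tp = tp, fp = length(predPairs) - tp,
             fn = length(truthPairs) - tp)
  gp$f1 <- .f1(gp$precision, gp$recall)

  # --- breakpoint level ---
  uq <- unique(calls[, need, drop = FALSE])
  bpLevel <- function(w) {
    if (!nrow(uq)) {
      return(list(precision = NA_real_, recall = 0, f1 = 0, tp = 0L,
                  fp = 0L, fn = nrow(truth)))
    }
    hitTruth <- rep(FALSE, nrow(truth))
    hitPred <- rep(FALSE, nrow(uq))
    for (i in seq_len(nrow(uq))) {
      for (j in seq_len(nrow(truth))) {
        sameOrder <- uq$gene5[i] == truth$gene5[j] &&
          uq$gene3[i] == truth$gene3[j]
        swapped <- uq$gene5[i] == truth$gene3[j] &&
          uq$gene3[i] == truth$gene5[j]
        if (!sameOrder && !swapped) next
        d5 <- abs(uq$bp5[i] - if (sameOrder) truth$bp5[j] else truth$bp3[j])
        d3 <- abs(uq$bp3[i] - if (sameOrder) truth$bp3[j] else truth$bp5[j])
        if (d5 <= w && d3 <= w) {
          hitPred[i] <- TRUE
          hitTruth[j] <- TRUE
        }
      }
    }
    res <- list(precision = sum(hitPred) / nrow(uq),
                recall = sum(hitTruth) / nrow(truth),
                tp = sum(hitPred), fp = sum(!hitPred),
                fn = sum(!hitTruth))
    res$f1 <- .f1(res$precision, res$recall)
    res
  }

  # --- shifts for gene-pair-matched predictions ---
  shifts <- integer()
  for (i in seq_len(nrow(uq))) {
    best <- NULL
    for (j in seq_len(nrow(truth))) {
      sameOrder <- uq$gene5[i] == truth$gene5[j] &&
        uq$gene3[i] == truth$gene3[j]
      swapped <- uq$gene5[i] == truth$gene3[j] &&
        uq$gene3[i] == truth$gene5[j]
      if (!sameOrder && !swapped) next
      d5 <- abs(uq$bp5[i] - if (sameOrder) truth$bp5[j] else truth$bp3[j])
      d3 <- abs(uq$bp3[i] - if (sameOrder) truth$bp3[j] else truth$bp5[j])
      if (is.null(best) || (d5 + d3) < sum(best)) best <- c(d5, d3)
    }
    if (!is.null(best)) shifts <- c(shifts, best)
  }

  list(gene_pair = gp, strict = bpLevel(strict_window),
       fuzzy = bpLevel(fuzzy_window), shifts = as.integer(shifts))
}
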