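#' Associate cluster representatives with gene probe sets by position
#'
#' Stage (ii) of the protocol. An association is emitted for every
#' (representative, probe set) pair on the same chromosome whose anchor
#' position lies within the probe set's base range extended by
#' \code{window} base pairs on each side, i.e. in
#' \code{[start - window, end + window]} inclusive. A representative may
#' match several probe sets and a probe set several representatives; the
#' window is symmetric and strand is ignored. Overlap is computed with
#' IRanges; the result equals the brute-force all-pairs interval check.
#'
#' @param reduction a \code{methylation_reduction}.
#' @param expr an \code{expression_set} (on either scale).
#' @param window flanking window in base pairs (default 20000); 0 reduces
#'   to pure containment in the probe-set range.
#' @return Data frame with one row per association: \code{assoc_id},
#'   \code{representative_id}, \code{region_id}, \code{cluster},
#'   \code{chromosome}, \code{anchor_pos}, \code{probeset_id}, \code{gene},
#'   and \code{distance} (base pairs from anchor to the probe-set range;
#'   0 when inside). Sorted by \code{assoc_id}.
#' @export
associate_clusters <- function(reduction, expr, window = 20000) {
  stopifnot(inherits(reduction, "methylation_reduction"),
            inherits(expr, "expression_set"))
  if (window < 0) stop("window must be nonnegative")
  cl <- reduction$clusters
  ps <- expr$probesets
  empty <- data.frame(assoc_id = character(),
                      representative_id = character(),
                      region_id = character(), cluster = integer(),
                      chromosome = character(), anchor_pos = numeric(),
                      probeset_id = character(), gene = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(cl) == 0L || nrow(ps) == 0L) {
    warning("no methylation-expression associations found")
    return(empty)
  }
  pieces <- list()
  for (chr in intersect(unique(cl$chromosome), unique(ps$chromosome))) {
    ci <- which(cl$chromosome == chr)
    pi <- which(ps$chromosome == chr)
    anchors <- IRanges::IRanges(start = cl$anchor_pos[ci], width = 1L)
    targets <- IRanges::IRanges(start = pmax(1, ps$start[pi] - window),
                                end = ps$end[pi] + window)
    hits <- IRanges::findOverlaps(anchors, targets)
    if (length(hits) == 0L) next
    i <- ci[S4Vectors::queryHits(hits)]
    j <- pi[S4Vectors::subjectHits(hits)]
    dist <- pmax(0, pmax(ps$start[j] - cl$anchor_pos[i],
                         cl$anchor_pos[i] - ps$end[j]))
    pieces[[chr]] <- data.frame(
      assoc_id = paste(cl$representative_id[i], ps$probeset_id[j],
                       sep = "|"),
      representative_id = cl$representative_id[i],
      region_id = cl$region_id[i], cluster = cl$cluster[i],
      chromosome = chr, anchor_pos = cl$anchor_pos[i],
      probeset_id = ps$probeset_id[j], gene = ps$gene[j],
      distance = dist, stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0L) {
    warning("no methylation-expression associations found")
    return(empty)
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$assoc_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
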