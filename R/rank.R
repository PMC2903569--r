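#' Score every association by sigmoid fit and permutation test
#'
#' Stage (iii), first half. For each association the cluster's
#' representative methylation profile is regressed against the probe set's
#' normalized expression profile (\code{\link{fit_curve}}) and a
#' permutation p-value is attached (\code{\link{permutation_pvalue}}).
#' Per-association permutation seeds are derived from the global seed by a
#' stable hash of the association id, so the result does not depend on
#' evaluation order. Associations with fewer than 4 complete pairs or a
#' failed fit are skipped; their ids and reasons are kept in the
#' \code{"skipped"} attribute.
#'
#' @param associations output of \code{\link{associate_clusters}}.
#' @param reduction the \code{methylation_reduction} the associations came
#'   from.
#' @param expr the normalized \code{expression_set}.
#' @param m_perm permutations per association (default 10000).
#' @param seed global integer seed.
#' @return The association data frame with columns \code{n_used},
#'   \code{a}, \code{b}, \code{c}, \code{SSR}, \code{SSE}, \code{R},
#'   \code{p_value} appended.
#' @export
score_associations <- function(associations, reduction, expr,
                               m_perm = 10000, seed = 1) {
  stopifnot(inherits(reduction, "methylation_reduction"),
            inherits(expr, "expression_set"))
  if (!expr$normalized)
    stop("expression must be normalized before scoring ",
         "(see normalize_expression)")
  n <- nrow(associations)
  num <- rep(NA_real_, n)
  out <- cbind(associations,
               data.frame(n_used = NA_integer_, a = num, b = num, c = num,
                          SSR = num, SSE = num, R = num, p_value = num))
  skipped <- list()
  for (i in seq_len(n)) {
    M <- reduction$representatives[associations$representative_id[i], ]
    E <- expr$profiles[associations$probeset_id[i], ]
    fit <- fit_curve(M, E)
    if (!fit$converged) {
      skipped[[associations$assoc_id[i]]] <- fit$reason
      next
    }
    pv <- permutation_pvalue(M, E, r_obs = fit$R, m_perm = m_perm,
                             seed = derive_seed(seed,
                                                associations$assoc_id[i]))
    out$n_used[i] <- fit$n_used
    out$a[i] <- fit$a; out$b[i] <- fit$b; out$c[i] <- fit$c
    out$SSR[i] <- fit$SSR; out$SSE[i] <- fit$SSE; out$R[i] <- fit$R
    out$p_value[i] <- pv$p_value
  }
  keep <- !is.na(out$R)
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Best association per gene
#'
#' For each gene keeps the association with the largest R (ties broken by
#' smaller p-value, then lexicographic association id), without any
#' significance filter. A Benjamini-Hochberg adjusted p-value over the
#' per-gene best p-values is appended as a supplementary \code{q_value}
#' column.
#'
#' @param scored output of \code{\link{score_associations}}.
#' @return Data frame with one row per gene, sorted by descending R.
#' @export
best_gene_associations <- function(scored) {
  if (nrow(scored) == 0L) return(cbind(scored, q_value = numeric(0)))
  ord <- order(scored$gene, -scored$R, scored$p_value, scored$assoc_id)
  s <- scored[ord, , drop = FALSE]
  best <- s[!duplicated(s$gene), , drop = FALSE]
  best$q_value <- stats::p.adjust(best$p_value, method = "BH")
  best <- best[order(-best$R, best$p_value, best$assoc_id), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Rank candidate epigenetically regulated genes
#'
#' Stage (iii), second half. Each gene is represented by its best-R
#' association (\code{\link{best_gene_associations}}); genes whose best
#' association has a raw permutation p-value below \code{alpha} are
#' retained and sorted by descending R. No multiple-testing correction is
#' applied to the filter; the supplementary BH \code{q_value} column is
#' carried through for the user's own use.
#'
#' @param scored output of \code{\link{score_associations}}.
#' @param alpha raw p-value threshold (default 0.05).
#' @return Data frame of ranked genes (one row per retained gene), sorted
#'   by descending R.
#' @export
rank_genes <- function(scored, alpha = 0.05) {
  best <- best_gene_associations(scored)
  out <- best[!is.na(best$p_value) & best$p_value < alpha, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no gene passes the p < ", alpha, " filter")
  rownames(out) <- NULL
  out
}
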