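#' Two-step dimensionality reduction of a methylation panel
#'
#' Stage (i) of the protocol. Sites are first grouped into regions by
#' genomic proximity (\code{\link{group_by_proximity}}); profiles are then
#' compressed once, globally, by PCA at the requested explained-variance
#' target (\code{\link{fit_pca}}); finally each region's sites are
#' clustered in component space by K-spectral clustering with automatic
#' (sigma, k) selection (\code{\link{select_parameters}}). Regions with
#' fewer than \code{min_region_size} sites bypass clustering as a single
#' cluster. Each cluster's representative profile is the per-cell-line mean
#' of its member sites' original methylation percentages, and its anchor is
#' the member site whose position is closest to the positional centroid of
#' the cluster (ties to the smaller position).
#'
#' @param meth a \code{methylation_set}.
#' @param gap proximity-merging distance in base pairs (default 2000).
#' @param variance_target PCA cumulative explained-variance target
#'   (default 0.99).
#' @param sigma_grid optional fixed bandwidth grid; \code{NULL} derives a
#'   per-region grid from the region's median pairwise distance.
#' @param k_max largest cluster count scanned per region (default 8).
#' @param min_region_size smallest region that undergoes clustering
#'   (default 3); smaller regions become single-cluster models.
#' @param seed integer seed; per-region sub-seeds are derived from it.
#' @param nstart k-means restarts per grid pair.
#' @return An object of class \code{methylation_reduction}: \code{$regions}
#'   (from \code{group_by_proximity}), \code{$pca}, \code{$clusters} (one
#'   row per cluster: \code{representative_id}, \code{region_id},
#'   \code{cluster}, \code{chromosome}, \code{anchor_site},
#'   \code{anchor_pos}, \code{n_sites}, \code{sigma}, \code{k},
#'   \code{compactness}), \code{$representatives} (cluster x cell-line
#'   matrix of mean percentages), and \code{$assignments} (one row per
#'   site: \code{site_id}, \code{region_id}, \code{cluster},
#'   \code{representative_id}).
#' @export
reduce_methylation <- function(meth, gap = 2000, variance_target = 0.99,
                               sigma_grid = NULL, k_max = 8,
                               min_region_size = 3, seed = 1, nstart = 10) {
  stopifnot(inherits(meth, "methylation_set"))
  regions <- group_by_proximity(meth, gap)
  prof <- meth$profiles
  prof_complete <- prof
  if (anyNA(prof_complete)) {
    # PCA cannot carry missing entries; impute each site's missing lines
    # with the site mean (representatives still average observed values)
    for (i in which(rowSums(is.na(prof_complete)) > 0)) {
      v <- prof_complete[i, ]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      prof_complete[i, ] <- v
    }
  }
  if (nrow(prof_complete) >= 2 && ncol(prof_complete) >= 2) {
    pca <- fit_pca(prof_complete, variance_target)
    scores <- pca$scores
  } else {
    pca <- NULL
    scores <- prof_complete
  }
  rownames(scores) <- meth$sites$site_id
  pos <- stats::setNames(meth$sites$position, meth$sites$site_id)
  chrom <- stats::setNames(meth$sites$chromosome, meth$sites$site_id)

  clus_rows <- vector("list", nrow(regions))
  assign_rows <- vector("list", nrow(regions))
  rep_rows <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    members <- regions$member_sites[[r]]
    n <- length(members)
    rid <- regions$region_id[r]
    if (n < min_region_size) {
      sel <- list(sigma = NA_real_, k = 1L, cluster = rep(1L, n),
                  compactness = NA_real_, fallback = FALSE)
    } else {
      sel <- select_parameters(scores[members, , drop = FALSE],
                               sigma_grid = sigma_grid,
                               k_grid = seq(2, min(k_max, n - 1)),
                               seed = derive_seed(seed, rid),
                               nstart = nstart)
    }
    ks <- sort(unique(sel$cluster))
    reps <- matrix(NA_real_, length(ks), ncol(prof),
                   dimnames = list(NULL, colnames(prof)))
    anchors <- character(length(ks))
    for (j in seq_along(ks)) {
      mem <- members[sel$cluster == ks[j]]
      reps[j, ] <- colMeans(prof[mem, , drop = FALSE], na.rm = TRUE)
      centroid <- mean(pos[mem])
      anchors[j] <- mem[order(abs(pos[mem] - centroid), pos[mem])][1]
    }
    rep_ids <- sprintf("%s_c%02d", rid, seq_along(ks))
    clus_rows[[r]] <- data.frame(
      representative_id = rep_ids, region_id = rid,
      cluster = seq_along(ks), chromosome = regions$chromosome[r],
      anchor_site = anchors, anchor_pos = unname(pos[anchors]),
      n_sites = as.integer(table(factor(sel$cluster, levels = ks))),
      sigma = sel$sigma, k = length(ks),
      compactness = sel$compactness, stringsAsFactors = FALSE)
    assign_rows[[r]] <- data.frame(
      site_id = members, region_id = rid,
      cluster = match(sel$cluster, ks),
      representative_id = rep_ids[match(sel$cluster, ks)],
      stringsAsFactors = FALSE)
    rep_rows[[r]] <- reps
  }
  clusters <- do.call(rbind, clus_rows)
  representatives <- do.call(rbind, rep_rows)
  rownames(representatives) <- clusters$representative_id
  out <- structure(list(regions = regions, pca = pca, clusters = clusters,
                        representatives = representatives,
                        assignments = do.call(rbind, assign_rows),
                        panel = meth$panel,
                        params = list(gap = gap,
                                      variance_target = variance_target,
                                      k_max = k_max,
                                      min_region_size = min_region_size,
                                      seed = seed)),
                   class = "methylation_reduction")
  out
}

#' @export
print.methylation_reduction <- function(x, ...) {
  n_sites <- nrow(x$assignments)
  n_clusters <- nrow(x$clusters)
  cat("methylation_reduction:\n")
  cat("  sites:   ", n_sites, "\n")
  cat("  regions: ", nrow(x$regions), "\n")
  cat("  clusters:", n_clusters,
      sprintf("(compression %.1f%%)", 100 * (1 - n_clusters / n_sites)), "\n")
  cat("  PCA components kept:",
      if (is.null(x$pca)) NA else x$pca$n_kept, "\n")
  invisible(x)
}
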