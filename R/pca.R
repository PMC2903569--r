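#' Compress methylation profiles by principal components
#'
#' Methylation profiles across a cell-line panel are strongly correlated
#' between lines, so before similarity clustering the site-by-line matrix is
#' projected onto the smallest number of principal components whose
#' cumulative explained variance reaches \code{variance_target}. The PCA is
#' fitted once on the full matrix (mean-centred per cell line), not per
#' region, so every region is clustered in a common component space.
#'
#' @param x numeric matrix, sites in rows, cell lines in columns; no
#'   missing values (impute or drop upstream).
#' @param variance_target cumulative explained-variance fraction to retain
#'   (default 0.99).
#' @return An object of class \code{meth_pca}: \code{$n_kept},
#'   \code{$variance_fraction}, \code{$rotation} (orthonormal loadings),
#'   \code{$center}, and \code{$scores} (sites x \code{n_kept}).
#' @export
fit_pca <- function(x, variance_target = 0.99) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("PCA needs at least 2 sites and 2 cell lines")
  if (anyNA(x))
    stop("PCA input contains missing values")
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must be in (0, 1]")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  total <- sum(ev)
  if (total <= 0) stop("methylation matrix has zero variance (rank 0)")
  cumfrac <- cumsum(ev) / total
  # 1e-12 slack so variance_target = 1 returns the numerical rank rather
  # than dragging in components that exist only as rounding error
  n_kept <- which(cumfrac >= variance_target - 1e-12)[1]
  structure(list(n_kept = n_kept,
                 variance_fraction = cumfrac[n_kept],
                 rotation = pr$rotation[, seq_len(n_kept), drop = FALSE],
                 center = pr$center,
                 scores = pr$x[, seq_len(n_kept), drop = FALSE]),
            class = "meth_pca")
}

#' @export
print.meth_pca <- function(x, ...) {
  cat("meth_pca:", x$n_kept, "components,",
      sprintf("%.2f%%", 100 * x$variance_fraction),
      "of variance\n")
  invisible(x)
}
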