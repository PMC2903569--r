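#' @name ksc
#' @title K-spectral clustering with compactness-based model selection
#'
#' @description
#' Methylation profiles within a genomic region are clustered by spectral
#' clustering: a Gaussian affinity matrix with zero diagonal, the
#' symmetrically normalized Laplacian \eqn{L = D^{-1/2} A D^{-1/2}}, the
#' eigenvectors of its k largest eigenvalues row-normalized to the unit
#' sphere, and k-means on the embedded rows. The affinity bandwidth
#' \eqn{\sigma} and cluster count k are selected automatically by
#' exhaustively scoring a grid of pairs with the compactness ratio W/B
#' (worst within-cluster point-to-centre distance over best between-centre
#' distance) and keeping the minimizer.
NULL

#' Gaussian affinity matrix
#'
#' \eqn{A_{ij} = \exp(-\|s_i - s_j\|^2 / 2\sigma^2)} for \eqn{i \neq j},
#' with \eqn{A_{ii} = 0}.
#'
#' @param points numeric matrix, observations in rows.
#' @param sigma bandwidth, must be positive.
#' @return Symmetric n x n matrix with zero diagonal and entries in (0, 1].
#' @export
affinity_matrix <- function(points, sigma) {
  points <- as.matrix(points)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a single positive number")
  if (nrow(points) < 2) stop("need at least 2 points")
  d2 <- as.matrix(stats::dist(points))^2
  A <- exp(-d2 / (2 * sigma^2))
  diag(A) <- 0
  dimnames(A) <- NULL
  A
}

#' Symmetrically normalized Laplacian
#'
#' \eqn{L = D^{-1/2} A D^{-1/2}} where \eqn{D_{ii}} is the i-th row sum of
#' A. Eigenvalues of L lie in \eqn{[-1, 1]}.
#'
#' @param A symmetric nonnegative affinity matrix with no all-zero row.
#' @return The normalized matrix L.
#' @export
normalized_laplacian <- function(A) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("affinity matrix must be nonnegative")
  if (max(abs(A - t(A))) > 1e-8) stop("affinity matrix must be symmetric")
  rs <- rowSums(A)
  zero <- which(rs == 0)
  if (length(zero))
    stop("point(s) ", paste(zero, collapse = ", "),
         " are isolated (zero affinity row sum); sigma too small")
  inv_sqrt <- 1 / sqrt(rs)
  A * (inv_sqrt %o% inv_sqrt)
}

#' Spectral embedding
#'
#' Takes the eigenvectors of the k algebraically largest eigenvalues of L
#' as columns of X, then scales each row of X to unit Euclidean norm.
#' Eigenvector sign is fixed deterministically (largest-magnitude entry
#' positive). Rows of exactly zero norm are left zero with a warning.
#'
#' @param L normalized Laplacian.
#' @param k number of embedding dimensions, \code{2 <= k <= n}.
#' @return n x k matrix Y with unit-norm (or zero) rows.
#' @export
spectral_embed <- function(L, k) {
  L <- as.matrix(L)
  n <- nrow(L)
  if (k < 2 || k > n) stop("k must be between 2 and n")
  ee <- eigen(L, symmetric = TRUE)
  X <- ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(X[, j]))
    if (X[i, j] < 0) X[, j] <- -X[, j]
  }
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm < 1e-300
  if (any(zero)) {
    warning(sum(zero), " embedding row(s) have zero norm; left at zero")
    nrm[zero] <- 1
  }
  X / nrm
}

# k-means with a fixed number of restarts under a local seed; the best
# total within-cluster sum of squares wins, ties broken by the earliest
# restart (strict improvement required).
kmeans_restarts <- function(Y, k, seed, nstart = 10) {
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      km <- tryCatch(
        suppressWarnings(stats::kmeans(Y, centers = k, iter.max = 100)),
        error = function(e) NULL)
      if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
        best <- km
    }
    if (is.null(best))
      stop("k-means failed for all restarts (k = ", k,
           ", likely fewer than k distinct points)")
    best
  })
}

#' Cluster profiles by K-spectral clustering
#'
#' Runs the full chain affinity -> normalized Laplacian -> spectral
#' embedding -> k-means, and carries the k-means assignment of each
#' embedded row back to the corresponding input profile.
#'
#' @param points numeric matrix of profiles (rows) in component space.
#' @param sigma affinity bandwidth.
#' @param k number of clusters.
#' @param seed integer seed fixing the k-means initializations.
#' @param nstart number of k-means restarts (default 10).
#' @return A list with \code{cluster} (integer assignments), \code{centers}
#'   (k-means centres in embedding space), and \code{Y} (the embedding).
#' @export
ksc_cluster <- function(points, sigma, k, seed = 1, nstart = 10) {
  points <- as.matrix(points)
  if (k == nrow(points)) {
    # degenerate limit: every point its own cluster
    Y <- spectral_embed(normalized_laplacian(affinity_matrix(points, sigma)),
                        min(k, nrow(points)))
    return(list(cluster = seq_len(nrow(points)), centers = Y, Y = Y))
  }
  A <- affinity_matrix(points, sigma)
  L <- normalized_laplacian(A)
  Y <- spectral_embed(L, k)
  km <- kmeans_restarts(Y, k, seed, nstart)
  list(cluster = km$cluster, centers = km$centers, Y = Y)
}

#' Cluster compactness (W/B)
#'
#' W is the maximum distance between a point and the centre of its cluster;
#' B is the minimum distance between two cluster centres. Smaller W/B means
#' tighter, better-separated clusters. Coincident centres (B = 0) return
#' \code{Inf} so the parameter pair is rejected during model selection.
#'
#' @param points numeric matrix of the clustered points.
#' @param assignments integer cluster index per point.
#' @param centers matrix of cluster centres (one row per cluster, indexed
#'   by the values in \code{assignments}).
#' @return Nonnegative score W/B, or \code{Inf} when centres coincide.
#' @export
compactness <- function(points, assignments, centers) {
  points <- as.matrix(points)
  centers <- as.matrix(centers)
  if (nrow(centers) < 2)
    stop("compactness is undefined for fewer than 2 clusters")
  if (length(assignments) != nrow(points))
    stop("one assignment per point required")
  W <- max(sqrt(rowSums((points - centers[assignments, , drop = FALSE])^2)))
  B <- min(stats::dist(centers))
  if (B == 0) return(Inf)
  W / B
}

#' Default bandwidth grid for a point set
#'
#' Eight log-spaced values between 0.1x and 10x the median pairwise
#' distance. Returns \code{NULL} when all points coincide (no positive
#' distance exists).
#'
#' @param points numeric matrix of profiles in component space.
#' @param n_sigma number of grid values (default 8).
#' @param lo,hi multipliers of the median pairwise distance bounding the
#'   grid (defaults 0.1 and 10).
#' @return Numeric vector of bandwidths, or \code{NULL}.
#' @export
default_sigma_grid <- function(points, n_sigma = 8, lo = 0.1, hi = 10) {
  d <- stats::dist(as.matrix(points))
  dpos <- d[d > 0]
  if (length(dpos) == 0) return(NULL)
  dmed <- stats::median(dpos)
  exp(seq(log(lo * dmed), log(hi * dmed), length.out = n_sigma))
}

#' Select sigma and k by minimum compactness
#'
#' Every (sigma, k) pair on the grid is clustered and scored with
#' \code{\link{compactness}} computed in the embedding space (rows of Y
#' against the k-means centres); the pair with the smallest finite score is
#' returned. Pairs whose clustering fails (isolated points at tiny sigma,
#' fewer distinct embedded points than k, coincident centres) are rejected.
#' If every pair is rejected, a single-cluster fallback model is returned
#' with a warning.
#'
#' Scores below \code{zero_tol} are treated as exact ties: they arise only
#' from duplicated profiles (W numerically zero), where the eigengap
#' degenerates and coarser k can spuriously score as well as the true
#' cluster count. Such ties are resolved toward the finest perfect
#' partition (largest k, then the earliest grid pair); ordinary noisy data
#' never produces them.
#'
#' @param points numeric matrix of profiles in component space.
#' @param sigma_grid bandwidths to scan; \code{NULL} uses
#'   \code{\link{default_sigma_grid}}.
#' @param k_grid cluster counts to scan; \code{NULL} uses
#'   \code{2:min(8, n - 1)}.
#' @param seed integer seed; the same seed is applied to every pair so the
#'   selection is deterministic and independent of grid order.
#' @param nstart k-means restarts per pair.
#' @return A list: \code{sigma}, \code{k}, \code{cluster} (assignments),
#'   \code{centers}, \code{Y}, \code{compactness}, \code{fallback}
#'   (logical), and \code{grid} (data frame of all scored pairs).
#' @export
select_parameters <- function(points, sigma_grid = NULL, k_grid = NULL,
                              seed = 1, nstart = 10, zero_tol = 1e-9) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(sigma_grid)) sigma_grid <- default_sigma_grid(points)
  if (is.null(k_grid)) k_grid <- seq(2, min(8, n - 1))
  k_grid <- k_grid[k_grid >= 2 & k_grid <= n]

  fallback <- function(msg) {
    warning("select_parameters: ", msg, "; falling back to a single cluster")
    list(sigma = NA_real_, k = 1L, cluster = rep(1L, n),
         centers = matrix(colMeans(points), 1), Y = NULL,
         compactness = NA_real_, fallback = TRUE,
         grid = data.frame(sigma = numeric(), k = integer(),
                           score = numeric()))
  }
  if (is.null(sigma_grid) || length(sigma_grid) == 0 || length(k_grid) == 0)
    return(fallback("empty parameter grid (degenerate region)"))

  grid <- expand.grid(k = as.integer(k_grid), sigma = sigma_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("sigma", "k")]
  scores <- rep(Inf, nrow(grid))
  best <- NULL
  row <- 0L
  for (s in sigma_grid) {
    # eigen-decompose once per sigma; k just slices leading eigenvectors
    ee <- tryCatch({
      L <- normalized_laplacian(affinity_matrix(points, s))
      eigen(L, symmetric = TRUE)
    }, error = function(e) NULL)
    for (k in k_grid) {
      row <- row + 1L
      if (is.null(ee)) next
      fit <- tryCatch({
        X <- ee$vectors[, seq_len(k), drop = FALSE]
        for (j in seq_len(k)) {
          i <- which.max(abs(X[, j]))
          if (X[i, j] < 0) X[, j] <- -X[, j]
        }
        nrm <- sqrt(rowSums(X^2))
        nrm[nrm < 1e-300] <- 1
        Y <- X / nrm
        km <- kmeans_restarts(Y, k, seed, nstart)
        list(score = compactness(Y, km$cluster, km$centers),
             cluster = km$cluster, centers = km$centers, Y = Y)
      }, error = function(e) NULL)
      if (is.null(fit)) next
      scores[row] <- fit$score
      if (!is.finite(fit$score)) next
      replace <- if (is.null(best)) TRUE
        else if (fit$score < zero_tol && best$score < zero_tol) k > best$k
        else if (fit$score < zero_tol) TRUE
        else if (best$score < zero_tol) FALSE
        else fit$score < best$score
      if (replace) best <- c(fit, list(sigma = s, k = as.integer(k)))
    }
  }
  grid$score <- scores
  if (is.null(best))
    return(fallback("no (sigma, k) pair produced a valid clustering"))
  list(sigma = best$sigma, k = best$k, cluster = best$cluster,
       centers = best$centers, Y = best$Y, compactness = best$score,
       fallback = FALSE, grid = grid)
}
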