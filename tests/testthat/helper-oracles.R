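# Independent brute-force oracles the vectorized/packaged implementations
# are checked against. Deliberately naive: double loops and linear scans.

affinity_bf <- function(points, sigma) {
  n <- nrow(points)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j)
      A[i, j] <- exp(-sum((points[i, ] - points[j, ])^2) / (2 * sigma^2))
  }
  A
}

laplacian_bf <- function(A) {
  n <- nrow(A)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- sum(A[i, ])
  L <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    L[i, j] <- A[i, j] / sqrt(d[i] * d[j])
  L
}

compactness_bf <- function(points, assignments, centers) {
  W <- 0
  for (i in seq_len(nrow(points))) {
    d <- sqrt(sum((points[i, ] - centers[assignments[i], ])^2))
    if (d > W) W <- d
  }
  B <- Inf
  for (i in seq_len(nrow(centers) - 1)) for (j in (i + 1):nrow(centers)) {
    d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
    if (d < B) B <- d
  }
  if (B == 0) Inf else W / B
}

# single-pass scan: number of proximity regions per chromosome
region_count_bf <- function(chromosome, position, gap) {
  ord <- order(chromosome, position)
  chromosome <- chromosome[ord]; position <- position[ord]
  n <- length(position)
  if (n == 0) return(0L)
  count <- 1L
  for (i in 2:n) {
    if (chromosome[i] != chromosome[i - 1] ||
        position[i] - position[i - 1] > gap)
      count <- count + 1L
  }
  count
}

# quadratic all-pairs interval check for the association window
associate_bf <- function(clusters, probesets, window) {
  out <- character(0)
  for (i in seq_len(nrow(clusters))) for (j in seq_len(nrow(probesets))) {
    if (clusters$chromosome[i] == probesets$chromosome[j] &&
        clusters$anchor_pos[i] >= probesets$start[j] - window &&
        clusters$anchor_pos[i] <= probesets$end[j] + window)
      out <- c(out, paste(clusters$representative_id[i],
                          probesets$probeset_id[j], sep = "|"))
  }
  sort(out)
}

# dense lattice search for the sigmoid fit (reference for R within 0.01)
lattice_fit_R <- function(M, E) {
  best_sse <- Inf; best <- c(0, 0, 0)
  a_grid <- seq(0, 200, length.out = 41)
  b_grid <- c(0, exp(seq(log(0.005), log(5), length.out = 40)))
  c_grid <- seq(-50, 150, length.out = 81)
  for (b in b_grid) for (cc in c_grid) {
    g <- 1 / (1 + exp(pmin(700, pmax(-700, b * (M - cc)))))
    for (a in a_grid) {
      sse <- sum((a * g - E)^2)
      if (sse < best_sse) { best_sse <- sse; best <- c(a, b, cc) }
    }
  }
  g <- 1 / (1 + exp(pmin(700, pmax(-700, best[2] * (M - best[3])))))
  fit <- best[1] * g
  ssr <- sum((fit - mean(E))^2)
  if (ssr + best_sse == 0) 0 else ssr / (ssr + best_sse)
}

# rank-based AUROC of scores for a binary truth label
auroc <- function(score, is_positive) {
  r <- rank(score)
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# minimal methylation_reduction for handcrafted association layouts
fake_reduction <- function(clusters, n_lines = 4) {
  reps <- matrix(50, nrow(clusters), n_lines,
                 dimnames = list(clusters$representative_id,
                                 sprintf("CL%02d", seq_len(n_lines))))
  structure(list(clusters = clusters, representatives = reps,
                 regions = NULL, assignments = NULL),
            class = "methylation_reduction")
}

make_clusters_df <- function(chromosome, anchor_pos,
                             ids = sprintf("rep%03d", seq_along(anchor_pos))) {
  data.frame(representative_id = ids, region_id = sub("_c.*", "", ids),
             cluster = 1L, chromosome = chromosome,
             anchor_site = ids, anchor_pos = anchor_pos,
             n_sites = 1L, sigma = 1, k = 1L, compactness = NA_real_,
             stringsAsFactors = FALSE)
}

make_expression_df <- function(chromosome, start, end,
                               gene = sprintf("G%03d", seq_along(start)),
                               ids = sprintf("ps%03d", seq_along(start)),
                               n_lines = 4) {
  panel <- methrank::cell_panel(sprintf("CL%02d", seq_len(n_lines)))
  probesets <- data.frame(probeset_id = ids, gene = gene,
                          chromosome = chromosome, start = start,
                          end = end, stringsAsFactors = FALSE)
  prof <- matrix(1, nrow(probesets), n_lines,
                 dimnames = list(ids, panel$cell_lines))
  structure(list(probesets = probesets, profiles = prof, panel = panel,
                 normalized = FALSE),
            class = "expression_set")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
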