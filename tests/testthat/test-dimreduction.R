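sites_df <- function(pos, chrom = "chr1") {
  data.frame(site_id = sprintf("s%03d", seq_along(pos)),
             chromosome = rep_len(chrom, length(pos)), position = pos,
             stringsAsFactors = FALSE)
}

test_that("proximity grouping splits on gaps above the threshold, inclusive", {
  r <- group_by_proximity(sites_df(c(100, 1500, 5000)), gap = 2000)
  expect_equal(nrow(r), 2)
  expect_identical(r$member_sites[[1]], c("s001", "s002"))
  expect_identical(r$member_sites[[2]], "s003")

  # a gap of exactly 2000 bp merges
  r2 <- group_by_proximity(sites_df(c(10, 2010, 4010, 10000)), gap = 2000)
  expect_equal(nrow(r2), 2)
  expect_equal(r2$n_sites, c(3L, 1L))

  # chromosomes never merge
  r3 <- group_by_proximity(sites_df(c(100, 200), c("chr1", "chr2")))
  expect_equal(nrow(r3), 2)
})

test_that("region count on a spacing mixture matches the linear-scan oracle", {
  withr::local_seed(11)
  n <- 10000
  spacing <- ifelse(runif(n) < 0.8, sample(10:500, n, TRUE),
                    sample(3000:50000, n, TRUE))
  chrom <- sort(sample(sprintf("chr%d", 1:6), n, TRUE))
  pos <- unlist(lapply(split(spacing, chrom), cumsum), use.names = FALSE)
  s <- sites_df(pos)
  s$chromosome <- chrom
  r <- group_by_proximity(s, gap = 2000)
  expect_equal(nrow(r), region_count_bf(chrom, pos, 2000))
  # conservation and idempotence
  expect_setequal(unlist(r$member_sites), s$site_id)
  expect_equal(sum(r$n_sites), n)
  one <- s[s$site_id %in% r$member_sites[[5]], ]
  again <- group_by_proximity(one, gap = 2000)
  expect_equal(nrow(again), 1)
  expect_identical(again$member_sites[[1]], r$member_sites[[5]])
})

test_that("PCA keeps the minimal component count for the variance target", {
  withr::local_seed(2)
  base <- rnorm(20)
  x <- cbind(base, 2 * base, -base, 0.5 * base)
  expect_equal(fit_pca(x, 0.99)$n_kept, 1)

  # exact rank-3 matrix at variance_target = 1
  y <- matrix(rnorm(40 * 3), 40, 3) %*% matrix(rnorm(3 * 10), 3, 10)
  expect_equal(fit_pca(y, 1.0)$n_kept, qr(scale(y, scale = FALSE))$rank)

  # planted inter-line correlation (factor structure) concentrates the
  # variance in few components, as correlated cell-line panels do
  lambda <- matrix(rnorm(45 * 6), 6, 45)
  f <- matrix(rnorm(500 * 6), 500, 6)
  z <- f %*% lambda + matrix(rnorm(500 * 45, 0, 0.05), 500, 45)
  kept <- fit_pca(z, 0.99)$n_kept
  expect_true(kept >= 6 && kept <= 15)

  expect_error(fit_pca(matrix(5, 10, 4)), "zero variance")
})

test_that("affinity matrix matches its definition and the brute force", {
  A <- affinity_matrix(rbind(c(1, 1), c(1, 1)), sigma = 0.7)
  expect_equal(A, rbind(c(0, 1), c(1, 0)))

  s <- 0.9
  pts <- rbind(c(0, 0), c(s * sqrt(2), 0))
  expect_equal(affinity_matrix(pts, s)[1, 2], exp(-1))

  withr::local_seed(4)
  p <- matrix(rnorm(40), 20, 2)
  expect_equal(affinity_matrix(p, 0.6), affinity_bf(p, 0.6),
               tolerance = 1e-12)
  expect_error(affinity_matrix(p, 0), "positive")
})

test_that("normalized Laplacian matches brute force and is well behaved", {
  A <- rbind(c(0, 1), c(1, 0))
  expect_equal(normalized_laplacian(A), A)

  withr::local_seed(5)
  p <- matrix(rnorm(60), 30, 2)
  A <- affinity_matrix(p, 0.8)
  L <- normalized_laplacian(A)
  expect_equal(L, laplacian_bf(A), tolerance = 1e-12)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev <= 1 + 1e-10 & ev >= -1 - 1e-10))

  # block-diagonal affinity keeps its block structure
  B <- matrix(0, 4, 4)
  B[1:2, 1:2] <- rbind(c(0, 0.5), c(0.5, 0))
  B[3:4, 3:4] <- rbind(c(0, 0.2), c(0.2, 0))
  LB <- normalized_laplacian(B)
  expect_equal(LB[1:2, 3:4], matrix(0, 2, 2))

  A0 <- matrix(0, 3, 3); A0[1, 2] <- A0[2, 1] <- 1
  expect_error(normalized_laplacian(A0), "isolated")
})

test_that("spectral embedding rows are unit norm and span the top eigenspace", {
  withr::local_seed(6)
  blobs <- rbind(matrix(rnorm(30, 0), 15, 2),
                 matrix(rnorm(30, 6), 15, 2))
  L <- normalized_laplacian(affinity_matrix(blobs, 1))
  Y <- spectral_embed(L, 2)
  expect_equal(unname(sqrt(rowSums(Y^2))), rep(1, 30))

  # subspace agreement with an independent SVD decomposition
  sv <- svd(L)
  keep <- order(sv$d * sign(colSums(sv$u * sv$v)), decreasing = TRUE)[1:2]
  U <- sv$u[, keep]
  ee <- eigen(L, symmetric = TRUE)
  X <- ee$vectors[, 1:2]
  expect_equal(X %*% t(X), U %*% t(U), tolerance = 1e-8)
})

test_that("KSC separates blobs, and k = n yields singletons", {
  withr::local_seed(7)
  blobs <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
                 matrix(rnorm(40, 5, 0.3), 20, 2),
                 matrix(rnorm(40, c(0, 8), 0.3), 20, 2, byrow = TRUE))
  truth <- rep(1:3, each = 20)
  res <- ksc_cluster(blobs, sigma = 1, k = 3, seed = 1)
  expect_equal(ari(res$cluster, truth), 1)

  small <- matrix(rnorm(10), 5, 2)
  res_n <- ksc_cluster(small, sigma = 1, k = 5, seed = 1)
  expect_equal(sort(unique(res_n$cluster)), 1:5)
})

test_that("compactness equals W/B with the documented degenerate cases", {
  pts <- rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0))
  asg <- c(1, 1, 2, 2)
  ctr <- rbind(c(0.5, 0), c(10.5, 0))
  expect_equal(compactness(pts, asg, ctr), 0.05)
  expect_equal(compactness(pts, asg, rbind(c(1, 1), c(1, 1))), Inf)
  expect_error(compactness(pts, rep(1, 4), matrix(0, 1, 2)),
               "fewer than 2 clusters")

  withr::local_seed(8)
  p <- matrix(rnorm(80), 40, 2)
  a <- sample(1:4, 40, TRUE)
  ctr <- do.call(rbind, lapply(1:4, function(k) colMeans(p[a == k, , drop = FALSE])))
  expect_equal(compactness(p, a, ctr), compactness_bf(p, a, ctr),
               tolerance = 1e-12)
})

test_that("parameter selection is an exhaustive grid arg-min", {
  withr::local_seed(9)
  pts <- rbind(matrix(rnorm(40, 0, 0.4), 20, 2),
               matrix(rnorm(40, 5, 0.4), 20, 2))
  # one-pair grid returns that pair
  one <- select_parameters(pts, sigma_grid = 1.3, k_grid = 2, seed = 5)
  expect_equal(one$sigma, 1.3)
  expect_equal(one$k, 2L)

  sel <- select_parameters(pts, sigma_grid = c(0.3, 1, 3),
                           k_grid = 2:4, seed = 5)
  # recompute every pair independently through the public chain
  rescore <- apply(sel$grid, 1, function(row) {
    tryCatch({
      cl <- ksc_cluster(pts, row[["sigma"]], as.integer(row[["k"]]), seed = 5)
      km_ctr <- cl$centers
      compactness(cl$Y, cl$cluster, km_ctr)
    }, error = function(e) Inf)
  })
  expect_equal(min(rescore), sel$compactness, tolerance = 1e-10)
  expect_equal(sel$grid$score, unname(rescore), tolerance = 1e-10)
})

test_that("degenerate regions fall back to a single cluster with a warning", {
  pts <- matrix(50, 5, 3) # all points coincide
  expect_warning(sel <- select_parameters(pts, seed = 1), "single cluster")
  expect_equal(sel$k, 1L)
  expect_true(all(sel$cluster == 1L))
})

test_that("reduction conserves sites and bounds representatives", {
  g <- generate_panel(n_lines = 12, n_genes = 12, sites_per_group = 5,
                      seed = 21)
  red <- reduce_methylation(g$methylation, seed = 3)
  # conservation: every site in exactly one region and one cluster
  expect_setequal(red$assignments$site_id, g$methylation$sites$site_id)
  expect_equal(sum(red$clusters$n_sites), nrow(g$methylation$sites))
  expect_equal(nrow(red$assignments), nrow(g$methylation$sites))

  # representative profile bounded by its members, per cell line
  prof <- g$methylation$profiles
  for (rid in utils::head(red$clusters$representative_id, 10)) {
    mem <- red$assignments$site_id[red$assignments$representative_id == rid]
    sub <- prof[mem, , drop = FALSE]
    rep_prof <- red$representatives[rid, ]
    expect_true(all(rep_prof >= apply(sub, 2, min) - 1e-9))
    expect_true(all(rep_prof <= apply(sub, 2, max) + 1e-9))
  }

  # planted structure: clusters recover the latent sub-groups
  truth_lab <- paste(red$assignments$region_id[
    match(g$truth$sites$site_id, red$assignments$site_id)],
    g$truth$sites$subgroup)
  found_lab <- red$assignments$representative_id[
    match(g$truth$sites$site_id, red$assignments$site_id)]
  expect_gte(ari(truth_lab, found_lab), 0.9)
})

test_that("a single site reduces to one region and its own profile", {
  s <- sites_df(123)
  prof <- matrix(c(10, 20, 30, 40), 1, 4,
                 dimnames = list("s001", sprintf("CL%02d", 1:4)))
  ms <- structure(list(sites = s, profiles = prof,
                       panel = cell_panel(colnames(prof)), dropped = 0L),
                  class = "methylation_set")
  red <- reduce_methylation(ms)
  expect_equal(nrow(red$regions), 1)
  expect_equal(nrow(red$clusters), 1)
  expect_equal(unname(red$representatives[1, ]), c(10, 20, 30, 40))
})
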