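test_that("the generator is deterministic and respects its invariants", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- generate_panel(n_lines = 10, n_genes = 15, seed = 5, dir = d1)
  g2 <- generate_panel(n_lines = 10, n_genes = 15, seed = 5, dir = d2)
  for (f in c("methylation.tsv", "expression.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  m <- g1$methylation
  expect_true(all(m$profiles >= 0 & m$profiles <= 100))
  expect_true(all(m$sites$position >= 1))
  ord <- order(m$sites$chromosome, m$sites$position)
  expect_identical(ord, seq_len(nrow(m$sites)))

  # intra-clump spacing far below the proximity rule, inter-clump far above
  r <- group_by_proximity(m, gap = 2000)
  expect_equal(nrow(r), 15)

  expect_equal(length(g1$truth$regulated_genes), round(0.15 * 15))

  # every probe set lies within the association window of its own clump
  ps <- g1$expression$probesets
  for (i in seq_len(nrow(ps))) {
    clump <- g1$truth$sites[g1$truth$sites$gene == ps$gene[i], ]
    expect_true(any(clump$position >= ps$start[i] - 20000 &
                      clump$position <= ps$end[i] + 20000))
  }
})

test_that("regulated genes carry the planted decreasing relation", {
  g <- generate_panel(n_lines = 20, n_genes = 20, noise_sd = 0, seed = 8)
  norm <- normalize_expression(g$expression)
  for (gene in g$truth$regulated_genes) {
    ps <- which(norm$probesets$gene == gene)[1]
    E <- norm$profiles[ps, ]
    M <- g$truth$promoter_mean[[gene]]
    expect_lt(cor(M, E, method = "spearman"), -0.99)
  }
  # null genes are independent of methylation
  nulls <- setdiff(unique(norm$probesets$gene), g$truth$regulated_genes)
  cors <- vapply(nulls, function(gene) {
    ps <- which(norm$probesets$gene == gene)[1]
    cor(g$truth$promoter_mean[[gene]], norm$profiles[ps, ])
  }, numeric(1))
  expect_lt(max(abs(cors)), 0.8)
})

test_that("concentric circles have the requested geometry", {
  cc <- generate_circles(50, radii = c(1, 3, 5), noise_sd = 0, seed = 2)
  r <- sqrt(rowSums(cc$points^2))
  expect_equal(r, rep(c(1, 3, 5), each = 50), tolerance = 1e-12)
  expect_identical(cc$labels, rep(1:3, each = 50))

  one <- generate_circles(30, radii = 2, noise_sd = 0.05, seed = 3)
  expect_true(all(one$labels == 1))
  expect_warning(generate_circles(30, radii = c(1, 1.1), noise_sd = 0.5),
                 "overlap")
  expect_error(generate_circles(30, radii = c(3, 1)), "increasing")
})
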