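test_that("data generated exactly from the curve reaches a perfect fit", {
  withr::local_seed(41)
  M <- runif(45, 0, 100)
  E <- 100 / (1 + exp(0.1 * (M - 50)))
  f <- fit_curve(M, E)
  expect_lt(f$SSE, 1e-10)
  expect_equal(f$R, 1, tolerance = 1e-9)
  expect_equal(f$a, 100, tolerance = 1e-4)
  expect_equal(f$b, 0.1, tolerance = 1e-3)
  expect_equal(f$c, 50, tolerance = 1e-2)

  # scale coherence: doubling E doubles a, still perfect
  f2 <- fit_curve(M, 2 * E)
  expect_equal(f2$R, 1, tolerance = 1e-9)
  expect_equal(f2$a, 200, tolerance = 1e-3)
})

test_that("constant expression is the degenerate R = 0 case", {
  M <- seq(5, 95, length.out = 20)
  f <- fit_curve(M, rep(7, 20))
  expect_lt(f$SSE, 1e-18)
  expect_lt(f$SSR, 1e-18)
  expect_equal(f$R, 0)
})

test_that("compute_R follows SSR / (SSR + SSE) with its conventions", {
  expect_equal(compute_R(5, 0), 1)
  expect_equal(compute_R(3, 3), 0.5)
  expect_equal(compute_R(0, 2), 0)
  expect_equal(compute_R(0, 0), 0)
  expect_error(compute_R(-1, 2), "nonnegative")
})

test_that("the optimizer matches a dense lattice search within 0.01", {
  withr::local_seed(42)
  for (i in 1:4) {
    M <- runif(30, 0, 100)
    E <- 90 / (1 + exp(0.12 * (M - 45))) + rnorm(30, 0, 8)
    E <- pmax(E, 0)
    f <- fit_curve(M, E)
    expect_lt(abs(f$R - lattice_fit_R(M, E)), 0.01)
  }
})

test_that("R is invariant to reordering the (M, E) pairs", {
  withr::local_seed(43)
  M <- runif(25, 0, 100)
  E <- 70 / (1 + exp(0.1 * (M - 55))) + rnorm(25, 0, 5)
  f1 <- fit_curve(M, E)
  idx <- sample(25)
  f2 <- fit_curve(M[idx], E[idx])
  expect_equal(f1$R, f2$R, tolerance = 1e-9)
})

test_that("pairs with missing values are dropped; too few pairs skip", {
  M <- c(10, 20, 30, 40, NA, 60)
  E <- c(9, 8, 7, 6, 5, NA)
  f <- fit_curve(M, E)
  expect_true(f$converged)
  expect_equal(f$n_used, 4)

  few <- fit_curve(c(1, 2, 3, NA), c(4, 3, 2, 1))
  expect_false(few$converged)
  expect_match(few$reason, "fewer than 4")
})

test_that("permutation p-values follow the plain count convention", {
  withr::local_seed(44)
  M <- runif(40, 0, 100)
  E <- 90 / (1 + exp(0.15 * (M - 50)))
  # perfect fit beats every permutation: p = 0 exactly
  pv <- permutation_pvalue(M, E, m_perm = 300, seed = 9)
  expect_identical(pv$p_value, 0)

  # degenerate R_obs = 0 is tied or beaten by every permutation: p = 1
  pv0 <- permutation_pvalue(M, rep(5, 40), m_perm = 50, seed = 9)
  expect_identical(pv0$p_value, 1)

  # monotonicity in R_obs for a fixed permutation stream
  En <- runif(40, 0, 100)
  nul <- permutation_pvalue(M, En, m_perm = 200, seed = 7,
                            keep_null = TRUE)$r_null
  p_of <- function(r) mean(nul >= r)
  rs <- sort(runif(10))
  expect_true(all(diff(vapply(rs, p_of, numeric(1))) <= 0))

  expect_error(permutation_pvalue(M, E, m_perm = 0), "at least 1")
})

test_that("gene ranking keeps the max-R association and filters on alpha", {
  scored <- data.frame(
    assoc_id = c("a1", "a2", "b1", "c1"),
    gene = c("G1", "G1", "G2", "G3"),
    R = c(0.5, 0.7, 0.4, 0.9),
    p_value = c(0.01, 0.02, 0.06, 0.001),
    stringsAsFactors = FALSE)
  best <- best_gene_associations(scored)
  expect_equal(best$R[best$gene == "G1"], 0.7)
  ranked <- rank_genes(scored, alpha = 0.05)
  expect_identical(ranked$gene, c("G3", "G1")) # G2 excluded at p = 0.06
  expect_identical(ranked$R, sort(ranked$R, decreasing = TRUE))
  expect_true(all(ranked$q_value >= ranked$p_value))
})
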