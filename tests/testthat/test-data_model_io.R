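test_that("methylation and expression tables round-trip through read/write", {
  dir <- withr::local_tempdir()
  g <- generate_panel(n_lines = 8, n_genes = 10, sites_per_group = 4,
                      seed = 42, dir = dir)
  ms1 <- read_methylation(file.path(dir, "methylation.tsv"))
  p2 <- file.path(dir, "meth2.tsv")
  write_methylation(ms1, p2)
  expect_identical(readLines(p2), readLines(file.path(dir, "methylation.tsv")))
  ms2 <- read_methylation(p2)
  expect_identical(ms1$sites, ms2$sites)
  expect_identical(ms1$profiles, ms2$profiles)

  es1 <- read_expression(file.path(dir, "expression.tsv"))
  e2 <- file.path(dir, "expr2.tsv")
  write_expression(es1, e2)
  expect_identical(readLines(e2), readLines(file.path(dir, "expression.tsv")))
  es2 <- read_expression(e2)
  expect_identical(es1$probesets, es2$probesets)
  expect_identical(es1$profiles, es2$profiles)
})

test_that("sites without valid chromosome annotation are dropped and counted", {
  f <- withr::local_tempfile(lines = c(
    "site_id\tchromosome\tposition\tA\tB",
    "s1\tchr1\t100\t10\t20",
    "s2\t\t200\t30\t40",
    "s3\tchr2\t300\t50\t60"))
  expect_message(ms <- read_methylation(f), "dropped 1 site")
  expect_equal(nrow(ms$sites), 2)
  expect_equal(ms$dropped, 1L)
  expect_setequal(ms$sites$site_id, c("s1", "s3"))
})

test_that("profile columns are reordered to the panel order", {
  f <- withr::local_tempfile(lines = c(
    "site_id\tchromosome\tposition\tB\tA",
    "s1\tchr1\t100\t10\t20"))
  panel <- cell_panel(c("A", "B"))
  ms <- read_methylation(f, panel)
  expect_identical(colnames(ms$profiles), c("A", "B"))
  expect_equal(unname(ms$profiles[1, ]), c(20, 10))
})

test_that("malformed tables are rejected with informative errors", {
  f1 <- withr::local_tempfile(lines = c(
    "site_id\tchromosome\tposition\tA",
    "s1\tchr1\tzzz\t10"))
  expect_error(read_methylation(f1), "line 2")
  f2 <- withr::local_tempfile(lines = c(
    "site_id\tchromosome\tposition\tA",
    "s1\tchr1\t10\t150"))
  expect_error(read_methylation(f2), "outside \\[0, 100\\]")
  f3 <- withr::local_tempfile(lines = c(
    "site_id\tchromosome\tposition\tA",
    "s1\tchr1\t10\t50"))
  expect_error(read_methylation(f3, cell_panel(c("A", "B"))), "missing: B")
  f4 <- withr::local_tempfile(lines = c(
    "probeset_id\tgene\tchromosome\tstart\tend\tA",
    "p1\tg1\tchr1\t500\t400\t2.5"))
  expect_error(read_expression(f4), "start > end")
  f5 <- withr::local_tempfile(lines = c(
    "probeset_id\tgene\tchromosome\tstart\tend\tA",
    "p1\tg1\tchr1\t100\t400\tnope"))
  expect_error(read_expression(f5), "column 'A'")
})

test_that("a gene may carry multiple probe sets and empty tables warn", {
  f <- withr::local_tempfile(lines = c(
    "probeset_id\tgene\tchromosome\tstart\tend\tA\tB",
    "p1\tg1\tchr1\t100\t400\t1\t2",
    "p2\tg1\tchr1\t150\t450\t3\t4"))
  es <- read_expression(f)
  expect_equal(nrow(es$probesets), 2)
  expect_equal(unique(es$probesets$gene), "g1")

  f0 <- withr::local_tempfile(lines =
    "probeset_id\tgene\tchromosome\tstart\tend\tA\tB")
  expect_warning(es0 <- read_expression(f0), "empty")
  expect_equal(nrow(es0$probesets), 0)
})

test_that("panel harmonization takes the sorted intersection", {
  a <- cell_panel(sprintf("L%02d", 1:58))
  b <- cell_panel(sprintf("L%02d", c(40:51, 1:33, 90:95)))
  h <- harmonize_panels(a, b)
  expect_equal(length(h), 45)
  expect_identical(h$cell_lines, sort(h$cell_lines))
  expect_identical(harmonize_panels(a, a)$cell_lines, sort(a$cell_lines))
  expect_error(harmonize_panels(cell_panel(c("x", "y")),
                                cell_panel(c("u", "v"))),
               "no cell lines")
})

test_that("expression normalization de-logs then min-max scales globally", {
  es <- make_expression_df("chr1", 100, 400, n_lines = 3)
  es$profiles[1, ] <- c(1, 2, 3) # log2 -> {2, 4, 8}
  norm <- normalize_expression(es, log_base = 2)
  expect_equal(unname(norm$profiles[1, ]), c(0, 100 * 2 / 6, 100),
               tolerance = 1e-12)
  expect_error(normalize_expression(norm), "already normalized")

  flat <- make_expression_df("chr1", 100, 400, n_lines = 3)
  expect_error(normalize_expression(flat), "constant")
})

test_that("normalization is monotone and attains both extremes once", {
  g <- generate_panel(n_lines = 10, n_genes = 12, seed = 3)
  norm <- normalize_expression(g$expression)
  v_in <- as.vector(g$expression$profiles)
  v_out <- as.vector(norm$profiles)
  expect_identical(order(v_in), order(v_out))
  expect_true(all(v_out >= 0 & v_out <= 100))
  expect_equal(sum(v_out == 0), 1)
  expect_equal(sum(v_out == 100), 1)
})
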