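test_that("gc_fraction is the G+C proportion", {
  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("GGCC"), 1)
  expect_equal(gc_fraction("ATAT"), 0)
  expect_equal(gc_fraction(c("ATGC", "GGCC")), c(0.5, 1))
})

test_that("codon usage w is frequency over family maximum", {
  orfs <- suppressMessages(orfs_from_sequences("x", "ATGGGG"))
  u <- build_usage(orfs)
  expect_equal(u$w[u$codon == "ATG"], 1)
  expect_equal(u$w[u$codon == "GGG"], 1)
  # 3:1 family counts give w = 1 and 1/3
  orfs2 <- suppressMessages(orfs_from_sequences("y", "GGGGGGGGGGGA"))
  u2 <- build_usage(orfs2)
  expect_equal(u2$w[u2$codon == "GGG"], 1)
  expect_equal(u2$w[u2$codon == "GGA"], 1 / 3)
  # unseen codons get the 0.5 pseudo-count, so w stays positive
  expect_true(all(u$w > 0))
  expect_true(all(u$w <= 1))
  expect_false(any(c("TAA", "TAG", "TGA") %in% u$codon))
})

test_that("CAI is the geometric mean of w excluding single-codon families", {
  code <- genetic_code()
  # usage where GGG has w = 1 and GGA has w = 0.25
  u <- orfselect:::usage_from_counts(c(GGG = 100, GGA = 25), code)
  expect_equal(cai("GGG", u), 1)
  expect_equal(cai("GGA", u), 0.25)
  expect_equal(cai("GGGGGA", u), 0.5)      # sqrt(1 * 0.25)
  # ATG (single-codon family) never enters the mean
  expect_equal(cai("ATGGGGGGA", u), 0.5)
  expect_error(cai("ATG", u), "no codons usable")
})

test_that("CAI is invariant under codon-order permutation", {
  set.seed(8)
  nt <- random_cds(60)
  orfs <- suppressMessages(orfs_from_sequences("z", nt))
  u <- build_usage(orfs)
  cods <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  perm <- paste(sample(cods), collapse = "")
  expect_equal(cai(nt, u), cai(perm, u), tolerance = 1e-12)
})

test_that("usage tables round-trip through the two-column text format", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# codon usage", "GGG 100", "GGA 25", "ATG 10"), f)
  u <- read_usage_table(f)
  expect_equal(u$w[u$codon == "GGA"], 0.25)
  writeLines(c("GGG notanumber"), f)
  expect_error(read_usage_table(f), "non-numeric")
})

test_that("two-sample K-S comparison matches hand-computed D", {
  same <- ks_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  disjoint <- ks_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(disjoint$statistic, 1)
  expect_equal(ks_compare(c(1, 2, 3), c(1, 2, 4))$statistic, 1 / 3)
  # symmetric in its samples
  set.seed(6)
  x <- rnorm(20); y <- rnorm(25, 1)
  expect_equal(ks_compare(x, y)$statistic, ks_compare(y, x)$statistic)
  expect_error(ks_compare(1, c(1, 2)), "at least 2")
})

test_that("K-S p-value decreases as D grows at fixed sample sizes", {
  x <- 1:20
  p_small <- ks_compare(x, x + 2)$p_value
  p_large <- ks_compare(x, x + 15)$p_value
  expect_gt(ks_compare(x, x + 2)$statistic, 0)
  expect_lt(p_large, p_small)
})
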