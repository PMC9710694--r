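test_that("contingency tables follow the product-and-round rule", {
  tab <- build_table(list(d_N = 0.1, N_NS = 600.7, d_S = 0.3, N_S = 200.3))
  expect_equal(unclass(tab)[c("ns_sub", "ns_unsub", "s_sub", "s_unsub")],
               list(ns_sub = 60L, ns_unsub = 541L, s_sub = 60L, s_unsub = 140L))
  # rounding is half-away-from-zero, not banker's
  tab <- build_table(list(d_N = 0, N_NS = 100, d_S = 10.5 / 100, N_S = 100))
  expect_equal(tab$s_sub, 11L)
  tab <- build_table(list(d_N = 0, N_NS = 50, d_S = 0, N_S = 20))
  expect_equal(tab$ns_sub, 0L)
  expect_equal(tab$s_sub, 0L)
  expect_error(build_table(list(d_N = 0, N_NS = 0, d_S = 0, N_S = 10)), "degenerate")
})

test_that("a substituted cell exceeding its rounded margin is clamped with a warning", {
  # a CODEML d_S slightly above 1 can round the product past the margin
  expect_warning(
    tab <- build_table(list(d_N = 0, N_NS = 10, d_S = 1.05, N_S = 10)),
    "clamping"
  )
  expect_equal(tab$s_sub, 10L)
  expect_equal(tab$s_unsub, 0L)
})

test_that("fisher_exact reproduces hand-enumerated p-values", {
  expect_equal(fisher_exact(matrix(c(5, 95, 5, 95), 2, byrow = TRUE)), 1)
  expect_equal(fisher_exact(matrix(c(0, 50, 0, 50), 2, byrow = TRUE)), 1)
  # only x = 10 and x = 0 are as-or-more extreme: p = 2 / choose(20, 10)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)),
               2 / choose(20, 10), tolerance = 1e-12)
})

test_that("fisher_exact agrees with stats::fisher.test on random tables", {
  set.seed(77)
  for (i in 1:50) {
    m <- matrix(rpois(4, 12), 2)
    expect_equal(
      fisher_exact(m),
      stats::fisher.test(m)$p.value,
      tolerance = 1e-7,
      info = paste(m, collapse = ",")
    )
  }
})

test_that("p-values are invariant under row and column swaps", {
  set.seed(78)
  for (i in 1:25) {
    m <- matrix(rpois(4, 8), 2)
    p <- fisher_exact(m)
    expect_equal(fisher_exact(m[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisher_exact(m[, 2:1]), p, tolerance = 1e-12)
  }
})

test_that("alpha adjustment implements the one-expected-false-positive rule", {
  expect_equal(adjust_alpha(1, 0.05), 0.05)
  expect_equal(adjust_alpha(1000, 0.05), 0.001)
  expect_equal(adjust_alpha(10, 0.5), 0.1)
  expect_equal(adjust_alpha(10, 0.05, policy = "bonferroni"), 0.005)
  expect_equal(adjust_alpha(10, 0.05, policy = "none"), 0.05)
  expect_error(adjust_alpha(0, 0.05), "positive")
})

test_that("batch classification assigns verdicts against the adjusted threshold", {
  ests <- tibble::tibble(
    d_N = c(0.05, 0.30, 0),
    d_S = c(0.30, 0.30, 0),
    N_S = c(200, 200, 200),
    N_NS = c(600, 600, 600),
    omega = c(0.167, 1, NA)
  )
  out <- classify_pairs(ests, alpha = 0.05, policy = "none")
  expect_equal(out$m_tests, rep(3L, 3))
  expect_equal(out$verdict[1], "confirmed")   # strong purifying signal
  expect_equal(out$verdict[2], "dubious")     # identical rates, p = 1
  expect_equal(out$verdict[3], "insufficient")# no substitutions at all
  expect_equal(out$p_value[3], 1)

  # one-fp policy tightens the threshold to 1/m
  many <- ests[rep(1:2, 50), ]
  out2 <- classify_pairs(many, alpha = 0.05, policy = "one-fp")
  expect_equal(unique(out2$alpha_adjusted), 0.01)
  g <- glance(out2)
  expect_equal(g$m_tests, 100L)
  expect_equal(g$n_confirmed + g$n_dubious + g$n_insufficient, 100L)
})
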