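ca_from <- function(codons_a, codons_b) {
  structure(
    tibble::tibble(column = seq_along(codons_a), codon_a = codons_a, codon_b = codons_b),
    class = c("codon_alignment", class(tibble::tibble()))
  )
}

test_that("substitution counting reproduces hand-worked codon pairs", {
  expect_equal(count_substitutions(ca_from("TTT", "TTT"))$subs, list(n_S = 0, n_NS = 0))
  expect_equal(count_substitutions(ca_from("TTT", "TTC"))$subs, list(n_S = 1, n_NS = 0))
  # two 2-step pathways TTT->GTT->GTA and TTT->TTA->GTA average to (0.5, 1.5)
  expect_equal(count_substitutions(ca_from("TTT", "GTA"))$subs, list(n_S = 0.5, n_NS = 1.5))
  expect_error(count_substitutions(ca_from(character(0), character(0))), "no codons")
})

test_that("pathway averaging agrees with the recursive enumerator on random codon pairs", {
  set.seed(21)
  pairs <- cbind(
    sample(SENSE_CODONS, 150, replace = TRUE),
    sample(SENSE_CODONS, 150, replace = TRUE)
  )
  for (i in seq_len(nrow(pairs))) {
    got <- count_substitutions(ca_from(pairs[i, 1], pairs[i, 2]))$subs
    want <- oracle_pair_subs(pairs[i, 1], pairs[i, 2])
    expect_equal(c(got$n_S, got$n_NS), unname(want), tolerance = 1e-12,
                 info = paste(pairs[i, ], collapse = "/"))
  }
})

test_that("estimate is symmetric under swapping the two sequences", {
  set.seed(31)
  a <- sample(SENSE_CODONS, 40, replace = TRUE)
  b <- sample(SENSE_CODONS, 40, replace = TRUE)
  e1 <- estimate_selection(ca_from(a, b))
  e2 <- estimate_selection(ca_from(b, a))
  expect_equal(e1$d_N, e2$d_N)
  expect_equal(e1$d_S, e2$d_S)
  expect_equal(e1$omega, e2$omega)
})

test_that("identical sequences give zero rates and undefined omega", {
  set.seed(32)
  a <- sample(SENSE_CODONS, 30, replace = TRUE)
  est <- estimate_selection(ca_from(a, a))
  expect_equal(est$d_N, 0)
  expect_equal(est$d_S, 0)
  expect_true(is.na(est$omega))
  expect_equal(est$source, "internal")
  expect_equal(est$N_S + est$N_NS, 90)
})

test_that("substitution proportions stay within site counts in the validity regime", {
  # the uncorrected proportions are rates only while divergence stays
  # moderate (the regime the d_S < 1 quality rule enforces); check on
  # simulated pairs at that divergence
  spec <- simulation_spec(n_codons = 100, omega_true = 1, expected_ds = 0.4,
                          n_pairs = 8, seed = 33)
  pairs <- simulate_orf_pairs(spec)
  for (i in seq_len(nrow(pairs))) {
    a <- split_codons_chr(pairs$nt_a[i])
    b <- split_codons_chr(pairs$nt_b[i])
    est <- estimate_selection(ca_from(a, b))
    expect_lte(est$n_S, est$N_S)
    expect_lte(est$n_NS, est$N_NS)
    expect_true(est$d_N >= 0 && est$d_N <= 1)
    expect_true(est$d_S >= 0 && est$d_S <= 1)
    expect_lte(est$n_S + est$n_NS, 3 * 100)
  }
})
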