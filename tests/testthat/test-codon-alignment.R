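write_fasta <- function(ids, seqs) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

test_that("read_orfs strips terminal stops and rejects invalid records", {
  fa <- write_fasta(
    c("good", "internal_stop", "bad_frame"),
    c("ATGGGGTAA", "ATGTAAGGG", "ATGGGGTAAA")
  )
  orfs <- suppressMessages(read_orfs(fa))
  expect_equal(orfs$id, "good")
  expect_equal(orfs$nt, "ATGGGG")
  expect_equal(orfs$aa, "MG")
  expect_equal(orfs$length_aa, 2L)
  skipped <- attr(orfs, "skipped")
  expect_setequal(skipped$id, c("internal_stop", "bad_frame"))
  expect_match(skipped$reason[skipped$id == "internal_stop"], "internal stop")
  expect_match(skipped$reason[skipped$id == "bad_frame"], "multiple of 3")
})

test_that("read_orfs errors on unreadable or empty input", {
  expect_error(read_orfs(tempfile()), "cannot read")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), fa)
  expect_error(read_orfs(fa), "no sequences")
})

test_that("align_pair handles identity and single-gap toy cases", {
  id <- align_pair("MG", "MG")
  expect_equal(id$aligned_a, "MG")
  expect_equal(id$aligned_b, "MG")
  expect_equal(id$identity, 1)

  pa <- align_pair("MAAG", "MAG")
  expect_equal(nchar(pa$aligned_a), 4)
  expect_equal(sum(strsplit(pa$aligned_b, "")[[1]] == "-"), 1)
  # identity over the 3 residue-pair columns only
  expect_equal(pa$identity, 1)
})

test_that("alignment score matches an independent affine-gap DP on short proteins", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  set.seed(42)
  for (i in 1:25) {
    a <- random_protein(sample(3:12, 1))
    b <- random_protein(sample(3:12, 1))
    expect_equal(
      align_pair(a, b)$score,
      oracle_align_score(a, b, e$BLOSUM62),
      tolerance = 1e-9,
      info = paste(a, b)
    )
  }
})

test_that("back_translate is lossless on gap-free alignments and drops gap/N columns", {
  nt_a <- "ATGGCTGCGGGT"   # MAAG
  nt_b <- "ATGGCAGGG"      # MAG
  a <- list(nt = nt_a, aa = "MAAG")
  b <- list(nt = nt_b, aa = "MAG")
  ca <- back_translate(align_pair(a$aa, b$aa), a, b)
  expect_equal(nrow(ca), 3)
  expect_equal(paste(ca$codon_b, collapse = ""), nt_b)

  set.seed(5)
  nt <- random_cds(30)
  rec <- list(nt = nt, aa = translate_cds(nt))
  ca <- back_translate(align_pair(rec$aa, rec$aa), rec, rec)
  expect_equal(paste(ca$codon_a, collapse = ""), nt)
  expect_equal(paste(ca$codon_b, collapse = ""), nt)

  expect_error(
    back_translate(align_pair("MG", "MG"), list(nt = "ATGGCT", aa = "MA"), rec),
    "inconsistent"
  )
})

test_that("quality filter applies the identity and d_S rules", {
  expect_true(passes_quality(0.92, 0.08)$pass)
  q <- passes_quality(0.50, 0.08)
  expect_false(q$pass)
  expect_match(q$reasons, "identity")
  q <- passes_quality(0.95, 1.4)
  expect_false(q$pass)
  expect_match(q$reasons, "d_S")
  # CODEML mode: unknown identity, only the d_S rule applies
  expect_true(passes_quality(NA, 0.5)$pass)
})

test_that("reciprocal best hits are mutual, symmetric, and deterministic", {
  set.seed(9)
  seqs <- vapply(1:4, function(i) random_cds(25), character(1))
  orfs_a <- suppressMessages(orfs_from_sequences(paste0("a", 1:4), seqs))
  orfs_b <- suppressMessages(orfs_from_sequences(paste0("b", 1:4), seqs))
  rbh <- reciprocal_best_pairs(orfs_a, orfs_b)
  expect_equal(rbh$id_a, paste0("a", 1:4))
  expect_equal(rbh$id_b, paste0("b", 1:4))
  # symmetry under swapping the proteomes
  rbh_swap <- reciprocal_best_pairs(orfs_b, orfs_a)
  expect_equal(rbh_swap$id_a, rbh$id_b)
  expect_equal(rbh_swap$id_b, rbh$id_a)
  # a non-reciprocated best hit is excluded
  orfs_small <- orfs_a[1:2, ]
  rbh2 <- reciprocal_best_pairs(orfs_small, orfs_b)
  expect_true(all(rbh2$id_a %in% c("a1", "a2")))
})
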