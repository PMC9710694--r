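#' Specify a codon-evolution simulation
#'
#' Defines the conditions under which homologous ORF pairs are generated:
#' an ancestral sense-codon sequence of `n_codons` codons at G+C fraction
#' `gc_target` evolves into two independent descendants (star topology,
#' matching the pairwise comparison design) under an acceptance-rejection
#' substitution process with known true selection pressure `omega_true`.
#' Proposed single-nucleotide changes are uniform over positions and target
#' bases (no transition/transversion bias, i.e. kappa = 1) and are accepted
#' with probability 1 if synonymous, `omega_true` if nonsynonymous, and 0
#' if they would create a stop codon. The number of proposals per branch is
#' calibrated so the expected number of accepted synonymous changes per
#' synonymous site across the pair equals `expected_ds`.
#'
#' Defaults describe the operating regime the package targets: 300-codon
#' ORFs at 61% G+C (the giant-virus regime motivating the tool), neutral
#' truth (`omega_true = 1`), pairwise synonymous divergence 0.3, and 500
#' replicate pairs.
#'
#' @param n_codons ORF length in codons (>= 10).
#' @param gc_target Ancestral G+C fraction; realised GC is within +/- 0.05.
#' @param omega_true Relative acceptance probability of nonsynonymous
#'   changes (1 = neutral null).
#' @param expected_ds Target synonymous divergence of the pair (> 0).
#' @param n_pairs Number of replicate pairs.
#' @param seed RNG seed used by [simulate_orf_pairs()].
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_codons = 300, gc_target = 0.61, omega_true = 1,
                            expected_ds = 0.3, n_pairs = 500, seed = 1) {
  if (n_codons < 10) rlang::abort("n_codons must be >= 10")
  if (expected_ds <= 0) rlang::abort("expected_ds must be > 0")
  if (omega_true < 0) rlang::abort("omega_true must be >= 0")
  if (gc_target <= 0 || gc_target >= 1) rlang::abort("infeasible gc_target")
  structure(
    list(
      n_codons = n_codons, gc_target = gc_target, omega_true = omega_true,
      expected_ds = expected_ds, n_pairs = n_pairs, seed = seed
    ),
    class = "simulation_spec"
  )
}

# random stop-free codon sequence at the target GC, first codon ATG;
# uses the current RNG state
ancestor_sequence <- function(n_codons, gc_target, code = genetic_code(),
                              max_tries = 200L) {
  stops <- names(code)[code == "*"]
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  for (try in seq_len(max_tries)) {
    m <- matrix(
      sample(names(p), 3L * (n_codons - 1L), replace = TRUE, prob = p),
      nrow = 3L
    )
    cods <- apply(m, 2L, paste, collapse = "")
    while (any(bad <- cods %in% stops)) {
      k <- sum(bad)
      cods[bad] <- apply(
        matrix(sample(names(p), 3L * k, replace = TRUE, prob = p), nrow = 3L),
        2L, paste, collapse = ""
      )
    }
    nt <- paste(c("ATG", cods), collapse = "")
    if (abs(gc_fraction(nt) - gc_target) <= 0.05) return(nt)
  }
  rlang::abort("could not realise gc_target within +/- 0.05 (infeasible?)")
}

#' Simulate an ancestral ORF
#'
#' Draws a random stop-free sense-codon sequence at the spec's length and
#' G+C target, starting with ATG. Seeds the RNG from `spec$seed`, so the
#' same spec always yields the same ancestor.
#'
#' @param spec A [simulation_spec()].
#' @param code A [genetic_code()].
#' @return A one-row ORF tibble (as [read_orfs()]).
#' @export
simulate_ancestor <- function(spec, code = genetic_code()) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  nt <- ancestor_sequence(spec$n_codons, spec$gc_target, code)
  suppressMessages(orfs_from_sequences("ancestor", nt, code))
}

# evolve one branch; nt as a character scalar; uses current RNG state
evolve_branch <- function(nt, n_proposals, omega_true, code) {
  bases <- c("A", "C", "G", "T")
  s <- strsplit(nt, "")[[1]]
  L <- length(s)
  if (n_proposals == 0L) return(nt)
  pos <- sample.int(L, n_proposals, replace = TRUE)
  pick <- sample.int(3L, n_proposals, replace = TRUE)
  acc <- stats::runif(n_proposals)
  for (i in seq_len(n_proposals)) {
    p <- pos[i]
    old <- s[p]
    new <- setdiff(bases, old)[pick[i]]
    c0 <- (p - 1L) %/% 3L
    cod <- s[(c0 * 3L + 1L):(c0 * 3L + 3L)]
    aa_old <- code[[paste(cod, collapse = "")]]
    cod[(p - 1L) %% 3L + 1L] <- new
    aa_new <- code[[paste(cod, collapse = "")]]
    if (aa_new == "*") next                       # never create a stop
    if (aa_new == aa_old) s[p] <- new             # synonymous: accept
    else if (acc[i] < omega_true) s[p] <- new     # nonsynonymous: accept w.p. omega
  }
  paste(s, collapse = "")
}

#' Evolve a pair of descendants from an ancestor
#'
#' Applies the spec's acceptance-rejection substitution process
#' independently along two branches. The proposal count per branch is
#' `3 * n_codons * expected_ds / 2`, which makes the expected number of
#' accepted synonymous changes per synonymous site across the pair equal
#' to `expected_ds` (a uniform proposal is synonymous with probability
#' `N_S / (3 n_codons)` for the ancestor's synonymous site count `N_S`).
#' Uses the current RNG state; seed via [simulate_orf_pairs()] or
#' [set.seed()].
#'
#' @param ancestor A one-row ORF tibble (or list with `nt`), stop-free.
#' @param spec A [simulation_spec()].
#' @param code A [genetic_code()].
#' @return A list with `nt_a`, `nt_b`, the two descendant coding sequences.
#' @export
evolve_pair <- function(ancestor, spec, code = genetic_code()) {
  stopifnot(inherits(spec, "simulation_spec"))
  nt <- if (is.data.frame(ancestor)) ancestor$nt[[1]] else ancestor$nt
  n_prop <- as.integer(round_half_up(3 * spec$n_codons * spec$expected_ds / 2))
  list(
    nt_a = evolve_branch(nt, n_prop, spec$omega_true, code),
    nt_b = evolve_branch(nt, n_prop, spec$omega_true, code)
  )
}

#' Simulate replicate homologous ORF pairs
#'
#' Seeds the RNG from `spec$seed`, then for each replicate draws an
#' ancestor and evolves two descendants. Fully deterministic for a fixed
#' spec.
#'
#' @param spec A [simulation_spec()].
#' @param code A [genetic_code()].
#' @return A tibble with columns `pair`, `id_a`, `id_b`, `ancestor_nt`,
#'   `nt_a`, `nt_b`.
#' @export
simulate_orf_pairs <- function(spec, code = genetic_code()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  rows <- purrr::map(seq_len(spec$n_pairs), function(i) {
    anc <- ancestor_sequence(spec$n_codons, spec$gc_target, code)
    des <- evolve_pair(list(nt = anc), spec, code)
    tibble::tibble(
      pair = i,
      id_a = sprintf("sim%04d_a", i), id_b = sprintf("sim%04d_b", i),
      ancestor_nt = anc, nt_a = des$nt_a, nt_b = des$nt_b
    )
  })
  dplyr::bind_rows(rows)
}

#' Write simulated pairs as FASTA files plus a pairs table
#'
#' Emits the two descendant sets as nucleotide FASTA files and the id
#' pairing as a TSV, so the full pipeline can consume simulated data
#' unchanged.
#'
#' @param pairs Output of [simulate_orf_pairs()].
#' @param fasta_a,fasta_b,pairs_tsv Output paths.
#' @return Invisibly, the three paths.
#' @export
write_pair_fasta <- function(pairs, fasta_a, fasta_b, pairs_tsv) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(pairs$nt_a, pairs$id_a)), fasta_a
  )
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(pairs$nt_b, pairs$id_b)), fasta_b
  )
  readr::write_tsv(pairs[, c("id_a", "id_b")], pairs_tsv, col_names = TRUE)
  invisible(c(fasta_a, fasta_b, pairs_tsv))
}

# align + back-translate + estimate for one simulated pair
pair_estimate <- function(nt_a, nt_b, code = genetic_code()) {
  rec_a <- list(nt = nt_a, aa = translate_cds(nt_a, code))
  rec_b <- list(nt = nt_b, aa = translate_cds(nt_b, code))
  pa <- align_pair(rec_a$aa, rec_b$aa)
  ca <- back_translate(pa, rec_a, rec_b)
  est <- estimate_selection(ca, code)
  est$identity <- pa$identity
  est
}

#' Operating characteristics of the test over a grid of conditions
#'
#' For each condition, simulates replicate pairs and runs the full
#' pipeline — align the translations, back-translate, estimate selection,
#' build the contingency table, Fisher's exact test — and reports the
#' rejection fraction at `alpha` together with estimator summaries. By
#' default no multiplicity adjustment is applied (`policy = "none"`), the
#' natural setting for measuring per-test size and power.
#'
#' @param grid A data frame with columns among `n_codons`, `gc_target`,
#'   `omega_true`, `expected_ds`, `n_pairs` (missing columns take the
#'   [simulation_spec()] defaults).
#' @param alpha Per-test significance level.
#' @param policy Threshold policy, see [adjust_alpha()].
#' @param seed Base seed; condition `i` uses `seed + i - 1`.
#' @param code A [genetic_code()].
#' @return A tibble, one row per condition: the condition columns plus
#'   `rejection_rate`, `mean_omega_hat`, `mean_ds_hat`, `n_tested`.
#' @export
operating_characteristics <- function(grid, alpha = 0.05,
                                      policy = c("none", "one-fp", "bonferroni"),
                                      seed = 1, code = genetic_code()) {
  policy <- match.arg(policy)
  if (nrow(grid) == 0L) rlang::abort("empty condition grid")
  defaults <- simulation_spec()
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    g <- as.list(grid[i, ])
    spec <- simulation_spec(
      n_codons = g$n_codons %||% defaults$n_codons,
      gc_target = g$gc_target %||% defaults$gc_target,
      omega_true = g$omega_true %||% defaults$omega_true,
      expected_ds = g$expected_ds %||% defaults$expected_ds,
      n_pairs = g$n_pairs %||% defaults$n_pairs,
      seed = seed + i - 1
    )
    pairs <- simulate_orf_pairs(spec, code)
    ests <- dplyr::bind_rows(
      purrr::map2(pairs$nt_a, pairs$nt_b, pair_estimate, code = code)
    )
    tested <- classify_pairs(ests, alpha = alpha, policy = policy)
    tibble::tibble(
      n_codons = spec$n_codons, gc_target = spec$gc_target,
      omega_true = spec$omega_true, expected_ds = spec$expected_ds,
      n_pairs = spec$n_pairs,
      rejection_rate = mean(tested$verdict == "confirmed"),
      mean_omega_hat = mean(tested$omega, na.rm = TRUE),
      mean_ds_hat = mean(tested$d_S),
      n_tested = nrow(tested)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("operating_characteristics", class(out))
  out
}
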