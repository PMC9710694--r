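#' Build the 2x2 contingency table of substituted vs non-substituted sites
#'
#' Rounds the fractional counts to integers so they are compatible with
#' Fisher's exact test: the substituted cells are `round(d_N * N_NS)` and
#' `round(d_S * N_S)`, the margins are the rounded site counts, and the
#' non-substituted cells are the differences. Rounding is
#' half-away-from-zero. Because cells and margins are rounded
#' independently, a substituted cell can in rare cases exceed its margin;
#' it is then clamped to the margin with a warning.
#'
#' @param est A one-row `selection_estimate` (from [estimate_selection()]
#'   or [parse_codeml_pairwise()]), or a list with fields `d_N`, `N_NS`,
#'   `d_S`, `N_S`; requires `N_S > 0` and `N_NS > 0`.
#' @return A list of class `contingency_table` with integer cells
#'   `ns_sub`, `ns_unsub`, `s_sub`, `s_unsub` (rows: nonsynonymous,
#'   synonymous; columns: substituted, non-substituted).
#' @examples
#' build_table(list(d_N = 0.1, N_NS = 600.7, d_S = 0.3, N_S = 200.3))
#' @export
build_table <- function(est) {
  if (is.data.frame(est)) {
    stopifnot(nrow(est) == 1L)
    est <- as.list(est)
  }
  if (est$N_S <= 0 || est$N_NS <= 0) rlang::abort("degenerate site counts")
  ns_tot <- as.integer(round_half_up(est$N_NS))
  s_tot <- as.integer(round_half_up(est$N_S))
  ns_sub <- as.integer(round_half_up(est$d_N * est$N_NS))
  s_sub <- as.integer(round_half_up(est$d_S * est$N_S))
  if (ns_sub > ns_tot) {
    rlang::warn("rounded nonsynonymous substitutions exceed rounded sites; clamping")
    ns_sub <- ns_tot
  }
  if (s_sub > s_tot) {
    rlang::warn("rounded synonymous substitutions exceed rounded sites; clamping")
    s_sub <- s_tot
  }
  structure(
    list(
      ns_sub = ns_sub, ns_unsub = ns_tot - ns_sub,
      s_sub = s_sub, s_unsub = s_tot - s_sub
    ),
    class = "contingency_table"
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact test of independence with margins fixed: the p-value is the sum of
#' hypergeometric point probabilities of every table as or less probable
#' than the observed one. Point probabilities are computed in log space via
#' `lchoose`, and "as probable" is resolved with a relative tie tolerance
#' of 1e-7 (floating-point equality of point probabilities is ill-defined).
#' A zero row or column margin carries no information and yields `p = 1`.
#'
#' @param tab A `contingency_table` from [build_table()], a list with
#'   fields `ns_sub`, `ns_unsub`, `s_sub`, `s_unsub`, or a 2x2 matrix
#'   (rows: nonsynonymous, synonymous; columns: substituted,
#'   non-substituted).
#' @return The two-sided p-value in `(0, 1]`.
#' @examples
#' fisher_exact(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
#' @export
fisher_exact <- function(tab) {
  if (is.matrix(tab)) {
    tab <- list(
      ns_sub = tab[1, 1], ns_unsub = tab[1, 2],
      s_sub = tab[2, 1], s_unsub = tab[2, 2]
    )
  }
  a <- tab$ns_sub; b <- tab$ns_unsub; cc <- tab$s_sub; d <- tab$s_unsub
  if (any(c(a, b, cc, d) < 0)) rlang::abort("negative cell in contingency table")
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  log_obs <- logp[x == a]
  keep <- logp <= log_obs + log1p(1e-7)
  min(1, sum(exp(logp[keep])))
}

#' Adjust the significance threshold for a batch of tests
#'
#' The default policy allows one expected false positive across the batch:
#' under the global null the expected number of rejections at threshold
#' `1/m` is one, so `alpha_adjusted = min(alpha, 1/m)`. Bonferroni
#' (`alpha/m`) and no adjustment are also available.
#'
#' @param m_tests Number of tests actually performed in the batch
#'   (positive integer).
#' @param alpha Nominal significance level.
#' @param policy `"one-fp"` (default), `"bonferroni"`, or `"none"`.
#' @return The adjusted threshold.
#' @export
adjust_alpha <- function(m_tests, alpha = 0.05, policy = c("one-fp", "bonferroni", "none")) {
  policy <- match.arg(policy)
  if (length(m_tests) != 1L || is.na(m_tests) || m_tests < 1) {
    rlang::abort("m_tests must be a positive integer")
  }
  switch(policy,
    "one-fp" = min(alpha, 1 / m_tests),
    "bonferroni" = alpha / m_tests,
    "none" = alpha
  )
}

#' Test a batch of selection estimates for departure from neutrality
#'
#' For each estimate: builds the 2x2 table, computes the two-sided Fisher
#' p-value, and classifies the pair against the batch-adjusted threshold.
#' `m_tests` is the number of rows supplied. Verdicts: `"confirmed"` when
#' the synonymous and nonsynonymous positions behave significantly
#' differently (`p <= alpha_adjusted`), `"dubious"` otherwise, and
#' `"insufficient"` when the pair shows no substitutions at all — the test
#' automatically filters out alignments that are too similar or too short
#' to be informative. Per-row failures (e.g. degenerate site counts) yield
#' an `NA` p-value and verdict `"insufficient"`; the batch continues.
#'
#' @param estimates A `selection_estimate` tibble (one row per pair).
#' @param alpha Nominal significance level.
#' @param policy Threshold adjustment policy, see [adjust_alpha()].
#' @return The input tibble with columns added: `ns_sub`, `ns_unsub`,
#'   `s_sub`, `s_unsub`, `p_value`, `m_tests`, `alpha_nominal`,
#'   `alpha_adjusted`, `verdict`.
#' @export
classify_pairs <- function(estimates, alpha = 0.05, policy = c("one-fp", "bonferroni", "none")) {
  policy <- match.arg(policy)
  if (nrow(estimates) == 0L) rlang::abort("no estimates to classify")
  m <- nrow(estimates)
  a_adj <- adjust_alpha(m, alpha, policy)
  per_row <- purrr::map(seq_len(m), function(i) {
    res <- tryCatch({
      tab <- build_table(as.list(estimates[i, ]))
      p <- fisher_exact(tab)
      verdict <- if (tab$ns_sub + tab$s_sub == 0L) {
        "insufficient"
      } else if (p <= a_adj) "confirmed" else "dubious"
      tibble::tibble(
        ns_sub = tab$ns_sub, ns_unsub = tab$ns_unsub,
        s_sub = tab$s_sub, s_unsub = tab$s_unsub,
        p_value = p, verdict = verdict
      )
    }, error = function(e) {
      rlang::warn(paste0("pair ", i, " not testable: ", conditionMessage(e)))
      tibble::tibble(
        ns_sub = NA_integer_, ns_unsub = NA_integer_,
        s_sub = NA_integer_, s_unsub = NA_integer_,
        p_value = NA_real_, verdict = "insufficient"
      )
    })
    res
  })
  class(estimates) <- setdiff(class(estimates), "selection_estimate")
  out <- tibble::as_tibble(dplyr::bind_cols(
    estimates,
    dplyr::bind_rows(per_row),
    tibble::tibble(
      m_tests = m, alpha_nominal = alpha, alpha_adjusted = a_adj
    )[rep(1, m), ]
  ))
  class(out) <- c("orf_tests", class(out))
  out
}
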