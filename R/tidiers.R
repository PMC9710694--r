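#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ORF validation result
#'
#' @param x An `orf_validation` from [run_validation()].
#' @param ... Unused.
#' @return The per-pair tibble (one row per tested pair).
#' @export
tidy.orf_validation <- function(x, ...) {
  tibble::as_tibble(x$pairs)
}

#' One-row summary of an ORF validation run
#'
#' @param x An `orf_validation` from [run_validation()].
#' @param ... Unused.
#' @return A one-row tibble: pair and verdict counts, `m_tests`, nominal
#'   and adjusted thresholds.
#' @export
glance.orf_validation <- function(x, ...) {
  s <- x$summary
  counts <- table(factor(
    x$pairs$verdict,
    levels = c("confirmed", "dubious", "insufficient", "filtered")
  ))
  tibble::tibble(
    n_pairs = s$n_pairs,
    n_confirmed = unname(counts[["confirmed"]]),
    n_dubious = unname(counts[["dubious"]]),
    n_insufficient = unname(counts[["insufficient"]]),
    n_filtered = unname(counts[["filtered"]]),
    m_tests = s$m_tests,
    alpha_nominal = s$alpha_nominal,
    alpha_policy = s$alpha_policy,
    alpha_adjusted = s$alpha_adjusted
  )
}

#' Tidy a batch of tested pairs
#'
#' @param x An `orf_tests` tibble from [classify_pairs()].
#' @param ... Unused.
#' @return The same data as a plain tibble.
#' @export
tidy.orf_tests <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "orf_tests")
  out
}

#' One-row summary of a tested batch
#'
#' @param x An `orf_tests` tibble from [classify_pairs()].
#' @param ... Unused.
#' @return A one-row tibble with verdict counts and thresholds.
#' @export
glance.orf_tests <- function(x, ...) {
  tibble::tibble(
    m_tests = x$m_tests[1],
    n_confirmed = sum(x$verdict == "confirmed"),
    n_dubious = sum(x$verdict == "dubious"),
    n_insufficient = sum(x$verdict == "insufficient"),
    alpha_nominal = x$alpha_nominal[1],
    alpha_adjusted = x$alpha_adjusted[1]
  )
}
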