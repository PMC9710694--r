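# Pathway-averaged substitution classification for one codon pair.
# For codons differing at k positions, all k! orderings of the single-
# nucleotide steps are enumerated; pathways passing through a stop codon are
# discarded and the synonymous/nonsynonymous step tallies averaged over the
# survivors. If every pathway is discarded, each differing position is
# classified independently against the direct single-position mutant.
codon_pair_subs <- function(c1, c2, code = genetic_code()) {
  code <- assert_genetic_code(code)
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diffs)
  if (k == 0L) return(c(s = 0, n = 0))
  b2 <- strsplit(c2, "")[[1]]
  orders <- switch(k,
    list(diffs),
    list(diffs, rev(diffs)),
    {
      p <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(p, function(ix) diffs[ix])
    }
  )
  tallies <- lapply(orders, function(ord) {
    cur <- c1
    s <- 0; n <- 0
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- b2[pos]
      if (code[[nxt]] == "*" && nxt != c2) return(NULL)  # stop intermediate
      if (code[[cur]] == code[[nxt]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s = s, n = n)
  })
  tallies <- tallies[!vapply(tallies, is.null, logical(1))]
  if (length(tallies) == 0L) {
    # fallback: classify each differing position against its direct mutant
    s <- 0; n <- 0
    for (pos in diffs) {
      m <- c1
      substr(m, pos, pos) <- b2[pos]
      if (code[[m]] != "*" && code[[m]] == code[[c1]]) s <- s + 1 else n <- n + 1
    }
    return(c(s = s, n = n))
  }
  colMeans(do.call(rbind, tallies))
}

# 61x61 lookup matrices of averaged synonymous / nonsynonymous substitution
# counts per codon pair, cached per genetic code
codon_pair_tables <- function(code = genetic_code()) {
  code <- assert_genetic_code(code)
  key <- paste0("pair_subs_", attr(code, "id"))
  if (!is.null(.orfselect_cache[[key]])) return(.orfselect_cache[[key]])
  sense <- names(code)[code != "*"]
  S <- matrix(0, length(sense), length(sense), dimnames = list(sense, sense))
  N <- S
  for (i in seq_along(sense)) {
    for (j in seq_along(sense)) {
      if (i == j) next
      sn <- codon_pair_subs(sense[i], sense[j], code)
      S[i, j] <- sn[["s"]]
      N[i, j] <- sn[["n"]]
    }
  }
  .orfselect_cache[[key]] <- list(S = S, N = N)
  .orfselect_cache[[key]]
}

#' Count sites and substitutions over a codon alignment
#'
#' Site counts (`N_S`, `N_NS`) are the average of the two sequences'
#' per-sequence fractional site counts over the retained codon columns.
#' Substitutions (`n_S`, `n_NS`) are classified per codon pair by
#' enumerating all orderings of the single-nucleotide steps between the
#' two codons, discarding pathways that pass through a stop codon, and
#' averaging the per-pathway synonymous/nonsynonymous tallies.
#'
#' @param ca A `codon_alignment` from [back_translate()] (columns
#'   `codon_a`, `codon_b`), non-empty.
#' @param code A [genetic_code()].
#' @return A list with `sites` (list `N_S`, `N_NS`) and `subs` (list
#'   `n_S`, `n_NS`).
#' @export
count_substitutions <- function(ca, code = genetic_code()) {
  code <- assert_genetic_code(code)
  if (nrow(ca) == 0L) rlang::abort("no codons to count")
  sa <- count_sites(ca$codon_a, code)
  sb <- count_sites(ca$codon_b, code)
  tabs <- codon_pair_tables(code)
  idx <- cbind(ca$codon_a, ca$codon_b)
  list(
    sites = list(N_S = (sa$N_S + sb$N_S) / 2, N_NS = (sa$N_NS + sb$N_NS) / 2),
    subs = list(n_S = sum(tabs$S[idx]), n_NS = sum(tabs$N[idx]))
  )
}

#' Estimate the selection pressure from a codon alignment
#'
#' Forms the uncorrected rates `d_N = n_NS / N_NS` and `d_S = n_S / N_S`
#' and the selection pressure `omega = d_N / d_S`. No multiple-hit
#' correction is applied: validity is confined to high-identity pairs where
#' multiple substitutions per site are improbable (see [passes_quality()]).
#' When `d_S = 0` the ratio is undefined and `omega` is `NA`.
#'
#' @inheritParams count_substitutions
#' @return A one-row tibble of class `selection_estimate`: `n_codons`,
#'   `N_S`, `N_NS`, `n_S`, `n_NS`, `d_N`, `d_S`, `omega`, `source`
#'   (`"internal"`).
#' @export
estimate_selection <- function(ca, code = genetic_code()) {
  cnt <- count_substitutions(ca, code)
  if (cnt$sites$N_S <= 0 || cnt$sites$N_NS <= 0) {
    rlang::abort("degenerate site counts (N_S or N_NS is zero)")
  }
  d_N <- cnt$subs$n_NS / cnt$sites$N_NS
  d_S <- cnt$subs$n_S / cnt$sites$N_S
  out <- tibble::tibble(
    n_codons = nrow(ca),
    N_S = cnt$sites$N_S, N_NS = cnt$sites$N_NS,
    n_S = cnt$subs$n_S, n_NS = cnt$subs$n_NS,
    d_N = d_N, d_S = d_S,
    omega = if (d_S > 0) d_N / d_S else NA_real_,
    source = "internal"
  )
  class(out) <- c("selection_estimate", class(out))
  out
}
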