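#' The genetic code
#'
#' Returns a genetic code as a named character vector mapping the 64 uppercase
#' DNA codons to amino-acid single-letter codes, with `"*"` marking stop
#' codons. Only the universal code ships with the package; the structure
#' accepts alternates (any complete 64-codon mapping) so user-supplied codes
#' can flow through every downstream function.
#'
#' @param id Code identifier. Only `"universal"` is bundled.
#' @return A named character vector of length 64 with class `genetic_code`
#'   and an `id` attribute.
#' @examples
#' code <- genetic_code()
#' code[["ATG"]]   # "M"
#' code[["TAA"]]   # "*"
#' @export
genetic_code <- function(id = "universal") {
  if (!identical(id, "universal")) {
    rlang::abort(paste0("unknown genetic code id: ", id))
  }
  bases <- c("T", "C", "A", "G")
  # TCAG-ordered translation string, the conventional table layout
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    ""
  )[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0
  )))
  code <- stats::setNames(aa, codons)
  structure(code, class = "genetic_code", id = id)
}

assert_genetic_code <- function(code) {
  if (!inherits(code, "genetic_code")) {
    if (is.character(code) && length(code) == 64 && !is.null(names(code))) {
      return(structure(code, class = "genetic_code", id = "custom"))
    }
    rlang::abort("`code` must be a genetic_code (64 named codon translations)")
  }
  code
}

#' Translate a coding nucleotide sequence
#'
#' @param nt Uppercase DNA coding sequence, length a multiple of 3.
#' @param code A [genetic_code()].
#' @return Single-letter amino-acid string; stop codons translate to `"*"`.
#' @export
translate_cds <- function(nt, code = genetic_code()) {
  code <- assert_genetic_code(code)
  vapply(nt, function(s) {
    n <- nchar(s)
    if (n %% 3L != 0L) rlang::abort("sequence length not a multiple of 3")
    if (n == 0L) return("")
    cods <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- unname(code[cods])
    if (anyNA(aa)) rlang::abort("ambiguous codon")
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

split_codons <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) rlang::abort("sequence length not a multiple of 3")
  if (n == 0L) return(character(0))
  substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Synonymous/nonsynonymous site profile of a codon
#'
#' Classifies each of the three positions of a sense codon into fractional
#' synonymous and nonsynonymous sites by the degeneracy of the genetic code:
#' the synonymous fraction at a position is the number of the three
#' single-nucleotide mutants at that position that encode the same amino acid,
#' divided by 3. Mutants that create a stop codon count as nonsynonymous
#' (they change the protein product), so the denominator is always 3.
#'
#' @param codon A sense codon (uppercase ACGT triplet).
#' @param code A [genetic_code()].
#' @return A list with `codon`, `syn_fraction_by_pos` (length 3),
#'   `syn_sites` and `nonsyn_sites` (`syn_sites + nonsyn_sites == 3`).
#' @examples
#' site_profile("TTT")$syn_sites   # 1/3: only TTC is a synonymous mutant
#' site_profile("GGG")$syn_sites   # 1: third position fully degenerate
#' site_profile("ATG")$syn_sites   # 0: Met is a single-codon family
#' @export
site_profile <- function(codon, code = genetic_code()) {
  code <- assert_genetic_code(code)
  if (!grepl("^[ACGT]{3}$", codon)) rlang::abort("ambiguous codon")
  aa <- unname(code[[codon]])
  if (aa == "*") rlang::abort("stop codon has no site profile")
  bases <- c("A", "C", "G", "T")
  frac <- vapply(1:3, function(pos) {
    orig <- substr(codon, pos, pos)
    muts <- vapply(setdiff(bases, orig), function(b) {
      m <- codon
      substr(m, pos, pos) <- b
      m
    }, character(1))
    sum(unname(code[muts]) == aa) / 3
  }, numeric(1))
  list(
    codon = codon,
    syn_fraction_by_pos = frac,
    syn_sites = sum(frac),
    nonsyn_sites = 3 - sum(frac)
  )
}

# per-codon syn_sites lookup, cached per code id
.orfselect_cache <- new.env(parent = emptyenv())

syn_sites_table <- function(code = genetic_code()) {
  code <- assert_genetic_code(code)
  key <- paste0("syn_sites_", attr(code, "id"))
  if (!is.null(.orfselect_cache[[key]])) return(.orfselect_cache[[key]])
  sense <- names(code)[code != "*"]
  tab <- vapply(sense, function(cd) site_profile(cd, code)$syn_sites, numeric(1))
  .orfselect_cache[[key]] <- tab
  tab
}

#' Count synonymous and nonsynonymous sites over a codon list
#'
#' Sums the fractional site profile over a vector of sense codons to give the
#' total synonymous (`N_S`) and nonsynonymous (`N_NS`) site counts;
#' `N_S + N_NS = 3 * length(codons)` always holds.
#'
#' @param codons Character vector of sense codons.
#' @inheritParams site_profile
#' @return A list with `N_S` and `N_NS`.
#' @export
count_sites <- function(codons, code = genetic_code()) {
  code <- assert_genetic_code(code)
  if (length(codons) == 0L) return(list(N_S = 0, N_NS = 0))
  tab <- syn_sites_table(code)
  s <- tab[codons]
  if (anyNA(s)) {
    bad <- codons[is.na(s)][1]
    if (!is.na(code[bad]) && code[bad] == "*") {
      rlang::abort("stop codon has no site profile")
    }
    rlang::abort(paste0("ambiguous codon: ", bad))
  }
  N_S <- sum(s)
  list(N_S = N_S, N_NS = 3 * length(codons) - N_S)
}
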