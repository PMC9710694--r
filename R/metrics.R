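#' G+C fraction of a nucleotide sequence
#'
#' @param nt Uppercase nucleotide string (or vector of strings).
#' @return Fraction of G and C bases in `[0, 1]`, vectorised over `nt`.
#' @examples
#' gc_fraction("ATGC")  # 0.5
#' @export
gc_fraction <- function(nt) {
  if (any(!nzchar(nt))) rlang::abort("empty sequence has no G+C fraction")
  vapply(nt, function(s) {
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Build a codon-usage table with relative adaptiveness
#'
#' Pools codon counts over all codons of all supplied ORFs and computes each
#' codon's relative adaptiveness `w`: its frequency divided by the maximum
#' frequency among its synonyms. Codons never observed receive a
#' pseudo-count of 0.5 so that `log(w)` stays finite. Stop codons never
#' enter the table.
#'
#' @param orfs A tibble from [read_orfs()] (columns `id`, `nt`), or any
#'   data frame with an `nt` column of stop-free CDSs.
#' @param code A [genetic_code()].
#' @return A tibble with class `codon_usage`: columns `codon`, `aa`,
#'   `count`, `w`. The most-used codon of every family has `w = 1`.
#' @export
build_usage <- function(orfs, code = genetic_code()) {
  code <- assert_genetic_code(code)
  if (nrow(orfs) == 0L) rlang::abort("cannot build usage from zero ORFs")
  cods <- unlist(lapply(orfs$nt, split_codons), use.names = FALSE)
  usage_from_counts(table(cods), code)
}

usage_from_counts <- function(counts, code = genetic_code()) {
  code <- assert_genetic_code(code)
  sense <- names(code)[code != "*"]
  n <- stats::setNames(numeric(length(sense)), sense)
  counts <- counts[names(counts) %in% sense]
  n[names(counts)] <- as.numeric(counts)
  n[n == 0] <- 0.5   # pseudo-count for unseen codons
  out <- tibble::tibble(codon = sense, aa = unname(code[sense]), count = unname(n)) |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(w = .data$count / max(.data$count)) |>
    dplyr::ungroup()
  class(out) <- c("codon_usage", class(out))
  out
}

#' Read a codon-usage table from a text file
#'
#' Plain text, one codon and one count per line (whitespace-separated);
#' `#` comment lines allowed. Stop codons in the file are ignored.
#'
#' @param path Path to the usage text file.
#' @inheritParams build_usage
#' @return A `codon_usage` tibble, as [build_usage()].
#' @export
read_usage_table <- function(path, code = genetic_code()) {
  if (!file.exists(path)) rlang::abort(paste0("cannot read usage table: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(parts, length, integer(1)) < 2L
  if (any(bad)) rlang::abort("malformed usage line (need codon and count)")
  cod <- toupper(vapply(parts, `[[`, character(1), 1L))
  cnt <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(cnt)) rlang::abort("non-numeric count in usage table")
  usage_from_counts(stats::setNames(cnt, cod), code)
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness `w` over the ORF's codons.
#' Codons of single-codon families (ATG/Met, TGG/Trp under the universal
#' code) are excluded from the mean, following the conventional CAI
#' definition.
#'
#' @param nt Stop-free coding nucleotide sequence (or vector of them).
#' @param usage A `codon_usage` tibble from [build_usage()] or
#'   [read_usage_table()].
#' @return CAI value(s) in `(0, 1]`.
#' @examples
#' orfs <- orfs_from_sequences("x", "ATGGGGGGA")
#' cai(orfs$nt, build_usage(orfs))
#' @export
cai <- function(nt, usage) {
  if (!inherits(usage, "codon_usage")) rlang::abort("`usage` must be a codon_usage table")
  fam_size <- stats::ave(seq_len(nrow(usage)), usage$aa, FUN = length)
  w <- stats::setNames(usage$w, usage$codon)
  multi <- stats::setNames(fam_size > 1L, usage$codon)
  vapply(nt, function(s) {
    cods <- split_codons(s)
    keep <- multi[cods]
    if (anyNA(keep)) rlang::abort("sequence contains a stop or unknown codon")
    cods <- cods[keep]
    if (length(cods) == 0L) rlang::abort("no codons usable for CAI")
    exp(mean(log(w[cods])))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample K-S test via [stats::ks.test()]. The exact p-value
#' is used when both samples are small and tie-free (the `stats` default);
#' otherwise the asymptotic formula applies, with a warning suppressed when
#' ties force the asymptotic route.
#'
#' @param x,y Numeric samples, each of size at least 2.
#' @param variable Optional label for the compared variable.
#' @return A one-row tibble: `variable`, `n_x`, `n_y`, `statistic` (D),
#'   `p_value`.
#' @export
ks_compare <- function(x, y, variable = NA_character_) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    rlang::abort("both samples must have at least 2 finite values")
  }
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided"))
  tibble::tibble(
    variable = variable, n_x = length(x), n_y = length(y),
    statistic = unname(kt$statistic), p_value = kt$p.value
  )
}
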