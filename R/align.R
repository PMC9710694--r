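blosum62 <- function() {
  if (is.null(.orfselect_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .orfselect_cache$BLOSUM62 <- e$BLOSUM62
  }
  .orfselect_cache$BLOSUM62
}

as_aa_string <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, "aa" %in% names(x))
    return(x$aa[[1]])
  }
  as.character(x)
}

#' Globally align two protein sequences
#'
#' End-to-end (Needleman-Wunsch) alignment of the two translations under a
#' fixed scoring scheme: BLOSUM62 with affine gap penalties (opening 10,
#' extension 0.5, end gaps penalised). The scheme and the dynamic-programming
#' traceback are fixed, so results are deterministic for fixed inputs.
#'
#' @param a,b One-row ORF tibbles (from [read_orfs()]) or plain amino-acid
#'   strings. Translations must be non-empty.
#' @return A list of class `protein_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, and `identity` — the fraction
#'   of identical residue pairs over aligned (non-gap) columns, not over
#'   the full alignment length.
#' @examples
#' align_pair("MAAG", "MAG")$identity
#' @export
align_pair <- function(a, b) {
  aa_a <- as_aa_string(a)
  aa_b <- as_aa_string(b)
  if (!nzchar(aa_a) || !nzchar(aa_b)) rlang::abort("empty translation")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa_a), Biostrings::AAString(aa_b),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5
  )
  ga <- as.character(Biostrings::alignedPattern(al))
  gb <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  paired <- ca != "-" & cb != "-"
  structure(
    list(
      aligned_a = ga, aligned_b = gb,
      score = Biostrings::score(al),
      identity = if (any(paired)) mean(ca[paired] == cb[paired]) else 0
    ),
    class = "protein_alignment"
  )
}

#' Back-translate a protein alignment to paired codon columns
#'
#' Maps each residue column of the protein alignment back to its source
#' codon in the two coding sequences. Columns where either side is a gap,
#' or where either codon contains an ambiguous base, are excluded.
#'
#' @param pa A `protein_alignment` from [align_pair()].
#' @param a,b The one-row ORF tibbles (or lists with `nt`, `aa`) the
#'   alignment was computed from.
#' @return A tibble of class `codon_alignment` with columns `column`
#'   (protein-alignment column index), `codon_a`, `codon_b`; the number of
#'   retained columns is `nrow()`.
#' @export
back_translate <- function(pa, a, b) {
  stopifnot(inherits(pa, "protein_alignment"))
  nt_a <- if (is.data.frame(a)) a$nt[[1]] else a$nt
  nt_b <- if (is.data.frame(b)) b$nt[[1]] else b$nt
  ga <- strsplit(pa$aligned_a, "")[[1]]
  gb <- strsplit(pa$aligned_b, "")[[1]]
  if (paste(ga[ga != "-"], collapse = "") != translate_cds(nt_a) ||
      paste(gb[gb != "-"], collapse = "") != translate_cds(nt_b)) {
    rlang::abort("alignment is inconsistent with the supplied records")
  }
  cods_a <- split_codons(nt_a)
  cods_b <- split_codons(nt_b)
  ia <- cumsum(ga != "-")
  ib <- cumsum(gb != "-")
  keep <- ga != "-" & gb != "-"
  out <- tibble::tibble(
    column = which(keep),
    codon_a = cods_a[ia[keep]],
    codon_b = cods_b[ib[keep]]
  )
  ok <- !grepl("[^ACGT]", out$codon_a) & !grepl("[^ACGT]", out$codon_b)
  out <- out[ok, ]
  class(out) <- c("codon_alignment", class(out))
  out
}

#' Alignment quality filter
#'
#' The validity regime of the uncorrected selection-pressure estimate:
#' a pair passes when protein identity exceeds `min_identity` (default 70%)
#' and the synonymous rate `d_S` stays below `max_ds` (default 1), keeping
#' multiple substitutions per site improbable. When identity is unknown
#' (CODEML-output mode) only the `d_S` rule applies.
#'
#' @param identity Fraction of identical residues over aligned columns
#'   (`NA` when not available).
#' @param d_s Synonymous substitution rate of the pair.
#' @param min_identity,max_ds Filter thresholds.
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   violated rules, empty when passing).
#' @export
passes_quality <- function(identity, d_s, min_identity = 0.70, max_ds = 1.0) {
  reasons <- character(0)
  if (!is.na(identity) && identity <= min_identity) {
    reasons <- c(reasons, sprintf("identity <= %.2f", min_identity))
  }
  if (!is.na(d_s) && d_s >= max_ds) {
    reasons <- c(reasons, sprintf("d_S >= %g", max_ds))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Reciprocal-best-hit ortholog pairing
#'
#' Pairs each sequence of proteome A with its best-scoring global-alignment
#' partner in proteome B, keeping a pair only when the choice is mutual.
#' Ranking uses the alignment score (identity is length-confounded); score
#' ties break towards the lexicographically smaller partner id.
#'
#' @param orfs_a,orfs_b ORF tibbles from [read_orfs()].
#' @return A tibble with columns `id_a`, `id_b`, `score`.
#' @export
reciprocal_best_pairs <- function(orfs_a, orfs_b) {
  if (nrow(orfs_a) == 0L || nrow(orfs_b) == 0L) rlang::abort("empty proteome")
  set_a <- Biostrings::AAStringSet(stats::setNames(orfs_a$aa, orfs_a$id))
  set_b <- Biostrings::AAStringSet(stats::setNames(orfs_b$aa, orfs_b$id))
  scores <- vapply(seq_along(set_a), function(i) {
    Biostrings::pairwiseAlignment(
      set_b, set_a[[i]], type = "global",
      substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
      scoreOnly = TRUE
    )
  }, numeric(length(set_b)))
  scores <- matrix(scores, nrow = length(set_b))  # rows: B, cols: A
  best_of <- function(v, ids) {
    top <- which(v == max(v))
    top[order(ids[top])][1]
  }
  best_b_for_a <- vapply(seq_len(ncol(scores)), function(j) best_of(scores[, j], orfs_b$id), integer(1))
  best_a_for_b <- vapply(seq_len(nrow(scores)), function(i) best_of(scores[i, ], orfs_a$id), integer(1))
  keep <- which(best_a_for_b[best_b_for_a] == seq_len(ncol(scores)))
  tibble::tibble(
    id_a = orfs_a$id[keep],
    id_b = orfs_b$id[best_b_for_a[keep]],
    score = scores[cbind(best_b_for_a[keep], keep)]
  ) |>
    dplyr::arrange(.data$id_a)
}
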