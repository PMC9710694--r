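#' Load predicted ORFs from a nucleotide FASTA file
#'
#' Reads coding nucleotide sequences (CDS/ORFs) and returns one row per valid
#' record. A terminal stop codon is stripped if present. Records that are not
#' a multiple of 3 long, contain an internal stop codon, or contain ambiguous
#' bases are rejected with a reason, never silently dropped: the rejected
#' records are reported via [message()] and attached as the `"skipped"`
#' attribute (a tibble with columns `id`, `reason`).
#'
#' @param path Path to a FASTA file of nucleotide CDSs.
#' @param code A [genetic_code()].
#' @return A tibble with columns `id`, `nt` (coding sequence, terminal stop
#'   stripped), `aa` (translation), `length_aa`, `gc` (G+C fraction).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">orf1", "ATGGGGTAA"), fa)
#' read_orfs(fa)
#' @export
read_orfs <- function(path, code = genetic_code()) {
  code <- assert_genetic_code(code)
  if (!file.exists(path)) rlang::abort(paste0("cannot read FASTA file: ", path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) rlang::abort(paste0("no sequences in ", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  orfs_from_sequences(ids, seqs, code = code)
}

#' Build an ORF table from in-memory sequences
#'
#' Same validation and stop-stripping rules as [read_orfs()], for sequences
#' already in memory (e.g. simulator output).
#'
#' @param ids Character vector of sequence identifiers.
#' @param seqs Character vector of uppercase nucleotide coding sequences.
#' @inheritParams read_orfs
#' @return A tibble as in [read_orfs()].
#' @export
orfs_from_sequences <- function(ids, seqs, code = genetic_code()) {
  code <- assert_genetic_code(code)
  stopifnot(length(ids) == length(seqs))
  rows <- purrr::map2(ids, seqs, function(id, nt) {
    if (nchar(nt) %% 3L != 0L) {
      return(list(skip = tibble::tibble(id = id, reason = "length not a multiple of 3")))
    }
    if (nchar(nt) == 0L) {
      return(list(skip = tibble::tibble(id = id, reason = "empty sequence")))
    }
    if (grepl("[^ACGT]", nt)) {
      return(list(skip = tibble::tibble(id = id, reason = "ambiguous bases")))
    }
    cods <- split_codons(nt)
    aa <- unname(code[cods])
    # strip one terminal stop codon
    if (aa[length(aa)] == "*") {
      cods <- cods[-length(cods)]
      aa <- aa[-length(aa)]
      nt <- paste(cods, collapse = "")
    }
    if (length(cods) == 0L) {
      return(list(skip = tibble::tibble(id = id, reason = "empty after stop stripping")))
    }
    if (any(aa == "*")) {
      return(list(skip = tibble::tibble(id = id, reason = "internal stop codon")))
    }
    list(orf = tibble::tibble(
      id = id, nt = nt, aa = paste(aa, collapse = ""),
      length_aa = length(cods), gc = gc_fraction(nt)
    ))
  })
  skipped <- dplyr::bind_rows(purrr::map(rows, "skip"))
  orfs <- dplyr::bind_rows(purrr::map(rows, "orf"))
  if (nrow(skipped) > 0L) {
    for (i in seq_len(nrow(skipped))) {
      message("skipping ", skipped$id[i], ": ", skipped$reason[i])
    }
  }
  if (nrow(orfs) == 0L) {
    orfs <- tibble::tibble(
      id = character(), nt = character(), aa = character(),
      length_aa = integer(), gc = numeric()
    )
  }
  attr(orfs, "skipped") <- skipped
  orfs
}

#' Read an ortholog pairs table
#'
#' Tab-separated file with two columns `id_a`, `id_b`; lines starting with
#' `#` are ignored. A header line is optional (detected when the first line
#' is literally `id_a<TAB>id_b`).
#'
#' @param path Path to the TSV pairs file.
#' @return A tibble with columns `id_a`, `id_b`.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("cannot read pairs file: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) > 0L && identical(trimws(lines[1]), "id_a\tid_b")) {
    lines <- lines[-1]
  }
  if (length(lines) == 0L) rlang::abort("no pairs in file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 2L
  if (any(bad)) rlang::abort("malformed pairs line (need two tab-separated ids)")
  tibble::tibble(
    id_a = vapply(parts, `[[`, character(1), 1L),
    id_b = vapply(parts, `[[`, character(1), 2L)
  )
}
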