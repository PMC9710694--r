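#' Parse CODEML pairwise-mode output
#'
#' Post-processes the main output of CODEML run in pairwise mode
#' (`runmode = -2`, `seqtype = 1`): for every compared pair it extracts the
#' summary line
#' `t= ...  S= ...  N= ...  dN/dS= ...  dN = ...  dS = ...`
#' together with the preceding pair header
#' `i (name_a) ... j (name_b)`. CODEML's `S` and `N` map to the synonymous
#' and nonsynonymous site counts `N_S` and `N_NS`; substitution counts are
#' reconstructed as `n_S = d_S * N_S` and `n_NS = d_N * N_NS`. CODEML is
#' never executed; only its output text is consumed.
#'
#' @param x Path to a CODEML main output file, or the output text itself
#'   (a single string or a character vector of lines).
#' @return A tibble of class `selection_estimate`, one row per pair in file
#'   order: `id_a`, `id_b`, `t`, `N_S`, `N_NS`, `n_S`, `n_NS`, `d_N`,
#'   `d_S`, `omega`, `source` (`"codeml"`).
#' @export
parse_codeml_pairwise <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) {
    readLines(x)
  } else if (length(x) == 1L) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
  head_re <- "^\\s*\\d+\\s*\\((\\S+)\\)\\s*\\.\\.\\.\\s*\\d+\\s*\\((\\S+)\\)"
  stat_re <- paste0(
    "t\\s*=\\s*(\\S+)\\s+S\\s*=\\s*(\\S+)\\s+N\\s*=\\s*(\\S+)\\s+",
    "dN/dS\\s*=\\s*(\\S+)\\s+dN\\s*=\\s*(\\S+)\\s+dS\\s*=\\s*(\\S+)"
  )
  heads <- grep(head_re, lines)
  stats_ln <- grep(stat_re, lines)
  if (length(heads) == 0L || length(stats_ln) == 0L) {
    rlang::abort("not a pairwise CODEML output (no pair blocks found)")
  }
  rows <- purrr::map(heads, function(h) {
    s <- stats_ln[stats_ln > h]
    if (length(s) == 0L) return(NULL)
    s <- s[1]
    hm <- regmatches(lines[h], regexec(head_re, lines[h]))[[1]]
    sm <- regmatches(lines[s], regexec(stat_re, lines[s]))[[1]]
    num <- suppressWarnings(as.numeric(sm[2:7]))
    if (anyNA(num)) {
      rlang::abort(paste0("malformed numeric field in line: ", trimws(lines[s])))
    }
    # header order is "2 (b) ... 1 (a)"; keep ids in file (b, a) order
    tibble::tibble(
      id_a = hm[2], id_b = hm[3],
      t = num[1], N_S = num[2], N_NS = num[3],
      omega = num[4], d_N = num[5], d_S = num[6]
    )
  })
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows) == 0L) rlang::abort("not a pairwise CODEML output (no pair blocks found)")
  out <- rows |>
    dplyr::mutate(
      n_S = .data$d_S * .data$N_S,
      n_NS = .data$d_N * .data$N_NS,
      n_codons = NA_integer_,
      source = "codeml"
    ) |>
    dplyr::select(
      "id_a", "id_b", "t", "n_codons", "N_S", "N_NS", "n_S", "n_NS",
      "d_N", "d_S", "omega", "source"
    )
  class(out) <- c("selection_estimate", class(out))
  out
}

#' Write a CODEML-style pairwise block (for fixtures and round-trips)
#'
#' Renders estimates in the pairwise summary dialect that
#' [parse_codeml_pairwise()] consumes. Used to build synthetic fixtures;
#' this is not CODEML output.
#'
#' @param est A tibble with columns `id_a`, `id_b`, `t`, `N_S`, `N_NS`,
#'   `d_N`, `d_S`, `omega`.
#' @return Character vector of output lines.
#' @export
format_codeml_pairwise <- function(est) {
  unlist(purrr::pmap(est, function(id_a, id_b, t, N_S, N_NS, d_N, d_S, omega, ...) {
    c(
      sprintf("2 (%s) ... 1 (%s)", id_a, id_b),
      sprintf(
        "t=%7.4f  S=%9.1f  N=%9.1f  dN/dS=%9.4f  dN =%9.4f  dS =%9.4f",
        t, N_S, N_NS, omega, d_N, d_S
      ),
      ""
    )
  }))
}
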