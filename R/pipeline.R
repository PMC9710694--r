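REPORT_COLUMNS <- c(
  "id_a", "id_b", "identity", "n_codons", "N_S", "N_NS", "n_S", "n_NS",
  "d_N", "d_S", "omega", "ns_sub", "ns_unsub", "s_sub", "s_unsub",
  "p_value", "alpha_adjusted", "verdict", "quality_pass", "quality_reasons",
  "cai_a", "cai_b", "gc_a", "gc_b", "length_a", "length_b", "estimate_source"
)
REPORT_VERSION <- "orfselect-report-v1"

#' Run the full ORF-validation pipeline
#'
#' Orchestrates the whole procedure over a batch of homologous ORF pairs:
#' load the coding sequences, pair them (a supplied pairs table or
#' reciprocal best hits), align each pair at the protein level,
#' back-translate to codons, estimate `d_N`, `d_S` and `omega`, apply the
#' alignment-quality filter, run Fisher's exact test on the 2x2 table of
#' substituted vs non-substituted positions, and annotate each pair with
#' CAI, G+C and length. Alternatively, post-process CODEML pairwise output
#' (`codeml =`) instead of aligning internally.
#'
#' Pairs failing the quality filter get verdict `"filtered"` and are
#' excluded from the test count `m_tests`, so the threshold adjustment
#' reflects tests actually performed.
#'
#' @param fasta_a,fasta_b Nucleotide FASTA files of the two ORF sets
#'   (omit when `codeml` is given).
#' @param pairs Optional pairs TSV path or tibble with `id_a`, `id_b`;
#'   default is reciprocal-best-hit pairing.
#' @param codeml Optional CODEML pairwise output path (or text); mutually
#'   exclusive with `fasta_a`/`fasta_b` alignment mode. `metrics_fasta`
#'   FASTA file(s) may supply sequences for CAI/GC/length annotation.
#' @param metrics_fasta Optional character vector of FASTA paths used only
#'   for annotation in CODEML mode.
#' @param alpha Nominal significance level.
#' @param alpha_policy Threshold adjustment, see [adjust_alpha()].
#' @param min_identity,max_ds Quality-filter thresholds
#'   (see [passes_quality()]).
#' @param usage Optional `codon_usage` table or path to one
#'   ([read_usage_table()] format); default builds usage from each input
#'   CDS set itself.
#' @param code A [genetic_code()].
#' @return An object of class `orf_validation`: a list with `pairs` (one
#'   tibble row per tested pair), `populations` (K-S comparisons between
#'   confirmed and dubious groups), and `summary` (verdict counts, m_tests,
#'   thresholds).
#' @export
run_validation <- function(fasta_a = NULL, fasta_b = NULL, pairs = NULL,
                           codeml = NULL, metrics_fasta = NULL,
                           alpha = 0.05,
                           alpha_policy = c("one-fp", "bonferroni", "none"),
                           min_identity = 0.70, max_ds = 1.0,
                           usage = NULL, code = genetic_code()) {
  alpha_policy <- match.arg(alpha_policy)
  fasta_mode <- !is.null(fasta_a) || !is.null(fasta_b)
  if (fasta_mode && !is.null(codeml)) {
    rlang::abort("supply either FASTA inputs or CODEML output, not both")
  }
  if (!fasta_mode && is.null(codeml)) {
    rlang::abort("no input: supply fasta_a/fasta_b or codeml")
  }

  if (fasta_mode) {
    orfs_a <- read_orfs(fasta_a, code)
    orfs_b <- read_orfs(fasta_b, code)
    if (is.null(pairs)) {
      pairs <- reciprocal_best_pairs(orfs_a, orfs_b)[, c("id_a", "id_b")]
    } else if (is.character(pairs)) {
      pairs <- read_pairs(pairs)
    }
    pairs <- dplyr::filter(pairs, .data$id_a %in% orfs_a$id, .data$id_b %in% orfs_b$id)
    if (nrow(pairs) == 0L) rlang::abort("zero testable pairs (no valid paired ORFs)")
    usage_a <- resolve_usage(usage, orfs_a, code)
    usage_b <- resolve_usage(usage, orfs_b, code)
    ests <- purrr::map2(pairs$id_a, pairs$id_b, function(ia, ib) {
      a <- orfs_a[orfs_a$id == ia, ][1, ]
      b <- orfs_b[orfs_b$id == ib, ][1, ]
      pa <- align_pair(a, b)
      ca <- back_translate(pa, a, b)
      est <- tryCatch(estimate_selection(ca, code), error = function(e) NULL)
      if (is.null(est)) return(NULL)
      est |>
        dplyr::mutate(
          id_a = ia, id_b = ib, identity = pa$identity,
          cai_a = cai(a$nt, usage_a), cai_b = cai(b$nt, usage_b),
          gc_a = a$gc, gc_b = b$gc,
          length_a = a$length_aa, length_b = b$length_aa
        )
    })
    ests <- dplyr::bind_rows(ests)
  } else {
    ests <- parse_codeml_pairwise(codeml)
    ests$identity <- NA_real_
    ann <- NULL
    if (!is.null(metrics_fasta)) {
      ann <- dplyr::bind_rows(lapply(metrics_fasta, read_orfs, code = code))
      usage_m <- resolve_usage(usage, ann, code)
      ann <- ann |>
        dplyr::mutate(cai = cai(.data$nt, usage_m)) |>
        dplyr::select("id", "cai", "gc", length = "length_aa")
    }
    ests <- annotate_from(ests, ann)
  }
  if (nrow(ests) == 0L) rlang::abort("zero testable pairs (all estimates failed)")

  qc <- purrr::map2(ests$identity, ests$d_S, passes_quality,
                    min_identity = min_identity, max_ds = max_ds)
  ests$quality_pass <- purrr::map_lgl(qc, "pass")
  ests$quality_reasons <- purrr::map_chr(qc, function(q) paste(q$reasons, collapse = "; "))

  testable <- ests[ests$quality_pass, ]
  filtered <- ests[!ests$quality_pass, ]
  if (nrow(testable) > 0L) {
    tested <- classify_pairs(testable, alpha = alpha, policy = alpha_policy)
  } else {
    rlang::abort("zero testable pairs (all filtered by quality rules)")
  }
  if (nrow(filtered) > 0L) {
    filtered$verdict <- "filtered"
    filtered$p_value <- NA_real_
    filtered$m_tests <- nrow(testable)
    filtered$alpha_nominal <- alpha
    filtered$alpha_adjusted <- unique(tested$alpha_adjusted)[1]
    filtered$ns_sub <- NA_integer_; filtered$ns_unsub <- NA_integer_
    filtered$s_sub <- NA_integer_; filtered$s_unsub <- NA_integer_
  }
  rows <- dplyr::bind_rows(tested, filtered)
  rows$estimate_source <- rows$source
  for (col in REPORT_COLUMNS) if (!col %in% names(rows)) rows[[col]] <- NA
  rows <- rows |>
    dplyr::select(dplyr::all_of(REPORT_COLUMNS)) |>
    dplyr::arrange(match(paste(.data$id_a, .data$id_b),
                         paste(ests$id_a, ests$id_b)))

  populations <- summarize_populations(rows)
  summary <- list(
    n_pairs = nrow(rows),
    verdict_counts = as.list(table(rows$verdict)),
    m_tests = nrow(testable),
    alpha_nominal = alpha,
    alpha_policy = alpha_policy,
    alpha_adjusted = unique(tested$alpha_adjusted)[1],
    report_version = REPORT_VERSION
  )
  structure(
    list(pairs = rows, populations = populations, summary = summary),
    class = "orf_validation"
  )
}

resolve_usage <- function(usage, orfs, code) {
  if (is.null(usage)) return(build_usage(orfs, code))
  if (is.character(usage)) return(read_usage_table(usage, code))
  stopifnot(inherits(usage, "codon_usage"))
  usage
}

annotate_from <- function(ests, ann) {
  if (is.null(ann)) {
    ests$cai_a <- NA_real_; ests$cai_b <- NA_real_
    ests$gc_a <- NA_real_; ests$gc_b <- NA_real_
    ests$length_a <- NA_integer_; ests$length_b <- NA_integer_
    return(ests)
  }
  ests |>
    dplyr::left_join(
      dplyr::rename(ann, id_a = "id", cai_a = "cai", gc_a = "gc", length_a = "length"),
      by = "id_a"
    ) |>
    dplyr::left_join(
      dplyr::rename(ann, id_b = "id", cai_b = "cai", gc_b = "gc", length_b = "length"),
      by = "id_b"
    )
}

#' Compare confirmed vs dubious pair populations
#'
#' Two-sample Kolmogorov-Smirnov comparisons of the `confirmed` and
#' `dubious` verdict groups on omega, length, CAI and G+C (per pair:
#' length/CAI/GC are the mean of the two ORFs). Groups with fewer than two
#' usable values are skipped with a notice row (`NA` statistic).
#'
#' @param rows The `pairs` tibble of an `orf_validation` (or any tibble
#'   with `verdict`, `omega`, `length_a/b`, `cai_a/b`, `gc_a/b`).
#' @return A tibble: one row per variable with group means, SDs, K-S
#'   statistic and p-value.
#' @export
summarize_populations <- function(rows) {
  vars <- list(
    omega = rows$omega,
    length = (rows$length_a + rows$length_b) / 2,
    cai = (rows$cai_a + rows$cai_b) / 2,
    gc = (rows$gc_a + rows$gc_b) / 2
  )
  conf <- rows$verdict == "confirmed"
  dub <- rows$verdict == "dubious"
  purrr::imap(vars, function(v, nm) {
    x <- v[conf]; x <- x[is.finite(x)]
    y <- v[dub]; y <- y[is.finite(y)]
    base <- tibble::tibble(
      variable = nm,
      n_confirmed = length(x), n_dubious = length(y),
      mean_confirmed = if (length(x)) mean(x) else NA_real_,
      sd_confirmed = if (length(x) > 1) stats::sd(x) else NA_real_,
      mean_dubious = if (length(y)) mean(y) else NA_real_,
      sd_dubious = if (length(y) > 1) stats::sd(y) else NA_real_
    )
    if (length(x) < 2L || length(y) < 2L) {
      base$statistic <- NA_real_
      base$p_value <- NA_real_
      base$note <- "skipped: group smaller than 2"
    } else {
      ks <- ks_compare(x, y, nm)
      base$statistic <- ks$statistic
      base$p_value <- ks$p_value
      base$note <- ""
    }
    base
  }) |>
    dplyr::bind_rows()
}

#' Write the validation report
#'
#' Emits the per-pair table as TSV (fixed, versioned column set) and the
#' run summary as JSON. Byte-stable for identical inputs: row order is
#' input order and all numeric formatting is fixed.
#'
#' @param x An `orf_validation` from [run_validation()].
#' @param tsv Output path for the per-pair TSV report.
#' @param json Optional output path for the JSON run summary.
#' @return Invisibly, `x`.
#' @export
write_report <- function(x, tsv, json = NULL) {
  stopifnot(inherits(x, "orf_validation"))
  readr::write_tsv(x$pairs, tsv)
  if (!is.null(json)) {
    jsonlite::write_json(x$summary, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(x)
}

#' @export
print.orf_validation <- function(x, ...) {
  cat("ORF validation:", x$summary$n_pairs, "pairs,",
      "m_tests =", x$summary$m_tests,
      sprintf("(alpha %.3g, policy %s, adjusted %.3g)\n",
              x$summary$alpha_nominal, x$summary$alpha_policy,
              x$summary$alpha_adjusted))
  counts <- x$summary$verdict_counts
  cat("verdicts:", paste(names(counts), unlist(counts), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
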