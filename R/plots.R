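#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ORF validation result
#'
#' Selection pressure per pair, coloured by verdict: confirmed pairs
#' (synonymous and nonsynonymous positions behave significantly
#' differently) against dubious ones (omega not significantly different
#' from 1), with filtered and insufficient pairs shown hollow.
#'
#' @param object An `orf_validation` from [run_validation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.orf_validation <- function(object, ...) {
  df <- object$pairs
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$omega,
                                   colour = .data$verdict)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$verdict %in% c("filtered", "insufficient"))) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1), guide = "none") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "pair", y = expression(omega == d[N] / d[S]),
                  colour = "verdict") +
    ggplot2::theme_minimal()
}

#' Plot operating characteristics
#'
#' Rejection rate against sequence length, one line per true omega, at the
#' simulated divergence. The dashed line marks the nominal level.
#'
#' @param object An `operating_characteristics` tibble.
#' @param alpha Nominal level to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.operating_characteristics <- function(object, alpha = 0.05, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_codons, y = .data$rejection_rate,
                                       colour = factor(.data$omega_true))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::labs(x = "ORF length (codons)", y = "rejection rate",
                  colour = expression(omega["true"])) +
    ggplot2::theme_minimal()
}
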