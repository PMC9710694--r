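# round-half-away-from-zero; stats::round() rounds half to even
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
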