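# Independent oracles, written without reference to the package internals.

UNIVERSAL <- genetic_code()
SENSE_CODONS <- names(UNIVERSAL)[UNIVERSAL != "*"]

# site profile by direct enumeration of the 9 single-nucleotide mutants
oracle_site_profile <- function(codon) {
  aa <- UNIVERSAL[[codon]]
  syn <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      m <- codon
      substr(m, pos, pos) <- b
      if (UNIVERSAL[[m]] == aa) syn <- syn + 1 / 3
    }
  }
  syn
}

# substitution classification by recursive pathway enumeration: from c1,
# change one differing position at a time until c2 is reached, pruning
# branches that visit a stop codon, then average tallies over complete paths
oracle_pair_subs <- function(c1, c2) {
  paths <- list()
  walk <- function(cur, s, n) {
    if (cur == c2) {
      paths[[length(paths) + 1L]] <<- c(s, n)
      return(invisible())
    }
    for (pos in 1:3) {
      if (substr(cur, pos, pos) == substr(c2, pos, pos)) next
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (UNIVERSAL[[nxt]] == "*") next
      if (UNIVERSAL[[nxt]] == UNIVERSAL[[cur]]) walk(nxt, s + 1, n) else walk(nxt, s, n + 1)
    }
  }
  walk(c1, 0, 0)
  if (length(paths) == 0L) {
    # every pathway blocked by a stop: classify each position directly
    s <- 0; n <- 0
    for (pos in 1:3) {
      if (substr(c1, pos, pos) == substr(c2, pos, pos)) next
      m <- c1
      substr(m, pos, pos) <- substr(c2, pos, pos)
      if (UNIVERSAL[[m]] != "*" && UNIVERSAL[[m]] == UNIVERSAL[[c1]]) s <- s + 1 else n <- n + 1
    }
    return(c(s, n))
  }
  colMeans(do.call(rbind, paths))
}

# two-sided Fisher p by hypergeometric enumeration with stats::dhyper
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  p <- stats::dhyper(x, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# affine-gap global alignment score (Gotoh), gap of length L costs
# open + L * ext, end gaps penalised
oracle_align_score <- function(a, b, mat, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a (b consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext, Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext, X[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# random stop-free CDS of n codons
random_cds <- function(n_codons) {
  cods <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  paste(cods, collapse = "")
}

split_codons_chr <- function(nt) {
  substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
}

random_protein <- function(n) {
  paste(sample(setdiff(unique(UNIVERSAL), "*"), n, replace = TRUE), collapse = "")
}
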