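# orfselect

Validation of predicted proteins by selection-pressure testing.

Genome annotation of newly sequenced microbes — giant viruses in
particular — produces predicted proteins that may not exist: stop-free
open reading frames (ORFs) conserved by chance between close genomes,
especially among "ORFans" with no homolog outside their clade. For a pair
of homologous coding sequences, a real protein leaves a signature: its
nonsynonymous positions diverge more slowly than its synonymous ones. The
classical summary is the selection pressure

    omega = dN / dS,   dN = n_NS / N_NS,   dS = n_S / N_S

with N_S, N_NS the synonymous/nonsynonymous site counts and n_S, n_NS the
substitutions observed at each site type. But omega is a ratio of two
small numbers and, on its own, carries no significance statement. orfselect
turns the four counts into a 2×2 contingency table (substituted vs
non-substituted positions, by position type) and applies Fisher's exact
test: a pair whose position types behave significantly differently is
**confirmed**; one compatible with uniform drift (omega ≈ 1) is
**dubious** — a candidate spurious prediction or pseudogene. The
significance threshold is adjusted across the batch to allow one expected
false positive (alpha_adj = min(alpha, 1/m)).

The package implements the full procedure: fractional synonymous site
classification by codon degeneracy, global protein alignment with
codon-wise back-translation, pathway-averaged substitution counting, the
exact test, an alignment-quality filter (identity > 70%, dS < 1), CAI /
G+C / length annotation with Kolmogorov–Smirnov comparisons between
verdict groups, a parser for CODEML pairwise output as an alternative
estimate source, and a codon-evolution simulator for measuring the test's
type-I error and power. See the methods vignette
(`vignettes/orf-validation-methods.Rmd`) for the model and its
assumptions.

## Worked example

Simulate 20 homologous ORF pairs evolved under strong purifying selection
(true omega 0.2, 200 codons, pairwise dS ≈ 0.3), then run the full
pipeline on the emitted FASTA files:

```r
library(orfselect)

spec <- simulation_spec(n_codons = 200, omega_true = 0.2, expected_ds = 0.3,
                        n_pairs = 20, seed = 42)
pairs <- simulate_orf_pairs(spec)
write_pair_fasta(pairs, "a.fasta", "b.fasta", "pairs.tsv")

v <- run_validation("a.fasta", "b.fasta", pairs = "pairs.tsv",
                    alpha = 0.05, alpha_policy = "one-fp")
v
#> ORF validation: 20 pairs, m_tests = 20 (alpha 0.05, policy one-fp, adjusted 0.05)
#> verdicts: confirmed=20

as.data.frame(tidy(v)[1:3, c("id_a", "identity", "d_N", "d_S", "omega", "p_value", "verdict")])
#>        id_a identity        d_N       d_S     omega      p_value   verdict
#> 1 sim0001_a    0.890 0.04943820 0.2645161 0.1869005 3.455995e-12 confirmed
#> 2 sim0002_a    0.890 0.05534639 0.2701271 0.2048901 6.591716e-12 confirmed
#> 3 sim0003_a    0.885 0.05681818 0.2687500 0.2114165 1.434104e-11 confirmed
```

Each row is one pair of homologous ORFs: `identity` is the protein-level
identity of the alignment, `d_N`/`d_S` the substitution rates at the two
position types, `omega` their ratio, and `p_value` the two-sided Fisher
probability that the two position types behave alike. All 20 pairs here
are confirmed — correctly, since they were simulated under selection; a
neutral batch (`omega_true = 1`) yields mostly `dubious` verdicts instead.
`write_report(v, "report.tsv", "summary.json")` emits the per-pair table
and run summary; `autoplot(v)` plots omega per pair coloured by verdict.

To post-process CODEML pairwise output instead of aligning internally:

```r
v <- run_validation(codeml = "codeml_output.txt")
```

A command-line wrapper with subcommands `pair`, `run`, `from-codeml`,
`simulate`, `calibrate` and `compare` is installed under
`inst/cli/orfselect`.

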