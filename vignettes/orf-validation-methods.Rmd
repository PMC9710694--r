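---
title: "Validating predicted proteins with a significance test on dN/dS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating predicted proteins with a significance test on dN/dS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(orfselect)
library(dplyr)
```

## The problem

Genome annotation of newly sequenced microbes — giant viruses especially —
produces many predicted proteins whose existence cannot be confirmed by
homology: the "ORFans". A last-resort computational validation compares each
predicted open reading frame (ORF) with a homolog from a close relative and
asks whether its coding sequence shows the signature of protein-level
selection. For a real protein, amino-acid-changing (nonsynonymous) positions
diverge more slowly than silent (synonymous) ones; for a spurious ORF the
distinction between the two position types is biologically meaningless, so
both types drift at the same rate.

The classical summary of this signature is the selection pressure

$$\omega = \frac{d_N}{d_S}, \qquad
  d_N = \frac{n_{NS}}{N_{NS}}, \qquad
  d_S = \frac{n_S}{N_S},$$

where $N_S$ and $N_{NS}$ are the numbers of synonymous and nonsynonymous
sites of the aligned coding sequences, and $n_S$, $n_{NS}$ the substitutions
observed at each site type. The difficulty is that $\omega$ is a ratio of
two small numbers: with the short, highly similar alignments the method
requires, a point estimate of, say, $\omega = 0.4$ may or may not be
distinguishable from 1. orfselect therefore attaches a significance test to
every pair: the four quantities are cast into a 2×2 contingency table of
substituted versus non-substituted positions,

| position type | substituted | non-substituted |
|---|---|---|
| nonsynonymous | $n_{NS}$ | $N_{NS} - n_{NS}$ |
| synonymous | $n_S$ | $N_S - n_S$ |

and Fisher's exact test asks whether the two position types behave
differently. A significant pair is *confirmed* (the ORF behaves like a
protein-coding gene, whatever the direction of selection); a nonsignificant
one is *dubious* — compatible with a spurious prediction or a
pseudogenizing gene.

## The procedure step by step

1. **Site classification.** Each codon position is classified fractionally
   by the degeneracy of the genetic code: the synonymous fraction at a
   position is the number of its three single-nucleotide mutants that
   preserve the amino acid, divided by 3 (the Nei–Gojobori counting
   convention). Mutants creating a stop codon count as nonsynonymous — they
   certainly change the product — and the denominator stays 3. Sites sum to
   $N_S + N_{NS} = 3L$ exactly for $L$ codons.
2. **Alignment.** The two translations are aligned end-to-end
   (Needleman–Wunsch, BLOSUM62, affine gaps: opening 10, extension 0.5,
   end gaps penalised), then back-translated codon-wise. Columns with a gap
   or an ambiguous base are dropped. Identity is computed over aligned
   residue-pair columns only, not over alignment length.
3. **Substitution counting.** For a codon pair differing at $k$ positions,
   all $k!$ orderings of the single-nucleotide steps are enumerated,
   pathways through stop codons discarded, and the synonymous/nonsynonymous
   step tallies averaged over the surviving pathways (TTT↔GTA, for
   example, averages its two 2-step pathways to $n_S = 0.5$,
   $n_{NS} = 1.5$). Site counts are the average of the two sequences'
   counts over retained columns.
4. **Rates.** $d_N$ and $d_S$ are the *uncorrected* proportions — no
   multiple-hit correction. This implements the defining formulas literally
   and is valid exactly in the regime the quality filter enforces (below).
   When $d_S = 0$, $\omega$ is undefined and carried as `NA`.
5. **Test.** The table cells are the products $d_N N_{NS}$ and $d_S N_S$
   rounded half-away-from-zero to integers (margins rounded independently;
   a substituted cell exceeding its margin — possible only when a supplied
   $d_S$ or $d_N$ exceeds 1 — is clamped with a warning). The two-sided
   Fisher p-value sums all hypergeometric point probabilities no larger
   than the observed one, computed in log space; point-probability ties are
   resolved with a relative tolerance of 1e-7 because floating-point
   equality is ill-defined. A zero margin yields $p = 1$.

### Quality filter

The uncorrected estimate requires an alignment of impeccable quality and a
low probability of multiple substitutions per site. Pairs with protein
identity ≤ 70% or $d_S \ge 1$ are therefore *filtered*: excluded from
testing and from the test count $m$. In CODEML-output mode identity is not
available, so only the $d_S$ rule applies there.

### Multiplicity

Testing a whole proteome of pairs at a fixed $\alpha$ would confirm a
predictable number of spurious ORFs by chance. The default policy allows
one expected false positive across the batch:
$\alpha_{\text{adj}} = \min(\alpha, 1/m)$, with $m$ the number of tests
actually performed (filtered pairs excluded). We read "allow one false
positive" as an expected count under the global null — $m \cdot (1/m) = 1$
— rather than a family-wise error rate; Bonferroni ($\alpha/m$) and no
adjustment remain available through `alpha_policy`, and `m` is always
recorded in the run summary since reasonable batch definitions (e.g.
ORFans and non-ORFans jointly or separately) are the caller's choice.

Pairs with no substitutions at all get $p = 1$ and the distinct verdict
`insufficient`: the test automatically filters out alignments too similar
or too short to carry information, and collapsing that state into
`dubious` would hide it.

## Two estimate sources

The same test runs on two interchangeable inputs, with provenance
recorded per row:

- `internal`: the package's own counting over its own alignment, as above.
- `codeml`: `S`, `N`, `dN`, `dS`, `dN/dS` parsed from CODEML pairwise-mode
  output (`runmode = -2`, `seqtype = 1`); substitution counts are
  reconstructed as $n_S = d_S \cdot S$ and $n_{NS} = d_N \cdot N$. CODEML's
  maximum-likelihood site counts and distances will not numerically match
  the internal Nei–Gojobori-style counts for the same pair — the two
  sources are alternatives, not replicates, which is why provenance is
  carried rather than reconciled.

## Auxiliary metrics

Each pair is annotated with per-ORF length, G+C fraction and codon
adaptation index (CAI): the geometric mean over the ORF's codons of each
codon's relative adaptiveness $w$ (its frequency divided by the maximum
frequency among its synonyms), excluding the single-codon families Met and
Trp. The default reference usage is built from the full input CDS set
itself — with no expression data there is no better-grounded reference, and
an external two-column codon/count table can be supplied instead; unseen
codons get a 0.5 pseudo-count so $\log w$ stays finite. Confirmed and
dubious groups are compared on $\omega$, length, CAI and G+C with the
two-sample Kolmogorov–Smirnov test (per pair, length/CAI/GC are the mean
of the two ORFs; `stats::ks.test`, exact small-sample p-values where the
sample sizes permit).

## The simulator, and what passing tests mean

The package measures its own operating characteristics with a simulator of
homologous ORF pairs, because the test's size and power cannot be checked
on real annotations where truth is unknown. An ancestral stop-free
sense-codon sequence (first codon ATG) is drawn at a target G+C fraction
(realised within ±0.05 by rejection), then evolved independently along two
branches (star topology, matching the pairwise design): proposed
single-nucleotide changes are uniform over positions and target bases (no
transition/transversion bias, kappa = 1), accepted with probability 1 when
synonymous, $\omega_{\text{true}}$ when nonsynonymous, 0 when creating a
stop. The proposal count per branch is $3 L \cdot d_S^{\text{target}}/2$,
which makes the expected accepted synonymous changes per synonymous site
across the pair equal the target $d_S$ (a uniform proposal is synonymous
with probability $N_S / 3L$).

Default conditions are the regime the tool targets: 300-codon ORFs at 61%
G+C (the giant-virus genomes that motivate ORFan validation), pairwise
$d_S = 0.3$, 500 replicate pairs. This is deliberately *not* a full codon
rate-matrix (GY94-style) simulator: no transition bias, no
site-heterogeneous $\omega$, no indels, two tips only. Passing calibration
under it shows the test and estimator are internally coherent under the
model's own null and alternative; it does not show robustness to
real-data features such as selection heterogeneity along the gene,
alignment error around indels, or compositional drift between genomes.

Measured at the package's documented scales (500 pairs for size and
estimator recovery, 200 per condition for the power sweep across 150/300/
600 codons; `operating_characteristics()` reproduces all of them from a
seed):

- type-I error at unadjusted $\alpha = 0.05$ under the neutral null
  (checked against the 99% binomial envelope of 0.05; see the bias note
  below for why individual seeds can land slightly high);
- power at $\omega_{\text{true}} = 0.2$, which exceeds the null rejection
  rate and is nondecreasing in length;
- mean estimated $\omega$ on 1000-codon pairs, which recovers 1 under the
  null within ±0.05 and falls in [0.15, 0.30] for
  $\omega_{\text{true}} = 0.2$.

Two known biases are worth stating. Realised $d_S$ runs below the target
(about 20% low at $d_S = 0.3$) because the uncorrected estimator misses
multiple hits at one site; the bias largely cancels in the $d_N/d_S$
ratio. And because stop-creating proposals are rejected, the simulated
"neutral" process carries a slight deficit of nonsynonymous fixations
relative to the site classification (which books stop mutants as
nonsynonymous sites), so mean $\hat\omega$ under the null sits just below
1 rather than exactly at it, and the null rejection rate runs marginally
above the nominal level — enough that a fixed replication seed can land a
500-replicate rejection fraction just outside the 99% envelope.

## Numerical and design choices

- **Rounding** is half-away-from-zero (`floor(x + 0.5)` for the
  nonnegative quantities involved), documented because R's `round()`
  rounds half to even.
- **Tie-breaking** in the alignment is fixed by the scoring scheme and
  implementation; reproducibility of scores is guaranteed and verified
  against an independent affine-gap dynamic program on short sequences.
- **Reciprocal-best-hit pairing** ranks partners by alignment score, not
  identity (identity is length-confounded); score ties break to the
  lexicographically smaller id.
- **Degenerate inputs**: stop codons are hard errors in site profiles;
  internal stops reject a record at load time (a predicted protein cannot
  contain one) with the reason logged; terminal stops are stripped; empty
  alignments and zero site counts are errors, not NA propagation.
- **Determinism**: all simulator randomness flows from the spec's single
  seed; reports are byte-stable across reruns of the same inputs.

## Worked example

```{r example}
spec <- simulation_spec(n_codons = 200, omega_true = 0.2, expected_ds = 0.3,
                        n_pairs = 20, seed = 42)
pairs <- simulate_orf_pairs(spec)
fa <- tempfile(fileext = ".fa"); fb <- tempfile(fileext = ".fa")
tsv <- tempfile(fileext = ".tsv")
write_pair_fasta(pairs, fa, fb, tsv)

v <- run_validation(fa, fb, pairs = tsv, alpha = 0.05, alpha_policy = "one-fp")
glance(v)
tidy(v) |>
  select(id_a, identity, d_N, d_S, omega, p_value, verdict) |>
  head()
```

```{r plot, fig.width = 6, fig.height = 3.5}
autoplot(v)
```

## Limitations

- The uncorrected $d_N$, $d_S$ are rates only within the quality-filter
  regime; outside it (saturated pairs) they can exceed 1 and the test is
  not run.
- Verdicts are per pair, not per ORF; an ORF appearing in several pairs is
  tested several times, and the batch definition for the threshold
  adjustment is the caller's.
- "Confirmed" means the two position types behave differently — it does
  not distinguish purifying from positive selection; $\omega$ direction is
  annotation on top of the verdict.
- CODEML's likelihood machinery is not reimplemented; its output is only
  parsed, and its site counts differ by construction from the internal
  ones.
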