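---
title: "Methods: no-replicate differential expression and assembly QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: no-replicate differential expression and assembly QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mejaseq)
```

## The problem

Early de novo transcriptome studies of non-model organisms — here, cultured
*Taxus chinensis* cells elicited with methyl jasmonate (MeJA) versus
mock-treated controls — compared exactly two sequencing libraries with no
biological replicates. Differential expression then cannot rely on
dispersion estimation; the only tractable null model is that a gene's reads
fall into the two libraries as independent Poisson counts proportional to
library depth. `mejaseq` implements that analysis stack: expression
quantification by RPKM, the Audic–Claverie exact conditional test with a
two-sided p-value, Benjamini–Hochberg FDR control, fold-change-gated DEG
calls, the assembly/sequencing QC statistics such studies report, and
seeded synthetic-data generators so every stage can be calibrated without
the original reads.

## The exact two-library test

Condition on the count $x$ observed for a gene in library A (total depth
$N_1$). Under equal expression, the count $y$ in library B (depth $N_2$)
has, with $r = N_2/N_1$,

$$p(y \mid x) \;=\; r^{\,y}\,\frac{(x+y)!}{x!\,y!}\,(1+r)^{-(x+y+1)},$$

which is the negative binomial $\mathrm{NB}(\text{size}=x+1,\;
\text{prob}=N_1/(N_1+N_2))$ — a fact the test suite uses as an independent
cross-check. The two-sided p-value uses the lower-tail mass
$F(y) = \sum_{i \le y} p(i \mid x)$:

$$p = \begin{cases} 2F(y) & F(y) \le 1/2 \\ 2\,(1 - F(y)) & F(y) > 1/2.
\end{cases}$$

Two conventions are fixed deliberately. At the boundary $F = 1/2$ exactly,
the $2F$ branch applies (the complement branch is reserved for strictly
$F > 1/2$), so the all-zero gene gets $p = 1$. And the complement branch
excludes the point mass at $y$ itself — the literal reading of the
two-sided rule — rather than the point-inclusive or mid-p variants; the
test is therefore slightly liberal in the upper branch relative to the
point-inclusive form, by at most one point mass.

### Numerics

Each term is evaluated in log space with `lgamma`, and tails are summed in
linear space after factoring out the largest term, so counts of order
$10^6$ neither overflow nor underflow to zero prematurely. When
$F > 1/2$, computing $1 - F$ directly would cancel catastrophically for
$F \to 1$; the complement is instead obtained by summing the upper tail
$\sum_{i > y} p(i \mid x)$ in chunks, stopping once the running index has
passed the conditional mode and the geometric remainder bound — the term
ratio approaches $r/(1+r) < 1$ — is below $10^{-16}$ of the
accumulated sum. P-values are clamped into $(0, 1]$ with floor
`.Machine$double.xmin` so `log10(p)` transforms stay finite. Counts must be
integers; fractional input is rejected rather than rounded, because the
mass function is only defined on integers.

The unit and acceptance suites compare `ac_pvalue` against an
exact-rational evaluation of the same formula (Python stdlib fractions,
`inst/oracle/ac_exact.py`) on the full grid $x, y \in [0, 40]$ at library
ratios 1 and 3; agreement is to at least ten significant digits.

### Multiple testing

FDR control is the Benjamini–Hochberg step-up,
$q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$, delegated to `stats::p.adjust` and
verified against a hand-computed step-up in the tests. A gene is a DEG when
$q \le 0.001$ **and** $|\log_2 \text{ratio}| \ge 1$, boundary values
inclusive; both cuts are tunable (`fdr_cut`, `lfc_cut`).

## Expression values

RPKM is $10^9 C/(N L)$ with $C$ the gene's uniquely aligned reads, $N$ the
library's total uniquely aligned reads, and $L$ the transcript length in
bp. Within one gene the length cancels, so the RPKM ratio equals the raw
count ratio rescaled by $N_1/N_2$; the pipeline computes the log2 ratio
from RPKM but the two formulations are identical per gene.

Zero counts would make the ratio infinite. The default floor substitutes,
per gene, the RPKM a *single read* would attain in the smaller library on
that gene's length — a depth-aware pseudo-expression that shrinks as
sequencing gets deeper, overridable via `floor_rpkm`. Whether $N$ means
total clean reads or total uniquely aligned reads is a configuration
choice: the pipeline defaults to column sums of the supplied table and
accepts externally counted totals through `n1`/`n2`.

qRT-PCR-style validation data are handled by the comparative threshold
cycle method, fold change $2^{-\Delta\Delta C_t}$ against an internal
reference gene, on replicate-averaged $C_t$ values; replicate-level error
propagation is out of scope.

## QC statistics

* **N50**: sort lengths descending, accumulate, report the first length at
  which the running sum reaches half the total (ties and the exact-half
  boundary included). The returned value is always an element of the input,
  and sequences of at least that length always carry $\ge 50\%$ of bases.
* **Gap ratio**: fraction of `N` characters in an assembled sequence —
  scaffolding writes runs of `N` across unsequenced gaps — and the derived
  fraction of sequences with gap ratio strictly below 5%.
* **Q20 / N / GC percentages**: per-base statistics of a read set. "Q20" is
  implemented as $Q \ge 20$, the standard convention (a strict `>` flag
  exists for the literal reading). N bases count in every denominator but
  never in the GC numerator. Phred offset defaults to 33, with 64
  selectable for early-Illumina data; decoding a file at the wrong offset
  is detected (negative scores) and reported rather than passed through.
* **Length bins**: half-open intervals $[e_i, e_{i+1})$, plus the
  proportion at or above a cutoff. Printed percentages use round-half-up to
  two decimals (`round_half_up`), matching how such tables are reported;
  base R `round` would round half to even.

## The synthetic study design

`synthetic_scenario()` fixes the desk-scale study conditions: 2,000 genes;
library totals 29,460 and 29,896 (the study's two library read totals
scaled down by $10^3$, keeping their slight imbalance); log-normal baseline
abundance (meanlog 1.2, sdlog 1.6, giving the heavy-tailed abundance
spread typical of transcriptomes); 28.9% of genes DE (the study's DEG
fraction), split evenly between strong ($\pm 2.5$ log2) and slight
($\pm 1.25$ log2) classes, mirroring the strongly versus slightly induced
pathway genes; log-normal lengths (meanlog 6.5, sdlog 0.6, mean ≈ 744 bp,
matching the reported mean unigene length). Per gene the expected count is
$\lambda = N \cdot a_g L_g / \sum_g a_g L_g$ within each condition and
counts are Poisson — the test's own null — so column sums match the library
sizes up to Poisson noise. A gamma-Poisson `dispersion` option exists
purely to demonstrate how overdispersion breaks the no-replicate test's
type-I control; it is not the default. One root seed derives independent
sub-streams for counts, FASTA and FASTQ generation, and identical
scenario + seed gives byte-identical output.

FASTA generation places one contiguous interior `N` run per record, sized
so a target fraction of records (default 85.47%, the study's reported
value) stays below the 5% gap-ratio threshold. FASTQ generation draws
per-base qualities with $P(Q \ge 20)$ equal to the Q20 target and base
composition with $P(\mathrm{G\ or\ C})$ and $P(N)$ set unconditionally, so
the recovered percentages are unbiased for the targets (defaults 93.85%,
45.69%, 0.01% — the T0 library's reported values).

What the generator does **not** emulate: read-level alignment and
multi-mapping, positional/GC coverage bias, isoforms, and biological
replicate variability (unless `dispersion` is set). Passing tests therefore
show the pipeline is correct under its own stated model, not that the
no-replicate design is robust on real, overdispersed data — it is known not
to be, which is precisely what the dispersion switch demonstrates.

## Calibration experiments and their sizes

Type-I error uses 100 replicates of 1,000 all-null genes at the default
library sizes (10^5 null genes total); the empirical DEG fraction under
"$q \le 0.001$ and $|\log_2| \ge 1$" is compared to $0.001 + 3$ Monte-Carlo
standard errors. In practice the joint cut yields zero false calls at this
depth because the fold-change gate removes the near-boundary cases.

Power and effect recovery use a deeper design: 2,000 genes at library
sizes 2,946,000 / 2,989,600 (scale factor 10 instead of 1,000, so that a
usable share of genes has expected count $\ge 50$), baseline sdlog 1, 10%
DE at $|\log_2 \mathrm{FC}| = 3$. Sensitivity is measured on truly-DE genes
with $\lambda_A \ge 50$; the median estimated log2 ratio is compared to
truth per class on genes with $\min(\lambda_A, \lambda_B) \ge 100$, pooled
over five replicates.

One design choice deserves emphasis. RPKM normalises by the realised
library total, so the log2-ratio estimator recovers
$\text{true lfc} - \log_2(\sum w_B / \sum w_A)$: if differential expression
shifts total mRNA output between conditions, *every* gene's ratio shifts by
the same composition term — about 0.4 log2 units under the default DE mix.
This is the classic composition bias of total-count normalisation, not an
implementation artifact. The recovery experiment therefore uses an
output-balanced DE configuration — weight $1/9$ at $+3$ and $8/9$ at $-3$,
chosen so $\sum w(2^{\mathrm{lfc}} - 1) = 0$ — under which the estimator is
unbiased and the median estimate recovers the simulated effect to well
within 0.1 log2 units. On designs that are not output-balanced, reported
ratios should be read as relative to the (shifted) library average.

## Known limitations

* The exact test assumes pure Poisson technical sampling; with biological
  replicates or overdispersion it is anti-conservative and a
  dispersion-aware model (edgeR, DESeq2) should be used instead.
  Replicated-design models and multi-condition contrasts are deliberately
  out of scope.
* The FDR estimator is BH step-up; the adjusted values control the expected
  false-discovery proportion, not the per-family error.
* `gap_ratio` treats only `N` as a gap character; other IUPAC ambiguity
  codes count as ordinary non-GC bases.
* TPM/FPKM variants, GC/length bias correction and isoform-level
  quantification are not implemented.
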