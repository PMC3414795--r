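# mejaseq

Differential expression and QC toolkit for two-library, no-replicate de
novo transcriptome experiments — the design used in early RNA-seq studies
of non-model organisms, such as methyl-jasmonate-elicited *Taxus* cell
cultures profiled against mock-treated controls. It is aimed at analysts
who need the classical no-replicate stack, fully tested and calibrated:
RPKM quantification, the Audic–Claverie exact test, FDR-gated DEG calls,
assembly/sequencing QC statistics, and seeded simulators for all of it.

## The model

With library totals $N_1, N_2$ and a gene observed $x$ times in library A,
the count $y$ in library B under equal expression follows (with
$r = N_2/N_1$)

$$p(y \mid x) = r^{\,y}\,\frac{(x+y)!}{x!\,y!}\,(1+r)^{-(x+y+1)},$$

the negative binomial $\mathrm{NB}(x+1,\ N_1/(N_1+N_2))$. The two-sided
p-value is $2F$ for lower-tail mass $F = \sum_{i\le y} p(i\mid x) \le 1/2$,
else $2(1-F)$. Genes are called differentially expressed when the
Benjamini–Hochberg $q \le 0.001$ and the RPKM-based
$|\log_2 \text{ratio}| \ge 1$, where $\mathrm{RPKM} = 10^9 C/(NL)$.
Everything is evaluated in log space with direct upper-tail summation, so
counts of order $10^6$ are handled without overflow or cancellation.

Also included: N50 and length-bin statistics, gap (`N`) ratios of
scaffolded sequences, Q20/N/GC percentages of FASTQ read sets
(Phred+33/64), comparative-Ct ($2^{-\Delta\Delta C_t}$) fold changes, and
log-normal/Poisson count simulators with known ground truth.

## Worked example

The analysis is organised as numbered drivers under `analysis/`:

```sh
Rscript analysis/01_simulate.R --seed 1          # synthetic study inputs
Rscript analysis/02_assembly_qc.R                # read + assembly QC
Rscript analysis/03_differential_expression.R    # RPKM -> exact test -> DEGs
Rscript analysis/04_calibrate.R --seed 1         # type-I error and power
```

`03_differential_expression.R` prints, for the simulated two-library
table (2,000 genes, library totals 29,666 / 29,902):

```
tested 2000 genes: 47 up, 29 down, 76 total DEG (3.80%)
vs truth: 75/578 true DE called (13.0%); 1 false positives
```

— at desk-scale depth (mean expected count ≈ 15) only the strongest,
best-expressed effects clear both cuts, which is exactly the depth
dependence the calibration quantifies. The same script evaluates the
twelve published taxol-pathway RPKM pairs under the fold-change criterion
alone:

```
 symbol  rpkm_t0  rpkm_t16 log2_ratio passes_fc
     TS   1.1866    6.5920      2.474      TRUE
    TBT   1.1164    1.9310      0.790     FALSE
  T13aH   7.4494    8.4546      0.183     FALSE
   T2aH  17.2825   27.2296      0.656     FALSE
    ...
9 of 12 pass the fold-change cut
```

Nine genes (TS, DBAT, TAT, T10βH, BAPT, DBTNBT, T5αH, PAM, T7βH) clear
$|\log_2| \ge 1$; TBT, T13αH and T2αH do not — the published
strong/slight versus not-distinctly-up-regulated grouping. And
`04_calibrate.R` reports, under the test's own Poisson null:

```
type-I error: 0 (MC SE 0) over 100000 null genes
power by effect class:  up3 1.000  down3 0.999
```

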