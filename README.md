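# ploidyscan

Aneuploidy detection for cultured cell lines from short-read sequencing,
combining depth of coverage with within-sample allele frequencies.

Cell lines accumulate chromosomal abnormalities in culture: whole-chromosome
gains and losses, clonal heterogeneity, loss of heterozygosity. Before a line
is used for variant interrogation or genome editing, its gross karyotype
should be checked — copy number changes both the expected editing efficiency
(with per-copy homology-directed repair efficiency *e*, all *n* copies of a
site are repaired at rate *e*<sup>*n*</sup>) and the interpretation of any
phenotype. `ploidyscan` implements the standard desk analysis of a sequenced
sample:

1. **Coverage**: read counts in fixed genomic windows (default 10 kbp) are
   standardized by the median count over *baseline* chromosomes assumed to
   carry the most common copy number. A chromosome with copy number *c* on a
   baseline of ploidy *p* sits at standardized ratio *c*/*p*.
2. **Allele frequency (AF)**: at sites called heterozygous, the fraction of
   reads carrying the alternative allele, alt/(ref+alt), is summarized per
   chromosome by kernel density estimation and mode detection. A clonal
   mixture of karyotypes with copy numbers *n<sub>j</sub>*, alternative-copy
   counts *a<sub>j</sub>* and fractions *f<sub>j</sub>* has expected AF
   Σ *f<sub>j</sub> a<sub>j</sub>* / Σ *f<sub>j</sub> n<sub>j</sub>*; both
   allele orientations contribute, so a trisomic chromosome shows modes at
   1/3 and 2/3, a pentasomic one with a 1:4 allelic relationship at 1/5
   and 4/5.
3. **Classification**: each chromosome is scored against an enumerated space
   of single-clone and two-clone hypotheses,
   score = w<sub>cov</sub>(r<sub>obs</sub> − r<sub>exp</sub>)² +
   w<sub>af</sub>·(optimal mode assignment cost). Because distinct mixtures
   can be observationally indistinguishable (a 1:1 mixture of diploid and
   monosomic cells has the mode set of a trisomic population), results report
   a *degeneracy class* of equally supported hypotheses, not a single answer.

Supporting tools: GATK-style hard filtering of variant calls, genotype
concordance crosstables between samples, per-chromosome RNA-seq
expression-dosage summaries, and a synthetic karyotype simulator that emits
format-valid window counts, VCFs with allelic depths, and TPM tables.

## Worked example

Simulate a five-chromosome genome spanning the canonical states — disomic
(2:1 means 2 copies, 1 carrying the alternative allele), trisomic 3:1,
tetrasomic 4:2, pentasomic 5:1, monosomic 1:1 — then run the full pipeline:

```r
library(ploidyscan)

spec <- karyotype_spec(seed = 7)          # 5 chromosomes of 5 Mb
w    <- simulate_window_counts(spec)      # BED-like window counts
vcf  <- tempfile(fileext = ".vcf")
simulate_allelic_vcf(spec, c("s1", "s2"), file = vcf)

fit <- infer_karyotype(w, read_allelic_sites(vcf), sample = "s1",
                       baseline_chroms = "1")
fit
```

```
Karyotype inference (baseline ploidy 2, baseline median 101 reads/window, sample s1)

 chrom n_windows mean_ratio     se       modes fixed_fraction best_state
     1       500      1.000 0.0043       0.495              0        2:1
     2       500      1.480 0.0055 0.327,0.667              0        3:1
     3       500      1.971 0.0066       0.505              0        4:2
     4       500      2.471 0.0072 0.200,0.798              0        5:1
     5       500      0.496 0.0031         0,1              1        1:0
   score n_degenerate
 2.4e-05            4
 4.4e-04           14
 8.9e-04           10
 8.5e-04           10
 1.9e-05            2
```

Reading the table: chromosome 2 sits at coverage ratio 1.48 (≈ 3 copies on a
diploid baseline) with AF modes at 0.33 and 0.67 — a trisomic pattern. The
monosomic chromosome 5 has ratio ≈ 0.5 and fixed alleles at every site
(fixed_fraction 1); its AF carries no orientation information, so 1:0 and
1:1 are the same hypothesis. `n_degenerate` counts the indistinguishable
hypotheses; inspect them with:

```r
fit$calls[["2"]]
#> <chromosome_call> chr 2
#>   observed ratio 1.48, modes {0.327, 0.667}, fixed fraction 0
#>   best state 3:1 (score 0.000439)
#>   degeneracy class: 3:1 ; 0.5*(1:1) + 0.5*(5:1) ; 0.5*(2:1) + 0.5*(4:1) ; 3:2 ; ...
```

`summary(fit)` prints all degeneracy classes, `plot(fit)` draws the coverage
panel with expected-level lines and the per-chromosome AF densities, and
`coef(fit)` returns the best state per chromosome.

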