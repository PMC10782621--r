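---
title: "Inferring chromosome copy number from coverage and allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring chromosome copy number from coverage and allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(ploidyscan)
```

## The model

A sequenced cell population is modelled, per chromosome, as a mixture of
clones: clone $j$ has total copy number $n_j$, carries $a_j$ copies of the
alternative allele at a heterozygous site ($0 \le a_j \le n_j$), and makes up
a fraction $f_j$ of cells ($\sum_j f_j = 1$). Two observables identify (up to
degeneracy) the mixture:

**Coverage.** Reads are counted in fixed windows and divided by the median
window count over user-chosen *baseline* chromosomes — those assumed to carry
the sample's most common copy number. If the baseline corresponds to ploidy
$p$, the expected standardized ratio of the chromosome is
$\sum_j f_j n_j / p$: 0.5 for monosomy, 1.5 for trisomy on a diploid
baseline, and so on. Median (not mean) standardization is robust to the
heavy upper tail that repetitive regions give window counts.

**Allele frequency.** At a heterozygous site, the expected fraction of reads
carrying the alternative allele is the copy-weighted average
$$\mathrm{E}[\mathrm{AF}] \;=\; \frac{\sum_j f_j\,a_j}{\sum_j f_j\,n_j}.$$
Either allele of the site can play the amplified role, with equal
probability across sites, so the distribution of observed AFs is a mixture
over the two *orientations* $a_j$ and $n_j - a_j$; the mode set is
$\{\mathrm{E[AF]},\, 1-\mathrm{E[AF]}\}$. A diploid (or any 1:1 allelic
relationship, e.g. tetrasomic 4:2) chromosome is unimodal at 0.5; trisomy
gives modes at 1/3 and 2/3; a pentasomic chromosome with a 1:4 allelic
relationship gives 1/5 and 4/5.

```{r modes}
signature_of(mixture_state(3, 1))   # trisomic
signature_of(mixture_state(5, 1))   # pentasomic, 1:4 alleles
```

**Degeneracy.** The map from mixtures to signatures is many-to-one. The
identities are exact in rational arithmetic: a 1:1 mixture of diploid
(2:1) and monosomic (1:1) cells has expected AF
$(\tfrac12 + \tfrac12)/(1 + \tfrac12) = 2/3$, the trisomic mode; a 1:1
mixture of hom-ref diploid (2:0) and trisomic (3:1) cells has expected AF
$1/5$, the pentasomic mode. Any inference must therefore return an
equivalence class, not a point estimate.

```{r degeneracy}
signatures_equal(signature_of(mixture_state(c(2, 1), c(1, 1))),
                 signature_of(mixture_state(3, 1)))
```

## Classification and scoring

`classify_chromosome()` scores every candidate state $s$ against the
observed evidence:
$$\mathrm{score}(s) = w_\mathrm{cov}\,(r_\mathrm{obs} - r_s)^2 +
  w_\mathrm{af}\, C(M_\mathrm{obs}, M_s),$$
where $C$ is the minimal partial-assignment cost between observed and
expected mode sets: matched pairs cost their squared difference, unmatched
modes on either side cost $\lambda$ each (exact search; mode sets have at
most a few elements). The *degeneracy class* is every candidate within `tol`
of the best score.

Defaults and rationale:

| parameter | default | role |
|---|---|---|
| `w_cov`, `w_af` | 1, 1 | balance coverage and mode evidence on comparable squared-error scales |
| `lambda` | 0.25 | an unmatched mode costs as much as a matched pair 0.5 apart — more than any plausible KDE localization error, less than ignoring a mode outright |
| `tol` | 1e-3 | collapses floating-point ties and true signature coincidences without merging distinct copy numbers (adjacent single-clone scores differ by $\ge (1/2)^2/4 \approx 0.06$ in the coverage term alone) |
| `max_copies` | 6 | covers monosomic through hexasomic single clones |
| `fraction_grid` | 0.5 | 1:1 two-clone mixtures; finer grids enlarge the space quadratically and mostly add near-duplicates of existing signatures |

Note that with `w_cov = 1` the classic clonal mimics (e.g. 1:1
diploid+monosomic vs trisomic) do *not* fall in one class, because their
coverage ratios differ (0.75 vs 1.5) even though their mode sets coincide;
they merge under mode-only scoring (`w_cov = 0`). Which comparison is
appropriate depends on whether the baseline ploidy itself is trusted — in
heavily rearranged lines it may not be — so the weight is exposed.

**Fixed alleles.** Where one allele has been lost (monosomy, uniparental
disomy), AFs pile up at 0 and 1, where kernel density modes are unreliable.
Such chromosomes are flagged by the *fixed-allele fraction* — the fraction
of sites with AF $\le 0.05$ or $\ge 0.95$ — and when it exceeds
`fixed_threshold` (default 0.6) the candidate space is restricted to states
whose mode set touches the boundary. The two orientations of a fully fixed
chromosome (e.g. 1:0 and 1:1) are inherently indistinguishable and share a
degeneracy class.

## Site selection and density estimation

For jointly called genome-sequencing samples, a site enters a sample's AF
set when called heterozygous in *either* sample (`policy = "either"`); a
site heterozygous only in the other sample is kept even when the evaluated
sample shows a single allele, because an AF of 0 or 1 at such a site is
direct evidence of loss — it feeds the fixed-allele fraction rather than the
mode reading. For samples called alone, `policy = "self"` uses only the
sample's own heterozygous calls. For RNA-seq, where per-site depth varies by
orders of magnitude, sites need at least five reads from each allele
(`select_sites_rnaseq()`).

The density is a Gaussian KDE on a 512-point uniform grid over $[0, 1]$,
renormalized to integrate to 1 over the interval (no boundary reflection —
boundary behaviour is deliberately delegated to the fixed-allele fraction).
Bandwidth defaults to 0.02 on the AF scale: at read depth $d \ge 20$ the
binomial spread of an AF observation is $\le \sqrt{0.25/20} \approx 0.11$
per site, and with thousands of sites a 0.02 kernel cleanly separates the
1/5-and-4/5 pentasomic pattern from the 1/3-and-2/3 trisomic one while
still smoothing over the granularity of small-depth fractions. Modes are local maxima (boundaries included) whose topographic
prominence exceeds 10% of the density maximum; equal-height maxima are all
retained.

Numerical conventions: medians of even counts use the midpoint; the
per-chromosome summary reports SE $= s/\sqrt{n}$ over window ratios;
zero-total-depth sites are skipped with a reported count; windows with zero
counts keep ratio 0; malformed windows, negative TPM, unknown samples and
unknown genotype encodings are loud errors, while absent INFO metrics never
fail a hard-filter clause (rank-sum annotations are only defined for
heterozygous sites in standard callers).

## The synthetic generator

`karyotype_spec()` defines the simulated study conditions. The default
genome has five 5-Mb chromosomes in states 2:1, 3:1, 4:2, 5:1 and 1:1 —
disomic control, trisomic, tetrasomic with 1:1 alleles, pentasomic with 1:4
alleles, and monosomic — with 10-kbp windows at 100 reads per window
(baseline), ~2,500 heterozygous sites per chromosome (density
$5 \times 10^{-4}$/bp) at 50 reads per site. These sizes give KDE-stable
mode estimates (mode SE well under the 0.02 bandwidth) while the whole
pipeline runs in seconds on one core; they correspond to roughly 0.2% of a
mammalian genome at typical resequencing depth.

The generative model is deliberately minimal: window counts are Poisson
(optionally negative binomial) with mean proportional to
$\sum_j f_j n_j / p$ and window width; site depths are Poisson scaled the
same way; alternative-read counts are Binomial at the orientation's expected
AF, with the orientation drawn uniformly per site and shared across samples
of the same line. Emitted VCFs carry GT/AD and the five hard-filter INFO
metrics drawn from passing ranges (QD 10–30, FS 0–10, MQ 55–60, rank sums
±2), with an optional fraction of deliberate QD = 1.0 failures for filter
testing. TPM tables scale expression with dosage:
$\log_{10}\mathrm{TPM} \sim N(\mu + \log_{10}(\sum_j f_j n_j/p),\ 0.5)$.

What the simulator does *not* emulate — and what passing tests therefore do
not demonstrate on real data: GC and mappability bias in window counts,
reference-allele mapping bias in allelic depths (which shifts real AF modes
slightly below their rational values), sequencing error at fixed sites,
linkage between neighbouring sites, segmental (sub-chromosomal) copy-number
changes, and joint-calling artefacts. On real samples the coverage track
should be inspected alongside the per-chromosome summary precisely because
segmental changes average out in a whole-chromosome mean.

One statistical subtlety the tests do account for: the baseline median is
itself estimated from a few hundred integer counts, so all standardized
ratios share a denominator error of order 0.5%. Comparisons of a
chromosome's mean ratio against its expected level therefore use an SE that
adds the bootstrap variance of the baseline median to the per-window SE of
the mean.

## End-to-end recovery

```{r pipeline}
spec <- karyotype_spec(seed = 7)
w <- simulate_window_counts(spec)
vcf <- tempfile(fileext = ".vcf")
simulate_allelic_vcf(spec, c("s1", "s2"), file = vcf)
fit <- infer_karyotype(w, read_allelic_sites(vcf), sample = "s1",
                       baseline_chroms = "1")
fit
```

```{r plot, fig.height = 6}
plot(fit)
```

Every chromosome's degeneracy class contains its generating state; this is
the package's flagship integration test.

## Editing-efficiency arithmetic

Aneuploidy matters for genome editing because an interpretable phenotype
generally needs all copies edited. With independent per-copy HDR efficiency
$e$, the all-copy rate is $e^n$:

```{r hdr}
100 * hdr_all_copy_rate(0.2, 2:4)   # % of sites fully repaired
```

At 20% per-copy efficiency, a trisomic region yields one-fifth the fully
repaired fraction of a disomic one — screening a line's karyotype before
designing an assay is cheap by comparison.

## Limitations

- Whole-chromosome calls only; segmental aneuploidy and complex
  rearrangements need changepoint methods on the window track.
- The baseline ploidy is an assumption, not an estimate; if the true
  baseline is triploid, all ratios and candidate interpretations shift
  accordingly (the `baseline_ploidy` argument propagates everywhere).
- Two-clone 1:1 mixtures are the only mixtures enumerated by default;
  arbitrary clone trees are out of scope.
- Expression dosage is corroborating evidence only; no copy number is
  inferred from RNA-seq alone.
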