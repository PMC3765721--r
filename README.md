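# texret — retention analysis of transposable-element-derived exons

Roughly 44% of the human genome derives from transposable elements (TEs),
and some TE sequences have been recruited as novel exons of host genes
("exonization"). Most such TE exons are alternatively spliced and retained
in mature mRNA at low but detectable rates. `texret` implements an
exon-level RNA-seq analysis of that retention for researchers studying TE
exonization and alternative splicing: it quantifies how strongly each exon
is retained relative to its host gene, compares TE exons against
constitutive and cassette exons and against intronic background, and
models which genomic features of a TE exon drive its expression level and
its cross-sample variability.

## The measure and the models

**Exon classes.** Integrating a refGene-like gene table, an
alternative-exon table and an exonized-TE table, every exon gets one of
five classes: C1 constitutive non-TE, C2 cassette non-TE, C3 TE exons with
an exact-coordinate counterpart in the gene table ("annotated"), C4 TE
exons without one ("un-annotated"), and C5 — simulated decoy exons on the
intronic sequence immediately downstream of each C4 exon, with equal
length. C5 regions estimate the background of pre-mRNA and DNA
contamination; 500 "fictional genes" assembled from 4–40 C5 exons each set
a sample-specific expressed-gene cutoff from the decoy RPKM distribution.

**Rescaled RPKM.** For exon *e* in host gene *g* with read count *c*,

    RPKM(e) = c / ((len(e)/1000) · (N/10^6)),      N = filtered reads
    expr(g) = mean of RPKM over g's annotated exons (C4/C5 excluded)
    rescaled(e) = min(RPKM(e) / expr(g), 10)

The rescaled RPKM is a double-normalised proxy of the exon's inclusion
rate in the host gene's transcripts. Exons of genes below the decoy-based
cutoff are excluded from all statistics.

**Two-step hurdle regression.** Because 30–80% of TE exons have no reads,
expression is modelled in two parts. With location indicators **R**
(CDS baseline), family indicators **F** (Alu baseline), l = log10 exon
length (ELN) and c = TE nucleotide proportion (RTE):

    Model-1:  logit P(z_i = 1)  =  μ  + R_iα  + F_iβ  + γ l_i  + φ c_i
    Model-2:  log10 y_j         =  μ* + R_jα* + F_jβ* + γ*l_j + φ*c_j + e_j   (y_j > 0)

Model-1 is a logistic regression on presence/absence (count ≥ 1); Model-2
is OLS on the log10 rescaled RPKM of the expressed subset. The same design
is refit on the per-exon cross-sample median *m* and coefficient of
variance *v* to contrast effects on level versus variability.

Around these sit Mann–Whitney / paired Wilcoxon stepwise class
comparisons, CV and pooled-SD t-statistics across sample groups,
complete-linkage Euclidean clustering of samples, and per-family Fisher
tests of whether highly expressed TE exons (rescaled RPKM > 0.25 in ≥ 2
samples) are enriched in C2H2 zinc-finger genes.

A seeded synthetic-data generator (`simulate_dataset()`) emulates the
study conditions — ~14,000 exons over ~1,750 genes, ~1,400 TE exons, 26
pseudo-samples with breast and prostate contrasts, ~8×10⁷-read libraries —
with hurdle-structured counts from planted coefficients, so every stage is
testable against known ground truth without any downloads.

## Worked example

```r
library(texret)

ds  <- simulate_dataset(generator_config(), default_truth(), seed = 11)
sq  <- quantify_samples(ds$counts, ds$annotation, ds$lib_sizes)
sq[[1]]
#> <sample_expression> BRneg_1: 59,329,324 filtered reads, cutoff 0.01731 RPKM,
#> 1750/1750 real genes expressed

head(class_summary_table(sq[1], ds$annotation))
#> # A tibble: 5 × 8
#>   sample_id exon_class n_total n_expressed r_unexpressed  m_mean      sd  p_value
#> 1 BRneg_1   C1           10101        9709        0.0388 1.08    0.122   NA
#> 2 BRneg_1   C2            2504        2310        0.0775 0.988   0.110   0
#> 3 BRneg_1   C3             230         156        0.322  0.440   0.365   2.30e-85
#> 4 BRneg_1   C4            1132        530         0.532  0.186   0.222   6.25e-24
#> 5 BRneg_1   C5            1132         67         0.941  0.00294 0.00146 1.01e-92
```

Reading down the classes: the un-expressed ratio `r` rises (4% → 94%) and
the mean rescaled RPKM `m` falls (≈1 → 0.003) from constitutive exons to
decoys; `m ≈ 1` for C1 is the normalisation identity at work. Each
`p_value` is the stepwise comparison against the previous class (C4 vs C5
is the paired signed-rank test against the decoys): un-annotated TE exons
are weakly but significantly expressed above background.

```r
fit <- two_step_fit(sq[[1]], ds$annotation$te_features)
fit$model2[fit$model2$term %in% c("MIR", "log10_eln", "rte"), ]
#> # A tibble: 3 × 4
#>   term      estimate     se  p_value
#> 1 MIR          0.412 0.0342 1.60e-30
#> 2 log10_eln   -0.441 0.0794 3.89e- 8
#> 3 rte         -0.998 0.0574 2.89e-56
```

MIR-derived exons are more highly retained than Alu-derived ones, and both
the exon length and the TE nucleotide proportion depress the retention
level — the fitted values recover the generator's planted coefficients
(+0.4, −0.5, −1.0) within two standard errors.

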