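# gbmti: gene body methylation and transcript integrity

In many flowering plants a large fraction of constitutively expressed genes
carry **gene body methylation (gbM)**: CG-context DNA methylation within the
transcribed region, without the CHG/CHH methylation typical of transposons.
Whether gbM *does* anything — in particular whether it suppresses aberrant
transcription (internal transcription starts, antisense transcription) and
splicing errors (intron retention) — is a long-standing open question.

`gbmti` is an R package for testing these hypotheses from standard genomics
inputs. It implements, as a reusable and fully tested pipeline:

* **Statistical gbM/UM/teM gene classification** from per-cytosine bisulfite
  counts (Bismark-style cytosine report). A gene is **gbM** when its count of
  methylated CG sites is significantly *above* the genic average and neither
  CHG nor CHH is elevated; **teM** (TE-like) when CHG or CHH is elevated;
  **UM** when no context is elevated and CG is significantly *below* the
  genic average. Per gene and context the test is an exact binomial tail
  against the pooled genic background rate, Benjamini–Hochberg adjusted
  across genes; site-level methylation calls are themselves exact binomial
  tests against the bisulfite non-conversion rate.
* **Full-length long-read (Isoseq-style) classification** of each spliced
  alignment against its gene: *conventional* TSS (5′ end at or before the
  annotated start of exon 1 in gene orientation) versus *internal* starts,
  antisense orientation, and intron retention (an annotated intron fully
  contained in one aligned block), aggregated to per-gene proportions.
* **Short-read coverage metrics**: the exon3/exon1 read-count ratio (a proxy
  for cryptic initiation between exons 1 and 3) and intron coverage in RPKM,
  with the wild-type-labels-in-mutant comparison design.
* **Group comparisons**: Wilcoxon rank-sum tests (exact for small, tie-free
  samples) and a covariate-adjusted quasibinomial GLM,

  `cbind(favorable, eligible − favorable) ~ class + log10(length) + log10(1 + expression)`

  whose class coefficient is the UM − gbM contrast on the logit scale,
  reported with its standard error, Z-ratio and p-value.
* **A seeded synthetic-data generator** that emits a complete input bundle
  (GFF3, cytosine report, BED12 long reads, BED short reads, truth table)
  with planted gene classes and planted effect sizes, so every stage of the
  pipeline is verifiable end to end without any external download.

Everything is data-frame first: functions accept and return tibbles, fitted
objects have `tidy()`/`glance()` methods, and result objects have
`autoplot()`/`plot_metric_by_class()` for the conventional boxplot-by-class
figures.

## Worked example

Simulate a 400-gene study and run the long-read arm end to end:

```r
library(gbmti)

cfg <- sim_config(n_genes = 400L, genes_per_chrom = 200L)
d <- file.path(tempdir(), "demo")
simulate_dataset(cfg, seed = 1, dir = d)

rep <- run_longread_analysis(
  file.path(d, "genes.gff3"),
  file.path(d, "cytosine_report.tsv"),
  file.path(d, "long_reads.bed")
)
rep
#> <gbmti_report>
#>  classification: gbM 95, teM 36, UM 186, undetermined 83
#>  comparisons:
#>                  metric n_gbm n_um    mean_gbm    mean_um  pooled_gbm
#> 1 prop_conventional_tss    95  185 0.808993372 0.78557733 0.813903743
#> 2        prop_antisense    95  185 0.007295176 0.01677899 0.006376196
#> 3  prop_intron_retained    95  185 0.159218505 0.10051391 0.153475936
#>    pooled_um wilcoxon_statistic   wilcoxon_p wilcoxon_alternative glm_contrast
#> 1 0.78565607            10103.0 4.031466e-02            two_sided   -0.1796304
#> 2 0.01630144             7206.0 9.877302e-04            two_sided    0.9569909
#> 3 0.10241782            12307.5 3.945472e-08            two_sided   -0.4643230
#>       glm_se     glm_z        glm_p
#> 1 0.07741111 -2.320473 2.031528e-02
#> 2 0.30130940  3.176107 1.492659e-03
#> 3 0.08566841 -5.420003 5.959802e-08
```

Reading the output: 95 genes were classified gbM and 186 UM from the
simulated methylome (undetermined genes have too few covered CG sites and are
excluded). Among genes with enough assigned reads, the mean per-gene
proportion of conventional TSSs is 0.809 in gbM genes versus 0.786 in UM
genes — the generator plants 0.81 versus 0.78 — and the covariate-adjusted
GLM contrast (UM − gbM, logit scale) is negative with p ≈ 0.02. Antisense
proportions (planted 0.0046 vs 0.016) and intron-retention proportions
(planted 0.149 vs 0.106) are likewise recovered with the expected contrast
signs. `plot_metric_by_class(rep$metrics, "prop_conventional_tss")` draws the
by-class boxplot; `tidy(rep$fits$prop_conventional_tss)` shows the length and
expression covariate estimates.

The short-read arm works the same way through `run_shortread_analysis()`,
which takes one or more condition BED files (e.g. WT and a methylation
mutant) and always classifies genes from the *reference* (WT) methylome, so a
group difference that persists in the mutant indicates a stable gene property
rather than a methylation effect.

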