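---
title: "Methods: classifying gene body methylation and measuring transcript integrity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying gene body methylation and measuring transcript integrity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmti)
```

## The scientific question

Gene body methylation (gbM) — CG-context methylation inside the transcribed
region of otherwise transposon-free genes — is conserved across most
flowering plants, yet its function is contested. Two candidate functions are
examined by this package's pipeline: suppression of aberrant transcription
(internal transcription starts within the gene body, and antisense
transcription), and suppression of splicing errors (intron retention). The
package provides the full chain from raw per-cytosine bisulfite counts and
read alignments to covariate-adjusted group comparisons between gbM and
unmethylated (UM) genes, together with a synthetic-data generator that plants
known classes and effect sizes so the whole chain can be validated.

## Gene classification from bisulfite counts

Classification is two-stage, both stages exact binomial:

1. **Site level.** A cytosine site with $m$ methylated of $n$ total reads is
   called methylated when the upper tail $P(X \ge m \mid n, e)$ is small,
   where $e$ is the bisulfite non-conversion rate (default 0.005). P-values
   are Benjamini–Hochberg adjusted across all sites and called at FDR 0.05.
   Sites with coverage below `min_coverage` (default 3) are dropped at
   parsing.
2. **Gene level.** Per gene and context $c \in \{CG, CHG, CHH\}$, with $k_c$
   methylated of $s_c$ covered sites and pooled genic background rate
   $\pi_c = \sum_g k_{gc} / \sum_g s_{gc}$, both binomial tails
   $P(X \ge k_c \mid s_c, \pi_c)$ and $P(X \le k_c \mid s_c, \pi_c)$ are
   computed and BH-adjusted across genes within each context and tail.

Labels: **teM** if CHG or CHH is significantly above background (TE-like
methylation takes precedence, so no teM gene can be called gbM); **gbM** if
CG is significantly above background and neither CHG nor CHH is; **UM** if no
context is above background *and* CG is significantly below it;
**undetermined** otherwise, including every gene with fewer than `min_sites`
(default 20) covered CG sites. Requiring active lower-tail significance for
UM means sparse, uninformative genes end up undetermined rather than
polluting the UM group; downstream comparisons use only gbM and UM. A
`strict` mode additionally requires CHG and CHH lower-tail significance for
gbM — the literal reading of "less methylated than the genic average" — but
is off by default because at typical site counts (tens of non-CG sites
against backgrounds of a few percent) the lower tail rarely reaches
significance and the strict rule empties the gbM set.

Defaults (`min_coverage` 3, `min_sites` 20, `alpha` 0.05, `error_rate` 0.005)
are conventional values for this classification tradition; all are arguments.

## Long-read calls

Reads are assigned to genes by maximal overlap of aligned blocks with gene
spans, strand-agnostic (antisense reads must remain assignable), requiring at
least 50% of the read's aligned bases inside the gene span; exact ties leave
a read unassigned. Per assigned read:

* **antisense** — read strand differs from gene strand;
* **conventional TSS** (sense reads) — the 5′-most aligned position is at or
  5′ of the start of annotated exon 1, in gene orientation, within
  `tss_tolerance` (default 0 bp, so a read starting 1 bp inside exon 1 is
  already nonconventional);
* **TSS-in-intron** — nonconventional and the 5′ start lies inside an
  annotated intron;
* **intron retention** — an annotated intron entirely contained in a single
  aligned block. Partial overlaps are not retention: this conservative rule
  is unambiguous and directly checkable against a per-base oracle.

Per-gene proportions use separate denominators: conventional/sense,
antisense/assigned, retaining/sense (intronless genes excluded); any
proportion whose denominator is below `min_reads` (default 5, to stabilise
per-gene proportions) is `NA`. Antisense reads are excluded from the TSS
denominator because the TSS and antisense analyses are separate questions.

## Short-read metrics

The exon3/exon1 ratio counts reads overlapping (≥ 1 bp, half-open intervals,
unstranded by default) exon 3 versus exon 1 in transcriptional order on the
canonical transcript; it is undefined for genes with fewer than three exons
or without exon-1 reads. A read overlapping both exons counts in both — the
ratio is a relative proxy, not an absolute rate. Intron RPKM is
$10^9 \cdot r / (L \cdot \ell)$ for $r$ reads overlapping any intron of the
gene (each read counted once per gene), library size $L$ and total intron
length $\ell$ bp.

In the two-condition design (`run_shortread_analysis()`), gene labels are
always taken from the designated reference (WT) methylome and propagated to
every condition. This is the analytical move that separates methylation
effects from stable gene properties: an effect that disappears in a
methylation-free mutant was plausibly caused by methylation, one that
persists was not.

## Group comparisons

Continuous metrics (exon3/exon1, intron RPKM) are compared by Wilcoxon
rank-sum tests only — one-sided in the two-condition design, matching how
such coverage comparisons are usually reported. Proportion metrics
additionally get a quasibinomial logit GLM on per-gene (favorable, eligible)
counts with `log10(length)` and `log10(1 + assigned reads)` as covariates,
because gbM genes are known to be longer and more highly expressed than UM
genes and both covariates correlate with the metrics. The quasi family
estimates a dispersion, making the Wald standard errors robust to
overdispersion across genes. The class factor is coded gbM-reference, so the
reported contrast is UM − gbM on the logit scale (positive = UM higher); the
sign convention is stated in the output. Log transforms of the covariates
are the conventional choice; the package does not attempt to infer them from
data.

## What the generator emulates

`sim_config()` defines the synthetic study conditions: 2000 genes of 3–8
exons (exons 100–300 bp, introns 80–200 bp) on non-overlapping loci, class
priors 0.35 gbM / 0.55 UM / 0.10 teM, and per-class site-methylation rates
(gbM: CG 0.80, non-CG at the error rate; UM: all at the error rate; teM: CG
0.80, CHG 0.70, CHH 0.40) with Poisson coverage (mean 15) and non-conversion
0.005. teM genes are simulated so the classifier's exclusion rule is
exercised, but they are excluded from group comparisons. The planted
transcript parameters are the reported per-class effect sizes: conventional
TSS 0.81 (gbM) vs 0.78 (UM), antisense 0.0046 vs 0.016, intron retention
0.149 vs 0.106, with a negative-binomial read count per gene (mean 20, size
10).

Three generator choices deserve explanation:

* **Read-level retention.** Retention is drawn per read (Bernoulli at the
  planted rate) and a retaining read keeps one uniformly chosen intron. Had
  each intron been retained independently at the per-class rate, the
  read-level proportion of reads retaining ≥ 1 intron — the quantity the
  pipeline measures — would depend on intron count and overshoot the planted
  value in multi-intron genes. Drawing at read level makes the realized
  proportion equal the planted parameter for every gene.
* **Internal start positions** are uniform over the gene body 3′ of the
  exon-1 start. A retaining internal-start read starts 5′ of its retained
  intron, so retention stays observable; a nonconventional start may fall
  inside an intron, in which case the truncated intron is carried into the
  first aligned block (no donor site survives), which is also how such
  transcripts look in real spliced alignments.
* **Two intron-coverage knobs.** The long-read retention rate (`p_retention`)
  and the short-read pre-mRNA component (`p_premrna`, default gbM 0.05 < UM
  0.10) are separate parameters because the two assays are reported with
  opposite class patterns in the source data (long-read retention higher in
  gbM; RNA-seq intron coverage lower in gbM). One shared parameter could not
  emulate both observations.

Short reads are single intervals drawn from three components: baseline
exonic coverage (uniform over exonic bases), an internal-initiation
component (uniform over exonic bases 3′ of exon 1, mixture weight
`0.5 × (1 − p_conventional)`), and a pre-mRNA component (uniform over intron
bases, weight `0.5 × p_premrna`). The step-increase mechanism is the minimal
one that makes exon3/exon1 respond monotonically to the planted internal
rate and intron RPKM to the pre-mRNA rate.

The generator does **not** simulate sequences, alignment error, mappability,
positional coverage biases, 5′ degradation of long reads (a major real-world
confounder the covariate adjustment is meant to absorb), or correlated
methylation along the gene. Passing tests therefore demonstrate that the
pipeline measures what it claims on clean alignments at realistic depths —
not that any biological conclusion transfers to a particular real data set.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GFF3 is converted from/to
  1-based closed and BED 0-based half-open at the IO boundary only.
* One canonical transcript per gene: greatest summed exon length, ties to
  the lexicographically smallest transcript id (an exon-union mode is
  available via `isoform = "union"`). The choice matters only for genes with
  isoform-variable first/third exons.
* Genes on short contigs or with < 3 exons are retained in the annotation;
  each metric decides its own eligibility downstream.
* Exact binomial tails come from `pbinom`, BH adjustment from `p.adjust`,
  rank-sum tests from `wilcox.test` (exact path for small tie-free samples),
  the GLM from `glm(quasibinomial)`. The test suite checks these against
  independent formulations: direct `dbinom` sums, exhaustive permutation
  enumeration, a brute-force per-base read classifier, and a closed-form 2×2
  Wald contrast.
* Degenerate inputs: zero-coverage sites are an error at the site-call stage;
  a context with no covered sites genome-wide is an error naming the context;
  empty gbM or UM groups abort the pipeline with the failing filter named;
  perfect separation in the GLM is flagged with a warning rather than an
  error.

## Simulation sizes used by the test suite

Calibration claims are checked at sizes chosen to give adequate Monte Carlo
precision while keeping the suite fast: classifier false-label control on
200 replicate methylomes of 1000 genes (binomial SE on the pooled rate
≈ 0.0005); planted-label recovery and effect recovery on the default
2000-gene design; GLM type-I error on 200 replicates of a 300-gene, mean
12-reads design (SE of the rejection rate ≈ 0.015 at the nominal 0.05);
monotonicity and the mutant-persistence control on 300-gene designs.

## Known limitations

* The gene-level binomial treats sites within a gene as independent;
  spatially correlated methylation would make the test anticonservative.
  Against the planted generator (independent sites) the FDR holds by
  construction; on real data the classification tradition accepts this
  approximation.
* The intron-retention rule (full containment in one block) misses retention
  evidenced only by partial intron overlap at read ends, so per-gene
  retention proportions are conservative.
* The exon3/exon1 ratio averages over genes with very different exon-1
  lengths; it is a within-design comparison statistic, not a calibrated rate
  of internal initiation.
* `expression_proxy` is the assigned read count of the same library whose
  metrics are being modelled; with very low counts the covariate and the
  response are weakly coupled. At the default mean of 20 reads per gene this
  has no visible effect on the contrast calibration (checked by the null
  simulations).
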