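---
title: "Parent-of-origin testing from allele-specific expression counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-of-origin testing from allele-specific expression counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asepo)
```

## The problem

Allele-specific expression (ASE) quantifies the transcriptional output of
a gene's two alleles separately, using heterozygous SNPs as tags. Two very
different mechanisms produce allelic imbalance. *Genetic ASE* follows the
allele's sequence: a cis-regulatory variant suppresses, say, the
alternative allele in every carrier. A *parent-of-origin* (PofO) effect —
genomic imprinting being the canonical example — follows the transmitting
parent instead: the paternal copy is expressed regardless of which
nucleotide it carries. Telling the two apart requires phased genotypes
(which allele came from which parent) and a model that controls genetic
ASE while testing the parental axis.

`asepo` implements the post-alignment half of such an analysis: it ingests
per-SNP allelic read counts in GATK ASEReadCounter format, annotates SNPs
against union-exon gene models, estimates sample contamination from
homozygous sites, applies retention filters, and scores every gene with a
cluster-robust quasi-Poisson regression. A built-in simulator emits
complete synthetic datasets (count tables, VCFs, GTF, sample sheet) with
known truth, so the whole chain is testable without access-controlled
data.

## The per-gene model

For a gene with $m$ distinct heterozygous SNPs, let $Y_{ijk}$ be the read
count for allele $k$ of SNP $j$ in subject $i$, with $k = 0$ the
reference and $k = 1$ the alternative allele. Each (subject, SNP) pair
contributes two observations. Define

* $X_{ijk} = +1/2$ for the reference-allele row, $-1/2$ for the
  alternative row (ref/alt axis);
* $Z_{ijk} = +1/2$ for the paternal-allele row, $-1/2$ for the maternal
  row (parental axis);
* $U$, the $N \times m$ SNP indicator matrix (one 1 per row);
* $V$, the $N \times q$ matrix of left singular vectors of $U$ whose
  singular values are at least 1% of the largest singular value.

The fitted mean structure is

$$\log E[Y_{ijk}] = \beta_0 + \mathit{po}\, Z_{ijk} + \beta_1 X_{ijk}
  + \sum_{l=1}^{q} \gamma_l V^{(l)}_{ijk}
  + \sum_{l=1}^{q} \delta_l \left(V^{(l)}_{ijk} X_{ijk}\right).$$

The coefficient of $Z$ is the PofO score `po`. The $V$ main effects absorb
per-SNP depth differences; the $V \times X$ interactions absorb per-SNP
genetic ASE, so a cis-effect shared by all carriers cannot masquerade as a
parental effect. Because $Z$ differs by exactly 1 between the paternal and
maternal rows, $\exp(|po|)$ is the implied expected-count ratio between
the favoured and disfavoured allele: $|po| > 3$ corresponds to at least a
$\exp(3) \approx 20$-fold difference.

Uncertainty comes from a sandwich covariance clustered on subjects. This
is what makes the model "quasi"-Poisson in practice: the point estimates
are the Poisson maximum-likelihood estimates, but the variance is
estimated empirically from per-subject score sums, so both overdispersion
and within-subject correlation (linkage disequilibrium ties a subject's
SNPs together) are absorbed without being modelled. `po_z = po / se(po)`
is the reported z-score; `|po_z| > 3` is the default significance gate and
`|po| > 3` the additional strong-effect gate. The Pearson dispersion is
reported as a diagnostic only — it is never multiplied into the clustered
standard error, which is already robust.

### Why $U$ is reduced by SVD, and the structural collinearity

For a disjoint indicator matrix the singular values are the square roots
of the per-SNP observation counts, so the 1% rule discards directions
supported by vanishingly few reads relative to the best-covered SNP.
"At least 1%" is read inclusively: a singular value exactly at the
threshold is kept.

When every singular vector is retained ($q = m$), the constant column
lies in the span of $V$ (each row of $U$ sums to 1) and $X$ lies in the
span of $V \times X$, so the design is rank deficient *by construction*.
`fit_quasipoisson()` resolves this with a greedy left-to-right rank scan
over the columns ordered intercept, $Z$, $X$, $V$, $V\times X$: a column
is kept only if it increases the rank of what is already kept. Redundancy
is therefore always charged to the nuisance columns, `po` keeps its
meaning, and — as the tests assert — the estimate is invariant to which
redundant $V$ column is sacrificed. If $Z$ itself is dependent the gene
is reported untestable (`po_unidentifiable`) rather than silently
re-parameterised.

### Numerical choices

* IRLS starts from $\mu = \max(y, 1/2)$ and iterates to a scaled
  coefficient change below $10^{-10}$ (relative for large coefficients,
  absolute near zero — a pure relative criterion never converges for a
  coefficient oscillating around 0 at machine precision), capped at 100
  iterations; non-convergence marks the gene `no_convergence`.
* The linear predictor is clamped to $\pm 30$ during iteration to avoid
  overflow on degenerate steps.
* The clustered sandwich uses a CR1-style $G/(G-1)$ small-sample factor
  ($G$ = subjects), configurable to `none`.
* Rank detection uses a pivoted QR on unit-scaled columns with tolerance
  $10^{-7}$.
* Zero counts are retained as observations ($y = 0$ is informative under
  the Poisson likelihood) as long as the SNP row passed the read filter.
* Testability defaults: at least 3 subject clusters, at least one phased
  SNP, $Z$ retained, IRLS converged. All are explicit, configurable
  choices (`pofo_test()` arguments).

## Annotation, contamination and filtering

**Union exons.** All isoform exons of a gene are merged into maximal
intervals; overlapping *and book-ended* exons merge (they are contiguous
transcribed sequence). The merge is performed with `IRanges::reduce()` on
`GRanges` and is validated in the tests against a brute-force per-base
oracle. A SNP inside two genes' exons yields one annotated row per gene —
there is no "best gene" heuristic, and unannotated records are emitted to
a side table rather than dropped. `exon_index` is zero-based, matching
the BED export of the merged models. Intronic positions (between a gene's
union exons) are deliberately *not* assigned to the gene.

**Phase convention.** Phasing tools differ on whether the first allele of
`0|1` is paternal or maternal, so the convention is an explicit parameter
(`first_is_paternal` by default, as the simulator emits). Flipping the
convention complements every paternal allele frequency — an exact
symmetry the tests assert.

**Contamination.** At a homozygous site, reads carrying the opposite
allele measure cross-sample contamination. The per-sample estimates are
*unweighted means over sites* of the per-site opposite-allele frequency
(hom-alt sites give the non-alternative frequency, hom-ref sites the
non-reference frequency), never pooled count ratios — a single deep site
must not dominate, and duplicating every site leaves the estimate
unchanged. `other_bases` count as contaminant evidence in both numerator
and denominator, since contaminant reads need not carry the on-panel
alternative base. Strands are pooled per site first (contamination is not
strand-specific). Defaults: `min_depth = 10` reads per site,
`min_sites = 5` sites per estimate. For maternal-contamination settings
(e.g. placental tissue), a per-gene estimate is computed from
offspring-hom-ref sites where the mother carries a non-reference
genotype.

**Filters.** The analysis-ready subset keeps rows with at least 10 reads
(boundary inclusive) from samples whose worst defined contamination
estimate is strictly below 5%; samples with no measurable estimate pass
by default ("when measurable"). For PofO testing, unphased rows are
additionally removed. Rules apply in a fixed order (count, contamination,
phasing) and each dropped row is attributed to the first rule it fails,
so `retained + dropped = input` exactly and re-filtering the output is a
no-op.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws allele counts from the same mean structure the
model fits, plus the nuisances the estimator must survive:

* a subject-level log-normal random effect (`subject_sd`, default 0.3)
  shared across all of a subject's rows — exactly the within-cluster
  correlation the sandwich is there to absorb;
* per-SNP genetic effects `b_j ~ N(0, genetic_sd)` applied along the
  ref/alt axis, shared across carriers — genetic ASE that the $V \times X$
  terms must soak up;
* per-SNP log-normal depth offsets (`depth_sd`, default 0.5) around a
  baseline of `exp(log 25)` reads per allele, giving a median total depth
  near 50, comfortably above the 10-read filter;
* Poisson or negative-binomial counts (`theta`), the latter converging to
  Poisson as `theta` grows;
* homozygous "marker" sites sequenced error-free for contamination
  estimation, and a per-subject mother genotype at those markers;
* contamination injected by re-labelling a `Binomial(total, c)` subset of
  each marker site's reads according to the contaminant's (the mother's)
  genotype, conserving totals read-for-read.

Counts are written on the strand file matching the host gene's strand, so
the strand-aware join is exercised end to end; each gene carries two
isoforms with overlapping exons so union-exon merging is non-trivial.
Everything derives from a single seeded RNG stream, and identical
configurations produce byte-identical files.

Two deliberate simplifications matter for interpreting green tests.
First, marker-site genotypes of mother and child are drawn independently
— Mendelian transmission is *not* enforced there. A pedigree-consistent
mother can never be the opposite homozygote of a hom-ref child, which
would cap the observable maternal-contamination signal at half the true
fraction; drawing the mother as the opposite homozygote (probability
`maternal_divergence`, default 1) makes the injected fraction fully
identifiable by the estimators, which is what a recovery test needs.
Second, contamination is injected only at the marker sites the
estimators read; heterozygous test SNPs stay clean. Passing recovery
tests therefore show the estimators are correct for informative sites,
not that PofO scores are robust to contaminated het sites. The simulator
also makes no attempt at read-level realism: no mapping bias, no
reference bias, no base-calling error, one contig, uniform A/G alleles.
Conclusions about those failure modes cannot be drawn from this suite.

## Validation at the study conditions

The test suite validates the chain at sizes chosen to make Monte-Carlo
error small while keeping a default run fast:

* *Oracle equivalence*: on 50 random designs (up to 30 subjects, 12
  SNPs), IRLS estimates match an independent generic-optimizer Poisson
  MLE and the clustered sandwich matches the reference implementation in
  the `sandwich` package, both to $10^{-6}$.
* *Null calibration*: 500 simulated null genes (50 subjects, subject SD
  0.3, genetic effects of SD 1) keep the $|po_z| > 3$ rate within
  $\pm 0.02$ of the nominal $2\Phi(-3) \approx 0.0027$ — strong genetic
  ASE does not masquerade as PofO.
* *Recovery*: 200 genes per true effect in $\{0.5, 1, 2\}$ recover the
  mean score within $\pm 0.1$; injected contamination in
  $\{0, 0.04, 0.05\}$ is recovered within $\pm 0.01$ (sample level) and
  $\pm 0.02$ (gene level), with zero contamination yielding exactly zero.
* *Exact symmetries*: label flips (parental, ref/alt, phase convention)
  act on the estimates exactly as the model algebra dictates.

## Known limitations

* Isoform-level ASE is out of scope: SNPs are annotated against union
  exons only.
* Multi-allelic sites and indels are skipped at VCF parsing.
* Gene-level contamination estimates are reported but not used to drop
  rows; only the sample-level estimate gates retention.
* The z-score is referred to fixed thresholds rather than a
  finite-sample reference distribution; with very few subjects the
  clustered sandwich is known to be anti-conservative, which is why
  `min_subjects` exists and why the calibration test runs at 50
  subjects.
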