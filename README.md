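# asepo

Post-alignment toolkit for allele-specific expression (ASE) analysis and
parent-of-origin (PofO) testing in R.

Allelic imbalance measured at heterozygous SNPs can be *genetic* (a
cis-regulatory variant suppresses one sequence allele in every carrier)
or *parent-of-origin* (imprinting: the paternal or maternal copy is
silenced regardless of its sequence). Distinguishing the two requires
phased genotypes and a model that controls genetic ASE while testing the
parental axis. `asepo` covers everything downstream of read counting:

* **Ingestion** — GATK ASEReadCounter count tables (per sample, per
  strand), sample sheets, and plain or bgzipped VCF genotypes, phased or
  not, concatenated into one unified count table.
* **Annotation** — per-gene union-exon models built from a GTF (isoform
  exons merged, book-ended intervals included), SNP-to-gene assignment
  with optional strand matching, and paternal/maternal allele assignment
  from phased genotypes under an explicit phase convention.
* **Contamination** — per-sample estimates from opposite-allele reads at
  homozygous sites, and per-gene maternal-contamination estimates for
  placental designs.
* **Filtering** — the standard retention rule (≥ 10 reads per SNP row,
  sample contamination < 5% when measurable, optionally phased-only)
  with exact drop accounting.
* **PofO testing** — per gene, a cluster-robust quasi-Poisson regression

  log E[Y<sub>ijk</sub>] = β₀ + po·Z<sub>ijk</sub> + β₁X<sub>ijk</sub> +
  Σ<sub>l</sub> γ<sub>l</sub>V<sup>(l)</sup><sub>ijk</sub> +
  Σ<sub>l</sub> δ<sub>l</sub>(V<sup>(l)</sup><sub>ijk</sub>·X<sub>ijk</sub>)

  where Y is the allele read count, Z = ±1/2 encodes paternal/maternal,
  X = ±1/2 encodes ref/alt, and V holds the left singular vectors of the
  SNP indicator matrix kept at the 1% singular-value rule. The V and V×X
  terms absorb genetic ASE; the sandwich covariance clustered on
  subjects absorbs overdispersion and within-subject correlation. The
  coefficient of Z is the PofO score `po` (positive = paternally biased);
  `po_z` is its cluster-robust z-score. `|po_z| > 3` flags significance
  and `|po| > 3` a strong effect — at least exp(3) ≈ 20-fold between the
  alleles.
* **Simulation** — a generator that writes complete synthetic datasets
  (count tables, VCFs, maternal VCFs, GTF, sample sheet, truth JSON) with
  known PofO effects, genetic effects, subject correlation,
  overdispersion and contamination, so every stage is testable without
  external data.

## Worked example

Simulate 15 subjects and four genes with true PofO effects
(0, 0, 1.5, 3.2) and 2% contamination, then run the full pipeline:

```r
library(asepo)

cfg <- sim_config(n_subjects = 15, n_genes = 4, snps_per_gene = 3,
                  po_true = c(0, 0, 1.5, 3.2), contamination = 0.02,
                  n_hom_sites = 100, seed = 42)
sim <- simulate_dataset(cfg, "ase-demo")

run_all(list(sample_sheet = sim$sample_sheet, gtf = sim$gtf,
             outdir = "ase-demo/results",
             filter = list(require_phased = TRUE)))

readr::read_tsv("ase-demo/results/pofo_results.tsv")
```

The per-gene results recover the simulated truth:

```
  gene_id     po  po_se   po_z n_subjects n_snps                class
1    G001 0.0495 0.1094  0.453         14      3      not_significant
2    G002 0.0133 0.0821  0.161         11      3      not_significant
3    G003 1.5752 0.0934 16.857         14      3 significant_paternal
4    G004 3.3154 0.1674 19.803         14      3      strong_paternal
```

The two null genes sit at `po ≈ 0`; the gene simulated at 1.5 is
significantly paternally biased (exp(1.58) ≈ 4.8-fold); the gene at 3.2
crosses the strong-effect bar (exp(3.32) ≈ 28-fold). The injected 2%
contamination is recovered in `contamination_sample.tsv`:

```
  sample_id est_homalt est_ref n_sites_homalt n_sites_ref
1      S001      0.018   0.018             46          54
2      S002      0.023   0.014             46          54
3      S003      0.017   0.019             48          52
```

and `filter_report.tsv` accounts for every row (here 1589 in, 89
retained for testing, 1500 unphased homozygous marker rows removed from
the phased subset).

A thin CLI over the same functions lives at `inst/cli/asepo.R`
(subcommands `simulate`, `ingest`, `annotate`, `contam`, `filter`,
`pofo`, `summarize`, `run-all`).

See `vignettes/parent-of-origin-testing.Rmd` for the model, its
assumptions, the numerical choices, and what the simulator does and does
not emulate.

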