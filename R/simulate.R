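# Synthetic ASE dataset generator.
#
# Emits exactly the formats the ingestion layer consumes — per-sample
# per-strand ASEReadCounter count tables, per-sample phased VCFs,
# maternal VCFs, a GTF with two isoforms per gene (so union-exon merging
# is exercised), and a sample sheet — plus a ground-truth object for
# recovery tests.

#' Simulation configuration
#'
#' Allele counts for a heterozygous (subject i, SNP j) pair in gene g are
#' drawn with means
#' `exp(mu0 + e_i + d_j + po_true_g/2 + b_j * x_pat)` (paternal) and
#' `exp(mu0 + e_i + d_j - po_true_g/2 + b_j * x_mat)` (maternal), where
#' `e_i ~ N(0, subject_sd)` is a subject random effect shared across all
#' of a subject's rows (the within-cluster correlation the sandwich must
#' absorb), `b_j ~ N(0, genetic_sd)` is a per-SNP ref-vs-alt genetic ASE
#' effect, `d_j ~ N(0, depth_sd)` a per-SNP log-normal depth offset, and
#' `x` is +1/2 on the ref allele. Defaults give a median total depth of
#' about 50 reads per SNP. Counts are Poisson or negative binomial
#' (size `theta`; Poisson recovered as `theta -> Inf`).
#'
#' Homozygous "marker" sites (genotyped hom-ref or hom-alt, sequenced
#' error-free) are emitted for contamination estimation; each subject's
#' simulated mother is the opposite homozygote at a marker with
#' probability `maternal_divergence` (marker genotypes are drawn
#' independently of the child — Mendelian transmission is deliberately
#' not enforced there, so the injected contamination fraction is fully
#' identifiable by the estimators).
#'
#' @param n_subjects,n_genes,snps_per_gene Dataset dimensions.
#' @param het_prob Probability a subject is heterozygous at a SNP.
#' @param phase_orientation_prob Probability the paternal allele is the
#'   reference allele at a het SNP.
#' @param baseline_log_mean `mu0`, log mean allele count.
#' @param subject_sd,genetic_sd,depth_sd Standard deviations of `e_i`,
#'   `b_j`, `d_j`.
#' @param po_true Per-gene parent-of-origin effect (log scale); recycled
#'   to `n_genes`.
#' @param dispersion `"poisson"` or `"negbin"`.
#' @param theta Negative-binomial size parameter (required for negbin).
#' @param contamination Contamination fraction `c` in `[0, 1]`, injected
#'   at marker sites with the mother as contaminant.
#' @param n_hom_sites Homozygous marker sites per sample (spread across
#'   genes' exons).
#' @param hom_depth Mean read depth at marker sites.
#' @param maternal_divergence Probability the mother is the opposite
#'   homozygote at a marker site.
#' @param seed RNG seed; the whole dataset is reproducible bit-for-bit
#'   from the configuration and seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 20L, n_genes = 10L, snps_per_gene = 4L,
                       het_prob = 0.5, phase_orientation_prob = 0.5,
                       baseline_log_mean = log(25), subject_sd = 0.3,
                       genetic_sd = 0.5, depth_sd = 0.5, po_true = 0,
                       dispersion = c("poisson", "negbin"), theta = NULL,
                       contamination = 0, n_hom_sites = 200L,
                       hom_depth = 80, maternal_divergence = 1,
                       seed = 1L) {
  dispersion <- match.arg(dispersion)
  stopifnot(
    n_subjects >= 1L, n_genes >= 1L, snps_per_gene >= 1L,
    snps_per_gene <= 24L,
    het_prob >= 0, het_prob <= 1,
    phase_orientation_prob >= 0, phase_orientation_prob <= 1,
    subject_sd >= 0, genetic_sd >= 0, depth_sd >= 0,
    contamination >= 0, contamination <= 1,
    maternal_divergence >= 0, maternal_divergence <= 1,
    n_hom_sites >= 0L, hom_depth > 0
  )
  if (dispersion == "negbin" && (is.null(theta) || theta <= 0)) {
    stop("negbin dispersion requires theta > 0", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_genes = as.integer(n_genes),
         snps_per_gene = as.integer(snps_per_gene), het_prob = het_prob,
         phase_orientation_prob = phase_orientation_prob,
         baseline_log_mean = baseline_log_mean, subject_sd = subject_sd,
         genetic_sd = genetic_sd, depth_sd = depth_sd,
         po_true = rep_len(po_true, n_genes), dispersion = dispersion,
         theta = theta, contamination = contamination,
         n_hom_sites = as.integer(n_hom_sites), hom_depth = hom_depth,
         maternal_divergence = maternal_divergence, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# set the RNG seed for the calling function's lifetime, restoring the
# caller's RNG state on exit (same defer idiom withr uses)
local_seed <- function(seed, envir = parent.frame()) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  restore <- function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
  do.call(on.exit, list(as.call(list(restore)), TRUE), envir = envir)
  set.seed(seed)
  invisible(NULL)
}

sim_gene_layout <- function(cfg) {
  g <- seq_len(cfg$n_genes)
  base <- 100000L * g
  tibble::tibble(
    gene_id = sprintf("G%03d", g),
    symbol = sprintf("SIM%03d", g),
    strand = ifelse(g %% 2L == 1L, "+", "-"),
    contig = "chr1",
    base = base
  )
}

sim_snp_layout <- function(cfg, genes) {
  # SNPs live in the second merged exon [base+2000, base+2999]
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    tibble::tibble(
      gene_id = genes$gene_id[i],
      position = genes$base[i] + 2000L + (seq_len(cfg$snps_per_gene) - 1L) * 40L
    )
  })
}

sim_marker_layout <- function(cfg, genes) {
  # homozygous marker sites live in the third exon [base+4000, base+4999]
  if (cfg$n_hom_sites == 0L) {
    return(tibble::tibble(gene_id = character(), position = integer()))
  }
  # spread evenly over genes; every gene gets the same number of markers
  per_gene <- min(ceiling(cfg$n_hom_sites / cfg$n_genes), 330L)
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    tibble::tibble(
      gene_id = genes$gene_id[i],
      position = genes$base[i] + 4000L + (seq_len(per_gene) - 1L) * 3L
    )
  })
}

draw_counts <- function(n, mu, cfg) {
  if (cfg$dispersion == "poisson") rpois(n, mu) else rnbinom(n, mu = mu, size = cfg$theta)
}

#' Simulate a complete synthetic ASE dataset
#'
#' Writes per-sample forward/reverse ASEReadCounter-format count tables,
#' phased per-sample VCFs, maternal VCFs, a two-isoform-per-gene GTF, a
#' sample sheet, and `truth.json`, all under `dir`. Counts of a gene are
#' emitted on the file matching the gene's strand so the strand-aware
#' annotation join is exercised. The first phased VCF allele is the
#' paternal allele (the `first_is_paternal` convention).
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `sample_sheet`, `gtf`, `truth`
#'   (the in-memory ground truth), and `counts` (the unified count
#'   tibble as emitted, post contamination injection).
#' @export
simulate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE)

  genes <- sim_gene_layout(cfg)
  snps <- sim_snp_layout(cfg, genes)
  markers <- sim_marker_layout(cfg, genes)
  subjects <- sprintf("S%03d", seq_len(cfg$n_subjects))
  e_i <- setNames(rnorm(cfg$n_subjects, 0, cfg$subject_sd), subjects)

  snps$b <- rnorm(nrow(snps), 0, cfg$genetic_sd)
  snps$depth_offset <- rnorm(nrow(snps), 0, cfg$depth_sd)
  po_by_gene <- setNames(cfg$po_true, genes$gene_id)

  # heterozygous SNP rows
  grid <- tidyr::expand_grid(sample_id = subjects,
                             snp_idx = seq_len(nrow(snps)))
  grid$gene_id <- snps$gene_id[grid$snp_idx]
  grid$position <- snps$position[grid$snp_idx]
  grid$b <- snps$b[grid$snp_idx]
  grid$depth_offset <- snps$depth_offset[grid$snp_idx]
  grid$het <- runif(nrow(grid)) < cfg$het_prob
  grid$paternal_is_ref <- runif(nrow(grid)) < cfg$phase_orientation_prob

  het <- grid[grid$het, , drop = FALSE]
  if (nrow(het) > 0L) {
    x_pat <- ifelse(het$paternal_is_ref, 0.5, -0.5)
    base_log <- cfg$baseline_log_mean + e_i[het$sample_id] + het$depth_offset
    mu_pat <- exp(base_log + po_by_gene[het$gene_id] / 2 + het$b * x_pat)
    mu_mat <- exp(base_log - po_by_gene[het$gene_id] / 2 - het$b * x_pat)
    het$pat_count <- draw_counts(nrow(het), mu_pat, cfg)
    het$mat_count <- draw_counts(nrow(het), mu_mat, cfg)
    het$ref_count <- as.integer(ifelse(het$paternal_is_ref, het$pat_count,
                                       het$mat_count))
    het$alt_count <- as.integer(ifelse(het$paternal_is_ref, het$mat_count,
                                       het$pat_count))
  }

  # homozygous marker rows (error-free)
  mgrid <- tidyr::expand_grid(sample_id = subjects,
                              marker_idx = seq_len(nrow(markers)))
  if (nrow(mgrid) > 0L) {
    mgrid$gene_id <- markers$gene_id[mgrid$marker_idx]
    mgrid$position <- markers$position[mgrid$marker_idx]
    mgrid$gclass <- ifelse(runif(nrow(mgrid)) < 0.5, "hom_ref", "hom_alt")
    mgrid$depth <- rpois(nrow(mgrid), cfg$hom_depth)
    mgrid$ref_count <- as.integer(ifelse(mgrid$gclass == "hom_ref",
                                         mgrid$depth, 0L))
    mgrid$alt_count <- as.integer(mgrid$depth - mgrid$ref_count)
    opposite <- runif(nrow(mgrid)) < cfg$maternal_divergence
    mgrid$maternal_gclass <- ifelse(
      opposite,
      ifelse(mgrid$gclass == "hom_ref", "hom_alt", "hom_ref"),
      mgrid$gclass
    )
  }

  strand_of_gene <- setNames(genes$strand, genes$gene_id)
  make_rows <- function(df) {
    tibble::tibble(
      sample_id = df$sample_id,
      contig = "chr1",
      position = df$position,
      variant_id = paste0("chr1_", df$position),
      ref_allele = "A",
      alt_allele = "G",
      ref_count = df$ref_count,
      alt_count = df$alt_count,
      total_count = df$ref_count + df$alt_count,
      other_bases = 0L,
      strand_label = ifelse(strand_of_gene[df$gene_id] == "+",
                            "forward", "reverse")
    )
  }
  pieces <- list()
  if (nrow(het) > 0L) pieces <- c(pieces, list(make_rows(het)))
  if (nrow(mgrid) > 0L) pieces <- c(pieces, list(make_rows(mgrid)))
  counts <- concat_counts(pieces)

  if (cfg$contamination > 0 && nrow(mgrid) > 0L) {
    mom_map <- tibble::tibble(
      sample_id = mgrid$sample_id, contig = "chr1",
      position = mgrid$position, gclass = mgrid$maternal_gclass
    )
    counts <- inject_contamination(counts, cfg$contamination, mom_map)
  }

  # ---- write count tables ----
  sheet_rows <- lapply(subjects, function(s) {
    fwd_path <- file.path("counts", paste0(s, "_fwd.tsv"))
    rev_path <- file.path("counts", paste0(s, "_rev.tsv"))
    sub <- counts[counts$sample_id == s, ]
    write_aserc(sub[sub$strand_label == "forward", ], file.path(dir, fwd_path))
    write_aserc(sub[sub$strand_label == "reverse", ], file.path(dir, rev_path))
    tibble::tibble(sample_id = s, count_file_forward = fwd_path,
                   count_file_reverse = rev_path,
                   vcf_file = file.path("vcf", paste0(s, ".vcf")),
                   maternal_vcf_file = file.path("vcf", paste0(s, ".mother.vcf")))
  })
  sheet <- dplyr::bind_rows(sheet_rows)

  # ---- write VCFs ----
  for (s in subjects) {
    het_s <- het[het$sample_id == s, , drop = FALSE]
    vcf_rows <- tibble::tibble(
      position = het_s$position,
      gt = ifelse(het_s$paternal_is_ref, "0|1", "1|0")
    )
    mom_rows <- NULL
    if (nrow(mgrid) > 0L) {
      mg_s <- mgrid[mgrid$sample_id == s, , drop = FALSE]
      vcf_rows <- dplyr::bind_rows(
        vcf_rows,
        tibble::tibble(position = mg_s$position,
                       gt = ifelse(mg_s$gclass == "hom_ref", "0/0", "1/1"))
      )
      mom_rows <- tibble::tibble(
        position = mg_s$position,
        gt = ifelse(mg_s$maternal_gclass == "hom_ref", "0/0", "1/1")
      )
    }
    write_sim_vcf(vcf_rows, s, file.path(dir, "vcf", paste0(s, ".vcf")))
    write_sim_vcf(mom_rows %||% vcf_rows[0, ], paste0(s, "_mother"),
                  file.path(dir, "vcf", paste0(s, ".mother.vcf")))
  }

  write_sim_gtf(cfg, genes, file.path(dir, "annotation.gtf"))
  readr::write_csv(sheet, file.path(dir, "sample_sheet.csv"), progress = FALSE)

  truth <- list(
    config = unclass(cfg),
    genes = tibble::tibble(gene_id = genes$gene_id, strand = genes$strand,
                           po_true = unname(po_by_gene[genes$gene_id])),
    snps = snps,
    subjects = tibble::tibble(sample_id = subjects, e = unname(e_i)),
    contamination = cfg$contamination,
    phase = tibble::tibble(
      sample_id = grid$sample_id, gene_id = grid$gene_id,
      position = grid$position, het = grid$het,
      paternal_allele = ifelse(!grid$het, NA_character_,
                               ifelse(grid$paternal_is_ref, "ref", "alt"))
    )
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(dir = dir, sample_sheet = file.path(dir, "sample_sheet.csv"),
                 gtf = file.path(dir, "annotation.gtf"), truth = truth,
                 counts = counts))
}

write_aserc <- function(rows, path) {
  out <- tibble::tibble(
    contig = rows$contig, position = rows$position,
    variantID = rows$variant_id, refAllele = rows$ref_allele,
    altAllele = rows$alt_allele, refCount = rows$ref_count,
    altCount = rows$alt_count, totalCount = rows$total_count,
    lowMAPQDepth = 0L, lowBaseQDepth = 0L,
    rawDepth = rows$total_count, otherBases = rows$other_bases,
    improperPairs = 0L
  )
  out <- dplyr::arrange(out, .data$contig, .data$position)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

write_sim_vcf <- function(rows, sample_name, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  rows <- rows[order(rows$position), , drop = FALSE]
  body <- if (nrow(rows) > 0L) {
    paste("chr1", rows$position, paste0("chr1_", rows$position), "A", "G",
          ".", "PASS", ".", "GT", rows$gt, sep = "\t")
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

write_sim_gtf <- function(cfg, genes, path) {
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    b <- genes$base[i]; gid <- genes$gene_id[i]
    sym <- genes$symbol[i]; strand <- genes$strand[i]
    attr1 <- function(tid) {
      sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "protein_coding";',
              gid, tid, sym)
    }
    # transcript 1: three exons; transcript 2 overlaps/extends exon 1 so
    # the union merge is non-trivial
    ex <- rbind(
      c(b, b + 999L, 1L), c(b + 2000L, b + 2999L, 1L),
      c(b + 4000L, b + 4999L, 1L),
      c(b + 500L, b + 1499L, 2L), c(b + 2000L, b + 2999L, 2L)
    )
    for (r in seq_len(nrow(ex))) {
      tid <- paste0(gid, ".t", ex[r, 3L])
      lines <- c(lines, paste("chr1", "sim", "exon", ex[r, 1L], ex[r, 2L],
                              ".", strand, ".", attr1(tid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Inject cross-sample contamination into a count table
#'
#' For each count record with a known contaminant genotype, a
#' `Binomial(total_count, c)` subset of the reads is drawn uniformly at
#' random (hypergeometric over the current ref/alt composition) and
#' re-labelled according to the contaminant's genotype allele profile:
#' hom-ref contaminant reads become ref, hom-alt become alt, het split
#' 50/50. Per-site totals are conserved exactly.
#'
#' @param counts Unified count tibble.
#' @param c Contamination fraction in `[0, 1]`.
#' @param contaminant_genotypes Tibble with `sample_id`, `contig`,
#'   `position`, `gclass` describing the contaminant at each site;
#'   records without a matching entry are untouched.
#' @param seed Optional RNG seed for reproducible injection.
#' @return The count tibble with relabelled reads.
#' @export
inject_contamination <- function(counts, c, contaminant_genotypes,
                                 seed = NULL) {
  stopifnot(c >= 0, c <= 1)
  if (!is.null(seed)) local_seed(seed)
  if (c == 0 || nrow(counts) == 0L) return(counts)
  key <- paste(counts$sample_id, counts$contig, counts$position, sep = "\r")
  ckey <- paste(contaminant_genotypes$sample_id, contaminant_genotypes$contig,
                contaminant_genotypes$position, sep = "\r")
  idx <- match(key, ckey)
  hit <- which(!is.na(idx) & counts$total_count > 0L)
  if (length(hit) == 0L) return(counts)
  gclass <- contaminant_genotypes$gclass[idx[hit]]
  total <- counts$total_count[hit]
  ref <- counts$ref_count[hit]
  alt <- counts$alt_count[hit]
  n_cont <- rbinom(length(hit), total, c)
  # reads to relabel, drawn uniformly from the current composition
  removed_ref <- rhyper(length(hit), ref, alt, n_cont)
  cont_ref <- ifelse(gclass == "hom_ref", n_cont,
                     ifelse(gclass == "hom_alt", 0L,
                            rbinom(length(hit), n_cont, 0.5)))
  counts$ref_count[hit] <- as.integer(ref - removed_ref + cont_ref)
  counts$alt_count[hit] <- as.integer(alt - (n_cont - removed_ref) +
                                        (n_cont - cont_ref))
  counts$total_count[hit] <- as.integer(counts$ref_count[hit] +
                                          counts$alt_count[hit])
  counts
}
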