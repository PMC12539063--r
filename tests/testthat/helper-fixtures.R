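# Fixture builders shared across the suite. Everything is generated in
# code at test time; nothing is stored on disk.

aserc_header <- paste(
  "contig", "position", "variantID", "refAllele", "altAllele", "refCount",
  "altCount", "totalCount", "lowMAPQDepth", "lowBaseQDepth", "rawDepth",
  "otherBases", "improperPairs", sep = "\t"
)

# write an ASEReadCounter-format file from a minimal description of rows
write_aserc_fixture <- function(rows, path = tempfile(fileext = ".tsv"),
                                header = aserc_header) {
  lines <- header
  for (r in seq_len(nrow(rows))) {
    x <- rows[r, ]
    total <- if (!is.null(x$totalCount)) x$totalCount else x$refCount + x$altCount
    other <- if (!is.null(x$otherBases)) x$otherBases else 0L
    lines <- c(lines, paste(
      x$contig, x$position, x$variantID %||% paste0(x$contig, "_", x$position),
      x$refAllele %||% "A", x$altAllele %||% "G", x$refCount, x$altCount,
      total, 0L, 0L, total, other, 0L, sep = "\t"
    ))
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# write a small single-sample VCF from (pos, gt) pairs
write_vcf_fixture <- function(pos, gt, sample = "S1",
                              path = tempfile(fileext = ".vcf"),
                              alt = rep("G", length(pos))) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  body <- paste("chr1", pos, ".", "A", alt, ".", "PASS", ".", "GT", gt,
                sep = "\t")
  writeLines(c(header, body), path)
  path
}

# write a GTF of exon features; `exons` has columns gene_id, start, end,
# and optionally strand / transcript_id / contig
write_gtf_fixture <- function(exons,
                              path = tempfile(fileext = ".gtf")) {
  strand <- exons$strand %||% rep("+", nrow(exons))
  tid <- exons$transcript_id %||% paste0(exons$gene_id, ".t1")
  contig <- exons$contig %||% rep("chr1", nrow(exons))
  lines <- vapply(seq_len(nrow(exons)), function(i) {
    paste(contig[i], "test", "exon", exons$start[i], exons$end[i], ".",
          strand[i], ".",
          sprintf('gene_id "%s"; transcript_id "%s";',
                  exons$gene_id[i], tid[i]),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  path
}

# brute-force union of 1-based inclusive intervals: mark every covered
# base, extract maximal runs
per_base_union <- function(start, end) {
  lo <- min(start)
  covered <- logical(max(end) - lo + 1L)
  for (i in seq_along(start)) {
    covered[(start[i] - lo + 1L):(end[i] - lo + 1L)] <- TRUE
  }
  r <- rle(covered)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] + lo - 1L, end = stops[keep] + lo - 1L)
}

# phased per-gene site table generated directly (independently of the
# package's file-emitting simulator) for regression-fit tests
make_gene_sites <- function(n_subjects, n_snps, po = 0, mu0 = log(25),
                            subject_sd = 0.3, b = rep(0, n_snps),
                            gene_id = "g1", het_prob = 1) {
  grid <- expand.grid(s = seq_len(n_subjects), j = seq_len(n_snps))
  grid <- grid[runif(nrow(grid)) < het_prob, , drop = FALSE]
  e <- rnorm(n_subjects, 0, subject_sd)
  pat_ref <- runif(nrow(grid)) < 0.5
  x_pat <- ifelse(pat_ref, 0.5, -0.5)
  mu_pat <- exp(mu0 + e[grid$s] + po / 2 + b[grid$j] * x_pat)
  mu_mat <- exp(mu0 + e[grid$s] - po / 2 - b[grid$j] * x_pat)
  pat <- rpois(nrow(grid), mu_pat)
  mat <- rpois(nrow(grid), mu_mat)
  tibble::tibble(
    gene_id = gene_id,
    sample_id = sprintf("S%03d", grid$s),
    contig = "chr1",
    position = 1000L + grid$j,
    variant_id = paste0("chr1_", 1000L + grid$j),
    ref_allele = "A", alt_allele = "G",
    ref_count = as.integer(ifelse(pat_ref, pat, mat)),
    alt_count = as.integer(ifelse(pat_ref, mat, pat)),
    other_bases = 0L,
    strand_label = "forward",
    paternal_allele = ifelse(pat_ref, "ref", "alt")
  ) |>
    dplyr::mutate(total_count = ref_count + alt_count)
}

# independent Poisson MLE via a generic optimizer on the kept columns
optim_poisson_mle <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(exp(eta) - y * eta)
  }
  grad <- function(b) {
    eta <- drop(X %*% b)
    drop(crossprod(X, exp(eta) - y))
  }
  o <- stats::optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-16))
  # BFGS stalls around 1e-5 gradient norm; polish to machine precision
  # with Newton steps computed directly from the likelihood
  b <- o$par
  for (it in 1:50) {
    g <- grad(b)
    if (max(abs(g)) < 1e-10) break
    H <- crossprod(X, X * exp(drop(X %*% b)))
    b <- b - solve(H, g)
  }
  b
}

# rebuild the model matrix of a pofo_design restricted to the fit's kept
# columns (for oracle comparisons)
design_model_matrix <- function(design, kept) {
  q <- design$q
  X <- cbind(1, design$z, design$x, design$v, design$v * design$x)
  colnames(X) <- c("(Intercept)", "z", "x",
                   if (q > 0) paste0("v", seq_len(q)),
                   if (q > 0) paste0("v", seq_len(q), ":x"))
  X[, kept, drop = FALSE]
}
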