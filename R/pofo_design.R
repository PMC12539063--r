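# Per-gene regression design for the parent-of-origin test.
#
# Observation layout: for a gene with m distinct SNPs, every
# (subject, SNP) pair contributes two rows, one per allele — the
# reference-allele row (x = +1/2) carries the ref read count, the
# alternative-allele row (x = -1/2) the alt count. z is +1/2 on the
# paternal-allele row and -1/2 on the maternal one.

untestable_condition <- function(reason, gene_id = NA_character_) {
  structure(
    class = c("asepo_untestable", "error", "condition"),
    list(message = paste0("gene ", gene_id, " untestable: ", reason),
         call = NULL, reason = reason, gene_id = gene_id)
  )
}

#' Build the per-gene design for parent-of-origin testing
#'
#' Expands filtered, phased heterozygous SNP rows of one gene into the
#' two-rows-per-(subject, SNP) allele-count design: counts `y`, parental
#' origin `z` (+1/2 paternal, -1/2 maternal), ref/alt status `x` (+1/2
#' ref, -1/2 alt), the SNP indicator matrix `u`, its SVD reduction `v`
#' (see [reduce_indicators()]), and subject cluster labels.
#'
#' @param gene_sites Phased annotated rows of a single gene
#'   (`paternal_allele` must be `"ref"` or `"alt"` everywhere).
#' @param combine_strands Sum ref/alt counts over `strand_label` per
#'   (sample, SNP) before building rows (default TRUE: the test is per
#'   gene, not per strand).
#' @param rel_threshold Relative singular-value threshold passed to
#'   [reduce_indicators()].
#' @return A `pofo_design` list: `gene_id`, `y`, `z`, `x`, `u`, `v`, `q`,
#'   `m`, `clusters`, `snp_ids`.
#' @export
build_design <- function(gene_sites, combine_strands = TRUE,
                         rel_threshold = 0.01) {
  gene_id <- unique(gene_sites$gene_id)
  if (length(gene_id) != 1L) {
    stop("build_design() expects rows from exactly one gene", call. = FALSE)
  }
  ok <- gene_sites$paternal_allele %in% c("ref", "alt")
  gene_sites <- gene_sites[ok, , drop = FALSE]
  if (nrow(gene_sites) == 0L) {
    stop(untestable_condition("no_phased_snps", gene_id))
  }
  if (combine_strands) {
    gene_sites <- dplyr::summarise(
      dplyr::group_by(gene_sites, .data$sample_id, .data$contig,
                      .data$position, .data$paternal_allele),
      ref_count = sum(.data$ref_count), alt_count = sum(.data$alt_count),
      .groups = "drop"
    )
  }
  snp_id <- paste0(gene_sites$contig, ":", gene_sites$position)
  snp_ids <- sort(unique(snp_id))
  m <- length(snp_ids)
  n_pairs <- nrow(gene_sites)

  # interleave ref row then alt row per (subject, SNP)
  y <- as.integer(rbind(gene_sites$ref_count, gene_sites$alt_count))
  x <- rep(c(0.5, -0.5), n_pairs)
  z_ref <- ifelse(gene_sites$paternal_allele == "ref", 0.5, -0.5)
  z <- as.numeric(rbind(z_ref, -z_ref))
  clusters <- rep(gene_sites$sample_id, each = 2L)
  snp_of_row <- rep(match(snp_id, snp_ids), each = 2L)

  u <- matrix(0, nrow = 2L * n_pairs, ncol = m)
  u[cbind(seq_len(2L * n_pairs), snp_of_row)] <- 1
  red <- reduce_indicators(u, rel_threshold)

  structure(
    list(gene_id = gene_id, y = y, z = z, x = x, u = u, v = red$v,
         q = red$q, m = m, clusters = clusters, snp_ids = snp_ids),
    class = "pofo_design"
  )
}

#' SVD reduction of the SNP indicator matrix
#'
#' Replaces the N x m SNP indicator matrix by the left singular vectors
#' whose singular values are at least `rel_threshold` times the largest
#' singular value ("at least" is inclusive, so ties at the threshold are
#' kept). For a disjoint indicator matrix the singular values are the
#' square roots of the per-SNP row counts, so the rule drops directions
#' supported by vanishingly few observations.
#'
#' @param u Indicator matrix (each row one 1).
#' @param rel_threshold Relative singular-value cutoff (default 0.01).
#' @return A list: `v` (N x q orthonormal columns), `q`, and
#'   `singular_values`.
#' @export
reduce_indicators <- function(u, rel_threshold = 0.01) {
  stopifnot(is.matrix(u), nrow(u) > 0L, ncol(u) > 0L)
  s <- svd(u)
  keep <- s$d >= rel_threshold * max(s$d) & s$d > 0
  list(v = s$u[, keep, drop = FALSE], q = sum(keep), singular_values = s$d)
}

#' @export
print.pofo_design <- function(x, ...) {
  cat("<pofo_design> gene ", x$gene_id, ": N=", length(x$y),
      " obs, m=", x$m, " SNP(s), q=", x$q, ", ",
      length(unique(x$clusters)), " subject(s)\n", sep = "")
  invisible(x)
}
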