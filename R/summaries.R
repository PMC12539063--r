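# Plot-ready summary tables: gene-level paternal allele frequency and
# per-gene SNP tracks with merged-exon boundaries.

#' Gene-level paternal allele frequency per sample
#'
#' Sums paternal and total counts over a gene's exonic SNPs for each
#' sample and takes the ratio of the sums — a pooled ratio, deliberately
#' not the mean of per-SNP ratios, so deep SNPs carry their full weight.
#' Counts on both strands of a SNP are pooled by the same summation.
#'
#' @param sites Filtered, phased annotated site tibble; rows without an
#'   assigned paternal allele are ignored.
#' @return Tibble with `gene_id`, `sample_id`, `paternal_sum`,
#'   `total_sum`, `gene_paternal_freq`, `n_snps`. Gene-sample pairs with
#'   no data are absent.
#' @export
gene_level_paternal_frequency <- function(sites) {
  phased <- sites[!is.na(sites$paternal_allele) &
                    sites$paternal_allele %in% c("ref", "alt") &
                    !is.na(sites$gene_id), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(phased, .data$gene_id, .data$sample_id),
    paternal_sum = sum(.data$paternal_count),
    total_sum = sum(.data$total_count),
    n_snps = dplyr::n_distinct(paste(.data$contig, .data$position)),
    .groups = "drop"
  )
  out$gene_paternal_freq <- ifelse(out$total_sum > 0,
                                   out$paternal_sum / out$total_sum, NA_real_)
  out[c("gene_id", "sample_id", "paternal_sum", "total_sum",
        "gene_paternal_freq", "n_snps")]
}

#' SNP-level plot data for one gene
#'
#' Per (SNP, sample) paternal allele frequencies with the gene's merged
#' exon boundary coordinates, plus an optional highlighted sample's SNP
#' count and median frequency.
#'
#' @param gene_id Gene to extract.
#' @param sites Filtered, phased annotated site tibble.
#' @param models A `gene_models` object containing the gene.
#' @param highlight_sample Optional sample_id to summarise.
#' @return A list: `snps` (tibble sample_id / contig / position /
#'   paternal_freq), `exon_boundaries` (1-based start and end of every
#'   merged exon, 2 coordinates per exon), and `highlight` (`NULL`, or a
#'   list with `sample_id`, `n_snps`, `median_freq` — `median_freq` is
#'   `NA` when the sample has no data).
#' @export
snp_plot_data <- function(gene_id, sites, models, highlight_sample = NULL) {
  if (!gene_id %in% models$genes$gene_id) {
    stop("unknown gene: ", gene_id, call. = FALSE)
  }
  gene_sites <- sites[!is.na(sites$gene_id) & sites$gene_id == gene_id &
                        !is.na(sites$paternal_freq), , drop = FALSE]
  snps <- dplyr::summarise(
    dplyr::group_by(gene_sites, .data$sample_id, .data$contig, .data$position),
    paternal_freq = sum(.data$paternal_count) / sum(.data$total_count),
    .groups = "drop"
  )
  exons <- models$exons[[gene_id]]
  boundaries <- sort(c(BiocGenerics::start(exons), BiocGenerics::end(exons)))
  highlight <- NULL
  if (!is.null(highlight_sample)) {
    hs <- snps[snps$sample_id == highlight_sample, ]
    highlight <- list(
      sample_id = highlight_sample,
      n_snps = nrow(hs),
      median_freq = if (nrow(hs) > 0L) median(hs$paternal_freq) else NA_real_
    )
  }
  list(snps = snps, exon_boundaries = boundaries, highlight = highlight)
}

#' Plot SNP-level paternal allele frequencies along a gene
#'
#' Thin ggplot2 layer over [snp_plot_data()]: one point per SNP per
#' sample with vertical lines at the merged exon boundaries. Requires
#' ggplot2; the tables, not the image, are the tested contract.
#'
#' @inheritParams snp_plot_data
#' @return A ggplot object.
#' @export
plot_gene_snps <- function(gene_id, sites, models, highlight_sample = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_gene_snps() requires the ggplot2 package", call. = FALSE)
  }
  pd <- snp_plot_data(gene_id, sites, models, highlight_sample)
  p <- ggplot2::ggplot(pd$snps,
                       ggplot2::aes(x = .data$position, y = .data$paternal_freq)) +
    ggplot2::geom_vline(xintercept = pd$exon_boundaries,
                        linetype = "dashed", colour = "grey70") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(title = gene_id, x = "position",
                  y = "paternal allele frequency")
  if (!is.null(highlight_sample)) {
    p <- p + ggplot2::geom_point(
      data = pd$snps[pd$snps$sample_id == highlight_sample, ],
      colour = "red", size = 2
    )
  }
  p
}
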