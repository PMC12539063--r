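# Contamination estimation from opposite-allele reads at homozygous and
# reference sites.

#' Per-site opposite-allele frequency
#'
#' At a homozygous site, reads carrying any base other than the genotyped
#' allele point at cross-sample contamination (or mislabeling). For a
#' `hom_alt` site the opposite-allele frequency is
#' `(ref + other) / (ref + alt + other)`; for a `hom_ref` site it is
#' `(alt + other) / (ref + alt + other)`. `other_bases` enter both
#' numerator and denominator because contaminant reads need not carry the
#' on-panel alternate base. Sites below `min_depth` are undefined (`NA`).
#'
#' @param ref_count,alt_count,other_bases Integer vectors of per-site counts.
#' @param gclass Character vector, each `"hom_ref"` or `"hom_alt"`;
#'   heterozygous input is a contract error.
#' @param min_depth Minimum `ref + alt + other` depth for a defined value.
#' @return Numeric vector of frequencies in `[0, 1]`, `NA` where undefined.
#' @export
site_opposite_freq <- function(ref_count, alt_count, other_bases, gclass,
                               min_depth = 10L) {
  if (any(!gclass %in% c("hom_ref", "hom_alt"))) {
    stop("site_opposite_freq() is defined for homozygous sites only",
         call. = FALSE)
  }
  denom <- ref_count + alt_count + other_bases
  num <- ifelse(gclass == "hom_alt", ref_count + other_bases,
                alt_count + other_bases)
  ifelse(denom < min_depth, NA_real_, num / denom)
}

pool_site_strands <- function(sites, extra_keys = character(0)) {
  dplyr::summarise(
    dplyr::group_by(sites, dplyr::across(dplyr::all_of(
      c("sample_id", "contig", "position", "gclass", extra_keys)))),
    ref_count = sum(.data$ref_count),
    alt_count = sum(.data$alt_count),
    other_bases = sum(.data$other_bases),
    .groups = "drop"
  )
}

#' Per-sample contamination estimates
#'
#' Computes, per sample, the unweighted mean opposite-allele frequency
#' over homozygous-alt sites (`est_homalt`, the non-alternative-allele
#' frequency) and over homozygous-ref sites (`est_ref`, the non-reference
#' -allele frequency). Counts are pooled across strands per site before
#' the frequency is taken (contamination is not strand-specific); the
#' mean is over sites, not pooled counts, so a single deep site cannot
#' dominate. An estimate is defined only when at least `min_sites` sites
#' pass `min_depth`.
#'
#' @param sites Annotated site tibble with `gclass` (hom rows used;
#'   het and genotype-less rows ignored).
#' @param min_depth Per-site depth threshold.
#' @param min_sites Minimum defined sites for a reported estimate.
#' @return Tibble with `sample_id`, `est_homalt`, `est_ref`,
#'   `n_sites_homalt`, `n_sites_ref`.
#' @export
sample_contamination <- function(sites, min_depth = 10L, min_sites = 5L) {
  hom <- sites[!is.na(sites$gclass) & sites$gclass %in% c("hom_ref", "hom_alt"), ]
  samples <- sort(unique(sites$sample_id))
  if (nrow(hom) == 0L) {
    return(tibble::tibble(sample_id = samples, est_homalt = NA_real_,
                          est_ref = NA_real_, n_sites_homalt = 0L,
                          n_sites_ref = 0L))
  }
  pooled <- pool_site_strands(hom)
  pooled$freq <- site_opposite_freq(pooled$ref_count, pooled$alt_count,
                                    pooled$other_bases, pooled$gclass,
                                    min_depth)
  est_one <- function(freqs) {
    freqs <- freqs[!is.na(freqs)]
    list(est = if (length(freqs) >= min_sites) mean(freqs) else NA_real_,
         n = length(freqs))
  }
  per_sample <- lapply(samples, function(s) {
    sub <- pooled[pooled$sample_id == s, ]
    ha <- est_one(sub$freq[sub$gclass == "hom_alt"])
    hr <- est_one(sub$freq[sub$gclass == "hom_ref"])
    tibble::tibble(sample_id = s, est_homalt = ha$est, est_ref = hr$est,
                   n_sites_homalt = ha$n, n_sites_ref = hr$n)
  })
  dplyr::bind_rows(per_sample)
}

#' Per-gene maternal contamination estimates
#'
#' For studies where maternal tissue contamination is a concern: at sites
#' where the offspring is homozygous-reference but the mother carries a
#' non-reference genotype (het or hom-alt), non-reference reads are
#' attributed to maternal contamination. The mean non-reference-allele
#' frequency over qualifying sites is reported per (sample, gene); genes
#' with no qualifying site are absent from the output.
#'
#' @param sites Annotated site tibble (must carry `gene_id` and `gclass`).
#' @param maternal_genotypes Genotype tibble from
#'   `ingest_genotypes(sheet, maternal = TRUE)`; samples absent from it
#'   are omitted (the operation is unavailable for them, not an error).
#' @param min_depth Per-site depth threshold.
#' @return Tibble with `sample_id`, `gene_id`, `est`, `n_sites`.
#' @export
gene_maternal_contamination <- function(sites, maternal_genotypes,
                                        min_depth = 10L) {
  empty <- tibble::tibble(sample_id = character(), gene_id = character(),
                          est = numeric(), n_sites = integer())
  if (is.null(maternal_genotypes) || nrow(maternal_genotypes) == 0L) {
    return(empty)
  }
  hom_ref <- sites[!is.na(sites$gclass) & sites$gclass == "hom_ref" &
                     !is.na(sites$gene_id), ]
  if (nrow(hom_ref) == 0L) return(empty)
  pooled <- pool_site_strands(hom_ref, extra_keys = "gene_id")
  mom <- dplyr::rename(
    maternal_genotypes[c("sample_id", "contig", "position", "gclass")],
    maternal_gclass = "gclass"
  )
  pooled <- dplyr::inner_join(pooled, mom,
                              by = c("sample_id", "contig", "position"))
  pooled <- pooled[pooled$maternal_gclass %in% c("het", "hom_alt"), ]
  if (nrow(pooled) == 0L) return(empty)
  pooled$freq <- site_opposite_freq(pooled$ref_count, pooled$alt_count,
                                    pooled$other_bases, pooled$gclass,
                                    min_depth)
  pooled <- pooled[!is.na(pooled$freq), ]
  if (nrow(pooled) == 0L) return(empty)
  dplyr::summarise(
    dplyr::group_by(pooled, .data$sample_id, .data$gene_id),
    est = mean(.data$freq), n_sites = dplyr::n(), .groups = "drop"
  )
}
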