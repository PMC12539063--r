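# Union-exon gene models and SNP annotation.

#' Build per-gene union-exon models from a GTF
#'
#' Collapses all isoform exons of each gene into its union exon set:
#' overlapping or book-ended exon intervals are merged into maximal
#' non-overlapping intervals. Gene strand and contig are taken from the
#' GTF exon records; genes whose exons span multiple contigs (or mix
#' strands) are skipped with a warning.
#'
#' @param gtf Path to a GTF file with `exon` features carrying `gene_id`
#'   (Ensembl/GENCODE attribute dialects: `gene_name`, and `gene_type` or
#'   `gene_biotype`, are picked up when present).
#' @return A `gene_models` object: a list with `genes` (a tibble of
#'   gene_id, symbol, gene_type, contig, strand, n_exons, exonic_bases)
#'   and `exons` (a `GRangesList` of merged exons, one element per gene,
#'   in genomic order).
#' @export
build_union_exons <- function(gtf) {
  if (!file.exists(gtf)) stop("GTF does not exist: ", gtf, call. = FALSE)
  gr <- tryCatch(
    rtracklayer::import(gtf, format = "gtf"),
    error = function(e) {
      stop("failed to parse GTF ", gtf, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  exons <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(exons) == 0L) stop("GTF contains no exon features: ", gtf, call. = FALSE)
  if (is.null(exons$gene_id) || anyNA(exons$gene_id)) {
    stop("GTF exon records lack gene_id attributes", call. = FALSE)
  }

  symbol <- exons$gene_name %||% exons$gene_id
  gtype <- exons$gene_type %||% exons$gene_biotype %||%
    rep(NA_character_, length(exons))

  meta <- tibble::tibble(
    gene_id = exons$gene_id,
    symbol = ifelse(is.na(symbol), exons$gene_id, symbol),
    gene_type = gtype,
    contig = as.character(GenomeInfoDb::seqnames(exons)),
    strand = as.character(BiocGenerics::strand(exons))
  )
  meta <- dplyr::distinct(meta)
  per_gene <- dplyr::summarise(
    dplyr::group_by(meta, .data$gene_id),
    symbol = .data$symbol[1L], gene_type = .data$gene_type[1L],
    n_contigs = dplyr::n_distinct(.data$contig),
    n_strands = dplyr::n_distinct(.data$strand),
    contig = .data$contig[1L], strand = .data$strand[1L],
    .groups = "drop"
  )
  bad <- per_gene$gene_id[per_gene$n_contigs > 1L | per_gene$n_strands > 1L]
  if (length(bad) > 0L) {
    warning("skipping ", length(bad),
            " gene(s) with exons on multiple contigs or strands: ",
            paste(utils::head(bad, 3L), collapse = ", "), call. = FALSE)
    exons <- exons[!exons$gene_id %in% bad]
    per_gene <- per_gene[!per_gene$gene_id %in% bad, ]
  }

  # min.gapwidth = 1 merges overlapping and book-ended intervals only
  merged <- IRanges::reduce(
    S4Vectors::split(GenomicRanges::granges(exons), exons$gene_id),
    min.gapwidth = 1L
  )
  merged <- merged[per_gene$gene_id]

  genes <- tibble::tibble(
    gene_id = per_gene$gene_id,
    symbol = per_gene$symbol,
    gene_type = per_gene$gene_type,
    contig = per_gene$contig,
    strand = per_gene$strand,
    n_exons = S4Vectors::elementNROWS(merged),
    exonic_bases = unname(sum(BiocGenerics::width(merged)))
  )
  structure(list(genes = genes, exons = merged), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " gene(s), ",
      sum(x$genes$n_exons), " merged exon(s)\n", sep = "")
  print(utils::head(x$genes, 5L))
  invisible(x)
}

#' Export merged union exons as BED
#'
#' Writes one BED line (0-based half-open) per merged exon, with the
#' gene_id in the name column and the gene strand.
#'
#' @param models A `gene_models` object.
#' @param path Output BED path.
#' @export
write_merged_exon_bed <- function(models, path) {
  flat <- unlist(models$exons, use.names = TRUE)
  strand_map <- setNames(models$genes$strand, models$genes$gene_id)
  bed <- tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(flat)),
    start = BiocGenerics::start(flat) - 1L,
    end = BiocGenerics::end(flat),
    name = names(flat),
    score = 0L,
    strand = unname(strand_map[names(flat)])
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

record_strand_to_gr <- function(strand_label) {
  dplyr::case_when(
    strand_label == "forward" ~ "+",
    strand_label == "reverse" ~ "-",
    TRUE ~ "*"
  )
}

#' Assign SNP count records to union-exon gene models
#'
#' Joins each count record to every gene whose merged exons contain its
#' position (one output row per record-gene pair). With
#' `strand_specific = TRUE`, stranded records (`forward`/`reverse`) are
#' only joined to genes on the matching strand; unstranded records join
#' regardless. Records contained in no gene are returned in a side table,
#' never silently dropped.
#'
#' @param records Unified count tibble.
#' @param models A `gene_models` object.
#' @param strand_specific Enforce record-vs-gene strand matching.
#' @return A list with `assigned` (records plus `gene_id`, `symbol`,
#'   `gene_type`, `exon_index` — zero-based index of the containing merged
#'   exon, matching the BED export) and `unassigned` (the side table).
#' @export
assign_snps_to_genes <- function(records, models, strand_specific = FALSE) {
  if (nrow(records) == 0L) {
    empty <- dplyr::mutate(records, gene_id = character(0), symbol = character(0),
                           gene_type = character(0), exon_index = integer(0))
    return(list(assigned = empty, unassigned = records))
  }
  snp_gr <- GenomicRanges::GRanges(
    records$contig,
    IRanges::IRanges(records$position, records$position)
  )
  flat <- unlist(models$exons, use.names = TRUE)
  exon_index <- unlist(lapply(S4Vectors::elementNROWS(models$exons),
                              function(n) seq_len(n) - 1L), use.names = FALSE)
  hits <- GenomicRanges::findOverlaps(snp_gr, flat, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)

  gene_of_hit <- names(flat)[sh]
  if (strand_specific) {
    strand_map <- setNames(models$genes$strand, models$genes$gene_id)
    rec_strand <- record_strand_to_gr(records$strand_label)[qh]
    ok <- rec_strand == "*" | rec_strand == unname(strand_map[gene_of_hit])
    qh <- qh[ok]; sh <- sh[ok]; gene_of_hit <- gene_of_hit[ok]
  }

  gene_meta <- models$genes[match(gene_of_hit, models$genes$gene_id), ]
  assigned <- dplyr::bind_cols(
    records[qh, ],
    tibble::tibble(
      gene_id = gene_of_hit,
      symbol = gene_meta$symbol,
      gene_type = gene_meta$gene_type,
      exon_index = exon_index[sh]
    )
  )
  unassigned <- records[setdiff(seq_len(nrow(records)), unique(qh)), ]
  list(assigned = assigned, unassigned = unassigned)
}

#' Attach genotype classes to annotated sites
#'
#' Left-joins genotype calls onto a site table by
#' `(sample_id, contig, position)`. Sites without a genotype record get
#' `gclass = NA`.
#'
#' @param sites Site tibble (e.g. the `assigned` table).
#' @param genotypes Genotype tibble from [ingest_genotypes()].
#' @return `sites` with `gclass`, `phased`, `first_allele` columns.
#' @export
annotate_gclass <- function(sites, genotypes) {
  dplyr::left_join(
    sites,
    genotypes[c("sample_id", "contig", "position", "gclass", "phased",
                "first_allele")],
    by = c("sample_id", "contig", "position")
  )
}

#' Assign paternal/maternal alleles at phased heterozygous sites
#'
#' At each phased het site the paternal allele is set from the first
#' (left) haplotype allele under the chosen convention, and paternal and
#' maternal counts plus the per-SNP paternal allele frequency are derived.
#' Unphased hets get `paternal_allele = "unknown"` and undefined counts.
#' Applying this to a non-heterozygous site is a contract error.
#'
#' @param sites Site tibble with `gclass`, `phased`, `first_allele`,
#'   `ref_count`, `alt_count`, `total_count`.
#' @param convention `"first_is_paternal"` (default) or
#'   `"first_is_maternal"`: whether the first phased VCF allele is the
#'   paternal or the maternal haplotype. Pedigree-phasing tools differ, so
#'   this must be stated explicitly.
#' @return `sites` with `paternal_allele`, `paternal_count`,
#'   `maternal_count`, `paternal_freq` columns.
#' @export
assign_parental_alleles <- function(sites,
                                    convention = c("first_is_paternal",
                                                   "first_is_maternal")) {
  convention <- match.arg(convention)
  if (nrow(sites) > 0L && any(is.na(sites$gclass) | sites$gclass != "het")) {
    stop("assign_parental_alleles() requires heterozygous sites only",
         call. = FALSE)
  }
  pat <- ifelse(
    !sites$phased | is.na(sites$first_allele), "unknown",
    if (convention == "first_is_paternal") {
      sites$first_allele
    } else {
      ifelse(sites$first_allele == "ref", "alt", "ref")
    }
  )
  pat_count <- dplyr::case_when(
    pat == "ref" ~ sites$ref_count,
    pat == "alt" ~ sites$alt_count,
    TRUE ~ NA_integer_
  )
  mat_count <- ifelse(is.na(pat_count), NA_integer_,
                      sites$total_count - pat_count)
  dplyr::mutate(
    sites,
    paternal_allele = pat,
    paternal_count = pat_count,
    maternal_count = mat_count,
    paternal_freq = ifelse(is.na(pat_count) | sites$total_count == 0L,
                           NA_real_, pat_count / sites$total_count)
  )
}

#' Full site annotation: genes, genotype classes, parental alleles
#'
#' Convenience wrapper running [assign_snps_to_genes()],
#' [annotate_gclass()], and parental-allele assignment (applied to the
#' het rows; hom and genotype-less rows are kept with
#' `paternal_allele = "unknown"` so they remain available for
#' contamination estimation).
#'
#' @inheritParams assign_snps_to_genes
#' @inheritParams assign_parental_alleles
#' @param genotypes Genotype tibble from [ingest_genotypes()].
#' @return A list with `assigned` (fully annotated site tibble) and
#'   `unassigned`.
#' @export
annotate_sites <- function(records, models, genotypes,
                           strand_specific = FALSE,
                           convention = "first_is_paternal") {
  res <- assign_snps_to_genes(records, models, strand_specific)
  sites <- annotate_gclass(res$assigned, genotypes)
  is_het <- !is.na(sites$gclass) & sites$gclass == "het"
  het <- assign_parental_alleles(sites[is_het, , drop = FALSE], convention)
  non_het <- dplyr::mutate(
    sites[!is_het, , drop = FALSE],
    paternal_allele = "unknown", paternal_count = NA_integer_,
    maternal_count = NA_integer_, paternal_freq = NA_real_
  )
  assigned <- dplyr::arrange(
    dplyr::bind_rows(het, non_het),
    .data$sample_id, .data$contig, .data$position, .data$strand_label,
    .data$gene_id
  )
  list(assigned = assigned, unassigned = res$unassigned)
}
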