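test_that("union exons merge overlapping and book-ended intervals", {
  gtf <- write_gtf_fixture(data.frame(
    gene_id = "gA",
    start = c(100L, 150L, 300L),
    end = c(200L, 250L, 400L),
    transcript_id = c("t1", "t2", "t1")
  ))
  models <- build_union_exons(gtf)
  ex <- models$exons[["gA"]]
  expect_equal(BiocGenerics::start(ex), c(100L, 300L))
  expect_equal(BiocGenerics::end(ex), c(250L, 400L))
  expect_equal(BiocGenerics::width(ex), c(151L, 101L))

  # book-ended exons become one interval
  gtf2 <- write_gtf_fixture(data.frame(
    gene_id = "gB", start = c(100L, 201L), end = c(200L, 300L)
  ))
  ex2 <- build_union_exons(gtf2)$exons[["gB"]]
  expect_equal(length(ex2), 1L)
  expect_equal(BiocGenerics::width(ex2), 201L)

  # single exon maps to itself
  gtf3 <- write_gtf_fixture(data.frame(gene_id = "gC", start = 5L, end = 50L))
  expect_equal(BiocGenerics::width(build_union_exons(gtf3)$exons[["gC"]]), 46L)
})

test_that("union merge matches the per-base oracle and is idempotent", {
  withr::local_seed(101)
  for (rep in 1:20) {
    n <- sample(2:50, 1)
    start <- sample(1:2000, n, replace = TRUE)
    end <- start + sample(0:150, n, replace = TRUE)
    gtf <- write_gtf_fixture(data.frame(gene_id = "g", start = start, end = end))
    models <- build_union_exons(gtf)
    got <- data.frame(
      start = BiocGenerics::start(models$exons[["g"]]),
      end = BiocGenerics::end(models$exons[["g"]])
    )
    expect_equal(got, per_base_union(start, end))
    # total merged bases equal the cardinality of the per-base union
    expect_equal(models$genes$exonic_bases, sum(got$end - got$start + 1L))
    # idempotence: merging the merged model returns it unchanged
    gtf2 <- write_gtf_fixture(data.frame(gene_id = "g", start = got$start,
                                         end = got$end))
    again <- build_union_exons(gtf2)$exons[["g"]]
    expect_equal(BiocGenerics::start(again), got$start)
    expect_equal(BiocGenerics::end(again), got$end)
  }
})

test_that("genes with exons on multiple contigs are skipped with a warning", {
  gtf <- write_gtf_fixture(data.frame(
    gene_id = c("gA", "gA", "gB"), start = c(1L, 1L, 10L),
    end = c(50L, 50L, 90L), contig = c("chr1", "chr2", "chr1")
  ))
  expect_warning(models <- build_union_exons(gtf), "multiple contigs")
  expect_equal(models$genes$gene_id, "gB")
})

make_record <- function(position, strand_label = "forward", sample = "S1",
                        ref = 8L, alt = 2L) {
  tibble::tibble(
    sample_id = sample, contig = "chr1", position = position,
    variant_id = paste0("chr1_", position), ref_allele = "A",
    alt_allele = "G", ref_count = ref, alt_count = alt,
    total_count = ref + alt, other_bases = 0L, strand_label = strand_label
  )
}

test_that("SNPs join genes by union-exon containment with a side table", {
  gtf <- write_gtf_fixture(data.frame(
    gene_id = "gA", start = c(100L, 150L, 300L), end = c(200L, 250L, 400L),
    transcript_id = c("t1", "t2", "t1")
  ))
  models <- build_union_exons(gtf)
  res <- assign_snps_to_genes(
    dplyr::bind_rows(make_record(175L), make_record(275L)), models
  )
  expect_equal(nrow(res$assigned), 1L)
  expect_equal(res$assigned$gene_id, "gA")
  expect_equal(res$assigned$exon_index, 0L)
  expect_equal(res$unassigned$position, 275L)
})

test_that("strand-specific mode joins only strand-matched genes", {
  gtf <- write_gtf_fixture(data.frame(
    gene_id = c("gPlus", "gMinus"), start = c(100L, 100L),
    end = c(500L, 500L), strand = c("+", "-")
  ))
  models <- build_union_exons(gtf)
  rec <- make_record(200L, "forward")
  both <- assign_snps_to_genes(rec, models, strand_specific = FALSE)
  expect_equal(sort(both$assigned$gene_id), c("gMinus", "gPlus"))
  one <- assign_snps_to_genes(rec, models, strand_specific = TRUE)
  expect_equal(one$assigned$gene_id, "gPlus")
  expect_equal(nrow(one$unassigned), 0L)
  # unstranded records ignore the gene strand
  un <- assign_snps_to_genes(make_record(200L, "unstranded"), models,
                             strand_specific = TRUE)
  expect_equal(nrow(un$assigned), 2L)
})

test_that("parental allele assignment follows the phase convention", {
  site <- dplyr::mutate(make_record(100L), gclass = "het", phased = TRUE,
                        first_allele = "ref")
  got <- assign_parental_alleles(site, "first_is_paternal")
  expect_equal(got$paternal_allele, "ref")
  expect_equal(got$paternal_freq, 0.8)

  flipped <- dplyr::mutate(site, first_allele = "alt")
  got2 <- assign_parental_alleles(flipped, "first_is_paternal")
  expect_equal(got2$paternal_allele, "alt")
  expect_equal(got2$paternal_freq, 0.2)

  unphased <- dplyr::mutate(site, phased = FALSE, first_allele = NA_character_)
  got3 <- assign_parental_alleles(unphased)
  expect_equal(got3$paternal_allele, "unknown")
  expect_true(is.na(got3$paternal_freq))

  hom <- dplyr::mutate(site, gclass = "hom_alt")
  expect_error(assign_parental_alleles(hom), "heterozygous")
})

test_that("swapping the convention complements every paternal frequency", {
  withr::local_seed(7)
  sites <- dplyr::bind_rows(lapply(1:30, function(i) {
    dplyr::mutate(
      make_record(i * 10L, ref = sample(0:40, 1), alt = sample(1:40, 1)),
      gclass = "het", phased = TRUE,
      first_allele = sample(c("ref", "alt"), 1)
    )
  }))
  a <- assign_parental_alleles(sites, "first_is_paternal")
  b <- assign_parental_alleles(sites, "first_is_maternal")
  expect_equal(b$paternal_freq, 1 - a$paternal_freq)
  expect_equal(a$paternal_count + a$maternal_count, a$total_count)
})

test_that("merged-exon BED export is 0-based half-open", {
  gtf <- write_gtf_fixture(data.frame(gene_id = "gA", start = 100L, end = 200L))
  models <- build_union_exons(gtf)
  bed <- tempfile(fileext = ".bed")
  write_merged_exon_bed(models, bed)
  row <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(row[2:3]), c(99L, 200L))
  expect_equal(row[4], "gA")
})
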