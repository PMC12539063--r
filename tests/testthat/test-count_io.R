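test_that("parse_ase_counts copies fields, stamps sample and strand", {
  path <- write_aserc_fixture(data.frame(
    contig = "chr1", position = c(100L, 200L),
    refCount = c(7L, 12L), altCount = c(3L, 0L)
  ))
  rec <- parse_ase_counts(path, "S1", "forward")
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$total_count[1], 10L)
  expect_equal(rec$ref_count, c(7L, 12L))
  expect_true(all(rec$sample_id == "S1"))
  expect_true(all(rec$strand_label == "forward"))
  expect_true(all(rec$total_count == rec$ref_count + rec$alt_count))
})

test_that("header-only file yields an empty table", {
  path <- tempfile(fileext = ".tsv")
  writeLines(aserc_header, path)
  expect_equal(nrow(parse_ase_counts(path, "S1", "forward")), 0L)
})

test_that("inconsistent totalCount is repaired to ref + alt with a warning", {
  path <- write_aserc_fixture(data.frame(
    contig = "chr1", position = 100L, refCount = 7L, altCount = 3L,
    totalCount = 15L
  ))
  expect_warning(rec <- parse_ase_counts(path, "S1", "forward"),
                 "totalCount")
  expect_equal(rec$total_count, 10L)
})

test_that("format errors name the offending column or line", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("contig\tposition\trefCount", "chr1\t1\t5"), path)
  expect_error(parse_ase_counts(path, "S1", "forward"), "altCount")

  bad <- write_aserc_fixture(data.frame(
    contig = "chr1", position = 100L, refCount = "x", altCount = 3L,
    totalCount = 10L
  ))
  expect_error(parse_ase_counts(bad, "S1", "forward"), "line 2")
})

test_that("extra trailing columns are tolerated", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(paste(aserc_header, "extraCol", sep = "\t"),
               paste("chr1", 5L, "id", "A", "G", 4L, 6L, 10L, 0L, 0L, 10L,
                     0L, 0L, "zzz", sep = "\t")), path)
  rec <- parse_ase_counts(path, "S1", "reverse")
  expect_equal(rec$alt_count, 6L)
})

test_that("concat_counts is additive, order-independent and rejects duplicates", {
  expect_equal(nrow(concat_counts(list())), 0L)

  mk <- function(sample, strand, n = 5L) {
    p <- write_aserc_fixture(data.frame(
      contig = "chr1", position = seq_len(n) * 10L,
      refCount = seq_len(n), altCount = rev(seq_len(n))
    ))
    parse_ase_counts(p, sample, strand)
  }
  tabs <- list(mk("S1", "forward"), mk("S1", "reverse"),
               mk("S2", "forward"), mk("S2", "reverse"))
  uni <- concat_counts(tabs)
  expect_equal(nrow(uni), 20L)
  expect_identical(uni, concat_counts(rev(tabs)))

  expect_error(concat_counts(list(tabs[[1]], tabs[[1]])), "duplicate")
})

test_that("the unified table round-trips through TSV field-for-field", {
  p <- write_aserc_fixture(data.frame(
    contig = "chr1", position = c(10L, 20L), refCount = c(3L, 8L),
    altCount = c(9L, 1L)
  ))
  uni <- concat_counts(list(parse_ase_counts(p, "S1", "unstranded")))
  out <- tempfile(fileext = ".tsv")
  write_count_table(uni, out)
  expect_identical(as.data.frame(read_count_table(out)), as.data.frame(uni))
})

test_that("parse_genotypes classifies calls and counts multi-allelic skips", {
  path <- write_vcf_fixture(
    pos = c(100L, 200L, 300L, 400L, 500L),
    gt = c("0|1", "1/1", "1|0", "./.", "1/2"),
    alt = c("G", "G", "G", "G", "G,T")
  )
  expect_warning(g <- parse_genotypes(path, "S1"), "multi-allelic")
  expect_equal(nrow(g), 3L)  # ./., 1/2 skipped
  expect_equal(attr(g, "n_multiallelic_skipped"), 1L)

  r100 <- g[g$position == 100L, ]
  expect_equal(r100$gclass, "het")
  expect_true(r100$phased)
  expect_equal(r100$first_allele, "ref")

  r200 <- g[g$position == 200L, ]
  expect_equal(r200$gclass, "hom_alt")
  expect_false(r200$phased)

  r300 <- g[g$position == 300L, ]
  expect_equal(r300$first_allele, "alt")
})

test_that("phase of homozygotes is normalised away", {
  path <- write_vcf_fixture(pos = c(1L, 2L), gt = c("1|1", "0|0"))
  g <- parse_genotypes(path, "S1")
  expect_false(any(g$phased))
  expect_true(all(is.na(g$first_allele)))
})

test_that("sample sheet validation and unstranded ingestion", {
  dir <- tempfile(); dir.create(dir)
  cnt <- write_aserc_fixture(
    data.frame(contig = "chr1", position = 10L, refCount = 4L, altCount = 6L),
    path = file.path(dir, "s1.tsv")
  )
  vcf <- write_vcf_fixture(pos = 10L, gt = "0|1", path = file.path(dir, "s1.vcf"))
  writeLines(c("sample_id,count_file_forward,vcf_file",
               "S1,s1.tsv,s1.vcf"), file.path(dir, "sheet.csv"))
  sheet <- read_sample_sheet(file.path(dir, "sheet.csv"))
  expect_true(is.na(sheet$count_file_reverse[1]))
  counts <- ingest_counts(sheet)
  expect_equal(counts$strand_label, "unstranded")

  writeLines(c("sample_id,count_file_forward,vcf_file",
               "S1,s1.tsv,s1.vcf", "S1,s1.tsv,s1.vcf"),
             file.path(dir, "dup.csv"))
  expect_error(read_sample_sheet(file.path(dir, "dup.csv")), "duplicate")

  writeLines(c("sample_id,count_file_forward,vcf_file",
               "S1,absent.tsv,s1.vcf"), file.path(dir, "missing.csv"))
  expect_error(read_sample_sheet(file.path(dir, "missing.csv")), "missing file")
})
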