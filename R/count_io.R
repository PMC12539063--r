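# Ingestion of ASEReadCounter tables, sample sheets and VCF genotypes.

# the 13 columns GATK ASEReadCounter prints; newer GATK versions append
# extra columns, which are tolerated and ignored
ASERC_HEADER <- c(
  "contig", "position", "variantID", "refAllele", "altAllele",
  "refCount", "altCount", "totalCount", "lowMAPQDepth", "lowBaseQDepth",
  "rawDepth", "otherBases", "improperPairs"
)

#' Parse a GATK ASEReadCounter count table
#'
#' Reads one tab-separated ASEReadCounter output file and returns a tibble
#' of per-SNP allelic counts with the sample identity and strand label
#' stamped on every row. The 13-column GATK header is required; extra
#' trailing columns are ignored. Rows whose `totalCount` disagrees with
#' `refCount + altCount` are repaired to the sum (ASEReadCounter totals can
#' include filtered bases depending on its flags) with a warning.
#'
#' @param path Path to the tab-separated count file.
#' @param sample_id Sample identifier stamped on every record.
#' @param strand_label One of `"forward"`, `"reverse"`, `"unstranded"`.
#' @return A tibble with columns `sample_id`, `contig`, `position`,
#'   `variant_id`, `ref_allele`, `alt_allele`, `ref_count`, `alt_count`,
#'   `total_count`, `other_bases`, `strand_label`.
#' @export
parse_ase_counts <- function(path, sample_id, strand_label = "unstranded") {
  strand_label <- match.arg(strand_label, STRAND_LABELS)
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!file.exists(path)) {
    stop("count file does not exist: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(ASERC_HEADER, names(raw))
  if (length(missing) > 0L) {
    stop("not an ASEReadCounter table: missing column(s) ",
         paste(missing, collapse = ", "), " in ", path, call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(empty_count_table())
  }

  int_cols <- c("position", "refCount", "altCount", "totalCount", "otherBases")
  for (col in int_cols) {
    bad <- which(!grepl("^[0-9]+$", raw[[col]]))
    if (length(bad) > 0L) {
      stop("non-integer value in column '", col, "' at line ",
           bad[1L] + 1L, " of ", path, call. = FALSE)
    }
  }

  out <- tibble::tibble(
    sample_id   = sample_id,
    contig      = raw$contig,
    position    = as.integer(raw$position),
    variant_id  = raw$variantID,
    ref_allele  = raw$refAllele,
    alt_allele  = raw$altAllele,
    ref_count   = as.integer(raw$refCount),
    alt_count   = as.integer(raw$altCount),
    total_count = as.integer(raw$totalCount),
    other_bases = as.integer(raw$otherBases),
    strand_label = strand_label
  )

  inconsistent <- out$total_count != out$ref_count + out$alt_count
  if (any(inconsistent)) {
    warning(sum(inconsistent), " row(s) in ", basename(path),
            " had totalCount != refCount + altCount; totals recomputed as the sum",
            call. = FALSE)
    out$total_count <- out$ref_count + out$alt_count
  }
  out
}

empty_count_table <- function() {
  tibble::tibble(
    sample_id = character(), contig = character(), position = integer(),
    variant_id = character(), ref_allele = character(), alt_allele = character(),
    ref_count = integer(), alt_count = integer(), total_count = integer(),
    other_bases = integer(), strand_label = character()
  )
}

#' Concatenate per-sample / per-strand count tables
#'
#' Binds count tables from [parse_ase_counts()] into one unified table,
#' enforcing that `(sample_id, contig, position, strand_label)` is a unique
#' key, and sorting rows by that key so the result is independent of input
#' order.
#'
#' @param tables A list of count tibbles (or a single tibble).
#' @return The unified count tibble in canonical sort order.
#' @export
concat_counts <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  tables <- Filter(Negate(is.null), tables)
  if (length(tables) == 0L) {
    return(empty_count_table())
  }
  for (tab in tables) {
    missing <- setdiff(ASE_COUNT_COLS, names(tab))
    if (length(missing) > 0L) {
      stop("count table missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  out <- dplyr::bind_rows(tables)
  if (nrow(out) > 0L) {
    key <- paste(out$sample_id, out$contig, out$position, out$strand_label,
                 sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      first_dup <- strsplit(key[which(dup)[1L]], "\r", fixed = TRUE)[[1L]]
      stop("duplicate count record for sample=", first_dup[1L], " ",
           first_dup[2L], ":", first_dup[3L], " strand=", first_dup[4L],
           call. = FALSE)
    }
    out <- dplyr::arrange(out, .data$sample_id, .data$contig,
                          .data$position, .data$strand_label)
  }
  out[ASE_COUNT_COLS]
}

#' Write / read the unified count table
#'
#' The unified table round-trips through TSV field-for-field.
#'
#' @param counts A unified count tibble.
#' @param path Output (or input) TSV path.
#' @return `write_count_table()` returns `path` invisibly;
#'   `read_count_table()` returns the tibble.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts[ASE_COUNT_COLS], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), contig = readr::col_character(),
    position = readr::col_integer(), variant_id = readr::col_character(),
    ref_allele = readr::col_character(), alt_allele = readr::col_character(),
    ref_count = readr::col_integer(), alt_count = readr::col_integer(),
    total_count = readr::col_integer(), other_bases = readr::col_integer(),
    strand_label = readr::col_character()
  ), progress = FALSE)
}

#' Read a sample sheet
#'
#' The sample sheet is a CSV with columns `sample_id`, `count_file_forward`,
#' `count_file_reverse` (optional), `vcf_file`, and `maternal_vcf_file`
#' (optional). Relative paths are resolved against the sheet's directory.
#' A row with no reverse count file is treated as unstranded: its single
#' count file is labelled `"unstranded"` and downstream strand matching is
#' skipped for those records.
#'
#' @param path Path to the CSV sample sheet.
#' @param check_paths Verify that every declared file exists (default TRUE).
#' @return A tibble with one row per sample.
#' @export
read_sample_sheet <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("sample sheet does not exist: ", path, call. = FALSE)
  sheet <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  required <- c("sample_id", "count_file_forward", "vcf_file")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0L) {
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("count_file_reverse", "maternal_vcf_file")) {
    if (!opt %in% names(sheet)) sheet[[opt]] <- NA_character_
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         sheet$sample_id[duplicated(sheet$sample_id)][1L], call. = FALSE)
  }
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(is.na(p) | p == "", NA_character_,
           ifelse(grepl("^/", p), p, file.path(base_dir, p)))
  }
  path_cols <- c("count_file_forward", "count_file_reverse", "vcf_file",
                 "maternal_vcf_file")
  for (col in path_cols) sheet[[col]] <- resolve(sheet[[col]])
  if (check_paths) {
    for (col in path_cols) {
      declared <- sheet[[col]][!is.na(sheet[[col]])]
      absent <- declared[!file.exists(declared)]
      if (length(absent) > 0L) {
        stop("sample sheet references missing file (", col, "): ",
             absent[1L], call. = FALSE)
      }
    }
  }
  sheet[c("sample_id", path_cols)]
}

#' Ingest all count files listed in a sample sheet
#'
#' Parses every sample's forward (and, when present, reverse) count file
#' and concatenates them into the unified count table. Samples without a
#' reverse file are read as unstranded.
#'
#' @param sheet A sample sheet tibble from [read_sample_sheet()].
#' @return The unified count tibble.
#' @export
ingest_counts <- function(sheet) {
  tables <- vector("list", 2L * nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    rev_file <- sheet$count_file_reverse[i]
    if (is.na(rev_file)) {
      tables[[2L * i - 1L]] <- parse_ase_counts(sheet$count_file_forward[i],
                                               sid, "unstranded")
    } else {
      tables[[2L * i - 1L]] <- parse_ase_counts(sheet$count_file_forward[i],
                                               sid, "forward")
      tables[[2L * i]] <- parse_ase_counts(rev_file, sid, "reverse")
    }
  }
  concat_counts(tables)
}

#' Extract genotype calls for one sample from a VCF
#'
#' Reads the `GT` field for `sample_id` and classifies each biallelic SNP
#' as `hom_ref`, `het`, or `hom_alt`. A call is phased only when it is a
#' heterozygote written with the `|` separator (phase of a homozygote
#' carries no information and is normalised away); for phased hets the
#' first (left) haplotype allele is recorded. Records whose GT uses an
#' allele index above 1 (multi-allelic) are skipped and counted in the
#' `n_multiallelic_skipped` attribute; missing genotypes (`./.`) are
#' skipped silently.
#'
#' @param path VCF path (plain or bgzipped).
#' @param sample_id Sample column to read. Defaults to the first sample.
#' @param relabel_as Optional sample_id to stamp on the output instead of
#'   `sample_id` (used when reading a maternal VCF on behalf of an
#'   offspring sample).
#' @return A tibble with columns `sample_id`, `contig`, `position`,
#'   `gclass`, `phased`, `first_allele`.
#' @export
parse_genotypes <- function(path, sample_id = NULL, relabel_as = NULL) {
  if (!file.exists(path)) stop("VCF does not exist: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  if (length(samples) == 0L) stop("VCF has no sample columns: ", path, call. = FALSE)
  if (is.null(sample_id)) sample_id <- samples[1L]
  if (!sample_id %in% samples) {
    stop("sample '", sample_id, "' not present in VCF ", path, call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")[, sample_id]
  contig <- vcf@fix[, "CHROM"]
  position <- as.integer(vcf@fix[, "POS"])

  gt_chr <- as.character(gt)
  alleles <- regmatches(gt_chr, regexec("^([0-9.])([/|])([0-9.])", gt_chr))
  a1 <- vapply(alleles, function(m) if (length(m)) m[2L] else NA_character_, "")
  sep <- vapply(alleles, function(m) if (length(m)) m[3L] else NA_character_, "")
  a2 <- vapply(alleles, function(m) if (length(m)) m[4L] else NA_character_, "")

  is_missing <- is.na(a1) | a1 == "." | a2 == "."
  n1 <- suppressWarnings(as.integer(a1))
  n2 <- suppressWarnings(as.integer(a2))
  is_multi <- !is_missing & (n1 > 1L | n2 > 1L)
  keep <- !is_missing & !is_multi

  n_multi <- sum(is_multi)
  if (n_multi > 0L) {
    warning(n_multi, " multi-allelic genotype record(s) skipped in ",
            basename(path), call. = FALSE)
  }

  gclass <- dplyr::case_when(
    n1 == 0L & n2 == 0L ~ "hom_ref",
    n1 == 1L & n2 == 1L ~ "hom_alt",
    TRUE ~ "het"
  )
  phased <- sep == "|" & gclass == "het"
  first_allele <- ifelse(phased, ifelse(n1 == 0L, "ref", "alt"), NA_character_)

  out <- tibble::tibble(
    sample_id = relabel_as %||% sample_id,
    contig = contig[keep],
    position = position[keep],
    gclass = gclass[keep],
    phased = phased[keep],
    first_allele = first_allele[keep]
  )
  attr(out, "n_multiallelic_skipped") <- n_multi
  out
}

#' Read genotypes for every sample in a sample sheet
#'
#' @param sheet Sample sheet tibble.
#' @param maternal Read the maternal VCFs instead of the offspring VCFs;
#'   samples without a maternal VCF are omitted. Maternal calls are
#'   relabelled with the offspring's `sample_id`.
#' @return A genotype tibble covering all (available) samples.
#' @export
ingest_genotypes <- function(sheet, maternal = FALSE) {
  col <- if (maternal) "maternal_vcf_file" else "vcf_file"
  rows <- which(!is.na(sheet[[col]]))
  pieces <- lapply(rows, function(i) {
    g <- parse_genotypes(sheet[[col]][i], relabel_as = sheet$sample_id[i])
    attr(g, "n_multiallelic_skipped") <- NULL
    g
  })
  dplyr::bind_rows(pieces)
}
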