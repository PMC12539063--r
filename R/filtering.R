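# Data-retention rules producing the analysis-ready subset.

#' Filter configuration
#'
#' Defaults reproduce the standard retention rule: keep SNP rows with at
#' least 10 reads, from samples whose contamination (when measurable) is
#' strictly below 5%.
#'
#' @param min_total_count Minimum `total_count` per SNP x sample x strand
#'   row (boundary inclusive: a row with exactly this many reads is kept).
#' @param max_contamination Samples whose largest defined contamination
#'   estimate is `>=` this fraction are dropped entirely (strict `<` to
#'   retain).
#' @param drop_unmeasurable_contamination Drop samples with no defined
#'   contamination estimate (default: they pass, i.e. "when measurable").
#' @param require_phased Additionally keep only rows with an assigned
#'   paternal allele (the parent-of-origin test subset).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_total_count = 10L, max_contamination = 0.05,
                          drop_unmeasurable_contamination = FALSE,
                          require_phased = FALSE) {
  stopifnot(min_total_count >= 0L,
            max_contamination >= 0, max_contamination <= 1)
  structure(
    list(min_total_count = as.integer(min_total_count),
         max_contamination = max_contamination,
         drop_unmeasurable_contamination = isTRUE(drop_unmeasurable_contamination),
         require_phased = isTRUE(require_phased)),
    class = "filter_config"
  )
}

#' Apply retention filters
#'
#' Rows are tested against the rules in a fixed order — read count,
#' sample contamination, phasing — and each dropped row is attributed to
#' the first rule it fails, so the drop accounting is deterministic and
#' `rows retained + rows dropped == rows in`.
#'
#' @param sites Annotated site tibble.
#' @param contam Per-sample contamination tibble from
#'   [sample_contamination()], or `NULL` (all samples unmeasurable).
#' @param cfg A [filter_config()].
#' @return A `filter_result` list: `retained` (tibble), `drops` (tibble of
#'   rule / n), `n_in`, `n_out`.
#' @export
apply_filters <- function(sites, contam = NULL, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  n_in <- nrow(sites)

  fail_count <- sites$total_count < cfg$min_total_count

  # a sample's contamination measure is the largest defined estimate
  sample_level <- rep(NA_real_, n_in)
  if (!is.null(contam) && nrow(contam) > 0L) {
    worst <- vapply(seq_len(nrow(contam)), function(i) {
      ests <- c(contam$est_homalt[i], contam$est_ref[i])
      if (all(is.na(ests))) NA_real_ else max(ests, na.rm = TRUE)
    }, numeric(1))
    sample_level <- worst[match(sites$sample_id, contam$sample_id)]
  }
  fail_contam <- ifelse(
    is.na(sample_level),
    cfg$drop_unmeasurable_contamination,
    sample_level >= cfg$max_contamination
  )

  fail_phase <- if (cfg$require_phased) {
    is.na(sites$paternal_allele) | sites$paternal_allele == "unknown"
  } else {
    rep(FALSE, n_in)
  }

  first_fail <- dplyr::case_when(
    fail_count ~ "count",
    fail_contam ~ "contamination",
    fail_phase ~ "unphased",
    TRUE ~ "retained"
  )
  retained <- sites[first_fail == "retained", , drop = FALSE]
  drops <- tibble::tibble(
    rule = c("count", "contamination", "unphased"),
    n = c(sum(first_fail == "count"), sum(first_fail == "contamination"),
          sum(first_fail == "unphased"))
  )
  structure(
    list(retained = retained, drops = drops, n_in = n_in,
         n_out = nrow(retained)),
    class = "filter_result"
  )
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> rows in: ", x$n_in, ", retained: ", x$n_out, "\n",
      sep = "")
  for (i in seq_len(nrow(x$drops))) {
    cat("  dropped by ", x$drops$rule[i], ": ", x$drops$n[i], "\n", sep = "")
  }
  invisible(x)
}

#' Write a filter report as TSV
#'
#' @param result A `filter_result`.
#' @param path Output TSV path.
#' @export
write_filter_report <- function(result, path) {
  report <- tibble::tibble(
    metric = c("rows_in", "rows_retained",
               paste0("dropped_", result$drops$rule)),
    n = c(result$n_in, result$n_out, result$drops$n)
  )
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}
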