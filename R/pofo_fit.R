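# Cluster-robust quasi-Poisson fit of the parent-of-origin model
#
#   log E[Y] = b0 + po*z + b1*x + sum_l gamma_l v_l + sum_l delta_l (v_l * x)
#
# Point estimates are the Poisson MLE under the log link (shared by the
# quasi-Poisson model), fitted by iteratively reweighted least squares.
# Uncertainty comes from the sandwich covariance clustered on subjects,
# which absorbs both overdispersion and within-subject correlation
# (e.g. linkage disequilibrium across a subject's SNPs).

# Greedy left-to-right rank scan: keep a column only if it increases the
# rank of what is already kept. Columns are ordered intercept, z, x,
# v, v:x, so redundancy is always resolved at the expense of the
# nuisance columns and po keeps its meaning. The intercept/v collinearity
# is structural: rows of u each sum to 1, so when every singular vector
# is retained the constant column lies in span(v) (and x in span(v:x)).
select_independent_columns <- function(X, tol = 1e-7) {
  p <- ncol(X)
  scale <- pmax(sqrt(colSums(X^2)), .Machine$double.eps)
  Xs <- sweep(X, 2L, scale, "/")
  keep <- integer(0)
  for (j in seq_len(p)) {
    cand <- Xs[, c(keep, j), drop = FALSE]
    if (qr(cand, tol = tol)$rank == length(keep) + 1L) keep <- c(keep, j)
  }
  keep
}

#' Fit the cluster-robust quasi-Poisson parent-of-origin model
#'
#' Assembles the model matrix `[1, z, x, v, v:x]` from a
#' [build_design()] object, resolves rank deficiency by dropping
#' dependent columns (nuisance columns first; if `z` itself is dropped
#' the gene is untestable), fits the Poisson MLE by IRLS, and computes
#' the subject-clustered sandwich covariance.
#'
#' @param design A `pofo_design`.
#' @param small_sample_correction `"G/(G-1)"` (default, CR1-style) or
#'   `"none"`; G is the number of subject clusters.
#' @param max_iter,tol IRLS iteration cap and relative-change tolerance.
#' @return A `pofo_fit` list with `coefficients` (named; `NA` for dropped
#'   columns), `vcov` (clustered sandwich over kept columns),
#'   `dropped_columns`, `converged`, `n_clusters`, `n_obs`,
#'   `pearson_dispersion` (diagnostic only; never applied to the sandwich).
#' @export
fit_quasipoisson <- function(design, small_sample_correction = c("G/(G-1)", "none"),
                             max_iter = 100L, tol = 1e-10) {
  small_sample_correction <- match.arg(small_sample_correction)
  stopifnot(inherits(design, "pofo_design"))
  y <- design$y
  q <- design$q
  vx <- design$v * design$x
  X <- cbind(1, design$z, design$x, design$v, vx)
  colnames(X) <- c("(Intercept)", "z", "x",
                   if (q > 0L) paste0("v", seq_len(q)),
                   if (q > 0L) paste0("v", seq_len(q), ":x"))

  keep <- select_independent_columns(X)
  dropped <- setdiff(colnames(X), colnames(X)[keep])
  if (!"z" %in% colnames(X)[keep]) {
    stop(untestable_condition("po_unidentifiable", design$gene_id))
  }
  Xk <- X[, keep, drop = FALSE]

  # IRLS for Poisson log link
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- rep(0, ncol(Xk))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    w <- mu
    zw <- eta + (y - mu) / mu
    wsqrt <- sqrt(w)
    fit <- qr(Xk * wsqrt)
    beta_new <- qr.coef(fit, zw * wsqrt)
    if (anyNA(beta_new)) {
      stop(untestable_condition("po_unidentifiable", design$gene_id))
    }
    # scaled change: relative for large coefficients, absolute near zero
    delta <- max(abs(beta_new - beta) / (1 + abs(beta_new)))
    beta <- beta_new
    eta <- pmin(pmax(drop(Xk %*% beta), -30), 30)
    mu <- exp(eta)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(untestable_condition("no_convergence", design$gene_id))
  }

  clusters <- design$clusters
  G <- length(unique(clusters))
  A <- crossprod(Xk, Xk * mu)                    # Fisher information
  Ainv <- tryCatch(solve(A), error = function(e) {
    stop(untestable_condition("po_unidentifiable", design$gene_id))
  })
  resid <- y - mu
  S <- rowsum(Xk * resid, clusters)              # per-cluster score sums
  M <- crossprod(as.matrix(S))
  cfac <- if (small_sample_correction == "G/(G-1)" && G > 1L) G / (G - 1) else 1
  V <- cfac * (Ainv %*% M %*% Ainv)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(Xk), colnames(Xk))

  p <- ncol(Xk)
  dispersion <- if (length(y) > p) sum(resid^2 / mu) / (length(y) - p) else NA_real_

  coefs <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  coefs[colnames(Xk)] <- beta

  structure(
    list(gene_id = design$gene_id, coefficients = coefs, vcov = V,
         kept_columns = colnames(Xk), dropped_columns = dropped,
         converged = converged, n_clusters = G, n_obs = length(y),
         n_snps = design$m, n_iter = iter,
         pearson_dispersion = dispersion, fitted = mu),
    class = "pofo_fit"
  )
}

#' @export
print.pofo_fit <- function(x, ...) {
  cat("<pofo_fit> gene ", x$gene_id, ": po=",
      format(x$coefficients[["z"]], digits = 4),
      " (", x$n_clusters, " subjects, ", x$n_obs, " obs, dispersion=",
      format(x$pearson_dispersion, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Extract the parent-of-origin score from a fit
#'
#' The PofO score `po` is the coefficient of the parental-origin
#' covariate `z`; `po_se` is its cluster-robust standard error and
#' `po_z = po / po_se`. A gene is testable when the fit converged, `z`
#' survived rank reduction, and at least `min_subjects` subjects
#' contribute. Positive `po` means paternally biased expression, negative
#' maternally biased.
#'
#' @param fit A `pofo_fit` (or an `asepo_untestable` condition caught by
#'   the caller — see [pofo_test()]).
#' @param min_subjects Minimum subject clusters for a testable gene.
#' @return One-row tibble: `gene_id`, `po`, `po_se`, `po_z`,
#'   `n_subjects`, `n_snps`, `n_obs`, `testable`, `untestable_reason`,
#'   `direction`.
#' @export
pofo_score <- function(fit, min_subjects = 3L) {
  po <- unname(fit$coefficients[["z"]])
  po_se <- sqrt(fit$vcov["z", "z"])
  testable <- fit$converged && fit$n_clusters >= min_subjects
  reason <- if (testable) "none" else "too_few_subjects"
  if (!testable) {
    po <- NA_real_; po_se <- NA_real_
  }
  tibble::tibble(
    gene_id = fit$gene_id,
    po = po,
    po_se = po_se,
    po_z = po / po_se,
    n_subjects = fit$n_clusters,
    n_snps = fit$n_snps,
    n_obs = fit$n_obs,
    testable = testable,
    untestable_reason = reason,
    direction = dplyr::case_when(
      !testable ~ NA_character_,
      po > 0 ~ "paternal",
      po < 0 ~ "maternal",
      TRUE ~ "balanced"
    )
  )
}

untestable_result <- function(gene_id, reason, n_subjects = NA_integer_,
                              n_snps = NA_integer_, n_obs = NA_integer_) {
  tibble::tibble(
    gene_id = gene_id, po = NA_real_, po_se = NA_real_, po_z = NA_real_,
    n_subjects = n_subjects, n_snps = n_snps, n_obs = n_obs,
    testable = FALSE, untestable_reason = reason, direction = NA_character_
  )
}

#' Classify parent-of-origin results
#'
#' `|po_z| > z_cut` denotes statistical significance; `|po| > po_cut`
#' additionally denotes a strong parentally determined effect (at the
#' default `po_cut = 3` this implies at least an `exp(3) ~ 20`-fold
#' difference between the alleles, since `z` differs by exactly 1 between
#' the paternal and maternal rows under the log link). The z gate applies
#' first: a large `po` with a small `po_z` is not significant.
#'
#' @param po,po_z Numeric vectors (recycled together).
#' @param po_cut,z_cut Thresholds (default 3 and 3).
#' @param testable Logical vector; `FALSE` yields `"untestable"`.
#' @return Character vector with levels `strong_paternal`,
#'   `strong_maternal`, `significant_paternal`, `significant_maternal`,
#'   `not_significant`, `untestable`.
#' @export
classify_pofo <- function(po, po_z, po_cut = 3, z_cut = 3,
                          testable = TRUE) {
  n <- max(length(po), length(po_z), length(testable))
  po <- rep_len(po, n); po_z <- rep_len(po_z, n)
  testable <- rep_len(testable, n)
  dir <- ifelse(po > 0, "paternal", "maternal")
  dplyr::case_when(
    !testable | is.na(po_z) ~ "untestable",
    abs(po_z) <= z_cut ~ "not_significant",
    abs(po) > po_cut ~ paste0("strong_", dir),
    TRUE ~ paste0("significant_", dir)
  )
}

#' Implied allelic fold change of a parent-of-origin score
#'
#' Under the log link the parental covariate differs by exactly 1 between
#' the paternal (+1/2) and maternal (-1/2) rows, so the expected-count
#' ratio between the favoured and disfavoured allele is `exp(|po|)`.
#'
#' @param po Parent-of-origin score(s).
#' @return `exp(abs(po))`.
#' @export
fold_change <- function(po) exp(abs(po))

#' Per-gene parent-of-origin testing over a site table
#'
#' Runs [build_design()], [fit_quasipoisson()], [pofo_score()] and
#' [classify_pofo()] for every gene in a filtered, phased site table.
#' Genes that cannot be tested (no phased SNPs, unidentifiable `po`,
#' non-convergence, too few subjects) are reported with their reason
#' rather than dropped.
#'
#' @param sites Filtered annotated site tibble (phased het rows; rows
#'   with `paternal_allele == "unknown"` are ignored).
#' @param min_subjects Minimum subject clusters for testability.
#' @param rel_threshold SVD threshold for [reduce_indicators()].
#' @param combine_strands Sum counts over strands before testing.
#' @param small_sample_correction See [fit_quasipoisson()].
#' @param po_cut,z_cut Classification thresholds.
#' @return Tibble with one row per gene, ordered by `gene_id`, including
#'   a `class` column.
#' @export
pofo_test <- function(sites, min_subjects = 3L, rel_threshold = 0.01,
                      combine_strands = TRUE,
                      small_sample_correction = "G/(G-1)",
                      po_cut = 3, z_cut = 3) {
  usable <- sites[!is.na(sites$gene_id), , drop = FALSE]
  gene_ids <- sort(unique(usable$gene_id))
  results <- lapply(gene_ids, function(g) {
    gene_sites <- usable[usable$gene_id == g, , drop = FALSE]
    res <- tryCatch({
      design <- build_design(gene_sites, combine_strands = combine_strands,
                             rel_threshold = rel_threshold)
      fit <- fit_quasipoisson(design,
                              small_sample_correction = small_sample_correction)
      pofo_score(fit, min_subjects = min_subjects)
    }, asepo_untestable = function(cond) {
      untestable_result(g, cond$reason)
    })
    res
  })
  out <- dplyr::bind_rows(results)
  if (nrow(out) == 0L) {
    out <- untestable_result(character(0), character(0))
  }
  out$class <- classify_pofo(out$po, out$po_z, po_cut, z_cut, out$testable)
  out
}

#' Write per-gene parent-of-origin results as TSV
#'
#' @param results Tibble from [pofo_test()].
#' @param path Output TSV path.
#' @export
write_pofo_results <- function(results, path) {
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}
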