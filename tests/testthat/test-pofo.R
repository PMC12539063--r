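one_snp_sites <- function(ref = 8L, alt = 2L, paternal = "ref",
                          sample = "A", strand = "forward") {
  tibble::tibble(
    gene_id = "g1", sample_id = sample, contig = "chr1", position = 100L,
    ref_count = ref, alt_count = alt, total_count = ref + alt,
    paternal_allele = paternal, strand_label = strand
  )
}

test_that("design rows come in ref/alt pairs with balanced z and x", {
  d <- build_design(one_snp_sites())
  expect_equal(length(d$y), 2L)
  expect_equal(d$m, 1L)
  expect_equal(d$y, c(8L, 2L))
  expect_equal(d$z, c(0.5, -0.5))
  expect_equal(d$x, c(0.5, -0.5))

  # paternal = alt flips z but not x
  d2 <- build_design(one_snp_sites(paternal = "alt"))
  expect_equal(d2$z, c(-0.5, 0.5))
  expect_equal(d2$x, c(0.5, -0.5))

  # pair-level invariants on a larger random design
  withr::local_seed(3)
  sites <- make_gene_sites(5, 3)
  d3 <- build_design(sites)
  expect_equal(length(d3$y), 30L)
  pair <- rep(seq_len(15), each = 2L)
  expect_true(all(tapply(d3$z, pair, sum) == 0))
  expect_true(all(tapply(d3$x, pair, sum) == 0))
  expect_true(all(rowSums(d3$u) == 1))
})

test_that("strand records are summed before row construction", {
  sites <- dplyr::bind_rows(one_snp_sites(8L, 2L, strand = "forward"),
                            one_snp_sites(5L, 1L, strand = "reverse"))
  d <- build_design(sites, combine_strands = TRUE)
  expect_equal(length(d$y), 2L)
  expect_equal(d$y, c(13L, 3L))
})

test_that("3 subjects x 2 SNPs gives N = 12 with balanced indicator columns", {
  withr::local_seed(1)
  sites <- make_gene_sites(3, 2)
  d <- build_design(sites)
  expect_equal(length(d$y), 12L)
  expect_equal(unname(colSums(d$u)), c(6, 6))
})

test_that("SVD reduction keeps singular vectors at the 1% rule", {
  # one SNP, four observations: the normalised constant vector
  u1 <- matrix(1, nrow = 4, ncol = 1)
  r1 <- reduce_indicators(u1)
  expect_equal(r1$q, 1L)
  expect_equal(abs(r1$v[, 1]), rep(0.5, 4))

  # disjoint indicators with 4 and 2 rows: singular values 2 and sqrt(2)
  u2 <- matrix(0, 6, 2); u2[1:4, 1] <- 1; u2[5:6, 2] <- 1
  r2 <- reduce_indicators(u2)
  expect_equal(r2$singular_values, c(2, sqrt(2)))
  expect_equal(r2$q, 2L)

  # grossly unbalanced support: the minor direction falls below 1%
  u3 <- matrix(0, 20001, 2); u3[1:20000, 1] <- 1; u3[20001, 2] <- 1
  r3 <- reduce_indicators(u3)
  expect_equal(r3$singular_values, c(sqrt(20000), 1))
  expect_equal(r3$q, 1L)

  # ties at the threshold are kept ("at least")
  u4 <- diag(2)
  expect_equal(reduce_indicators(u4, rel_threshold = 1)$q, 2L)
})

test_that("the symmetric two-subject fixture recovers po = ln 10 and beta1 = 0", {
  sites <- dplyr::bind_rows(
    one_snp_sites(30L, 3L, paternal = "ref", sample = "A"),
    one_snp_sites(3L, 30L, paternal = "alt", sample = "B")
  )
  fit <- fit_quasipoisson(build_design(sites))
  expect_equal(unname(fit$coefficients[["z"]]), log(10), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[["x"]]), 0, tolerance = 1e-8)
  # m = 1 makes v collinear with the intercept: rank reduction must fire
  expect_true(length(fit$dropped_columns) > 0)
})

test_that("flat counts with balanced z give po = 0", {
  sites <- dplyr::bind_rows(
    one_snp_sites(20L, 20L, paternal = "ref", sample = "A"),
    one_snp_sites(20L, 20L, paternal = "alt", sample = "B")
  )
  fit <- fit_quasipoisson(build_design(sites))
  expect_equal(unname(fit$coefficients[["z"]]), 0, tolerance = 1e-10)
})

test_that("IRLS matches glm and the sandwich matches vcovCL on random designs", {
  skip_if_not_installed("sandwich")
  withr::local_seed(20)
  for (i in 1:8) {
    sites <- make_gene_sites(sample(4:20, 1), sample(2:6, 1),
                             po = runif(1, -1, 1),
                             b = rnorm(6, 0, 1), het_prob = 0.9)
    d <- build_design(sites)
    fit <- fit_quasipoisson(d)
    Xk <- design_model_matrix(d, fit$kept_columns)
    gl <- stats::glm(d$y ~ Xk - 1, family = stats::poisson(),
                     control = stats::glm.control(epsilon = 1e-12))
    expect_equal(unname(coef(gl)),
                 unname(fit$coefficients[fit$kept_columns]),
                 tolerance = 1e-7)
    V <- sandwich::vcovCL(gl, cluster = d$clusters, type = "HC0")
    expect_lt(max(abs(V - fit$vcov)), 1e-7)
  }
})

test_that("label equivariance: z-flip negates po, x-flip leaves it unchanged", {
  withr::local_seed(8)
  for (i in 1:5) {
    sites <- make_gene_sites(8, 3, po = runif(1, -1.5, 1.5), b = rnorm(3))
    fit <- fit_quasipoisson(build_design(sites))

    zflip <- dplyr::mutate(sites, paternal_allele =
                             ifelse(paternal_allele == "ref", "alt", "ref"))
    fitz <- fit_quasipoisson(build_design(zflip))
    expect_equal(fitz$coefficients[["z"]], -fit$coefficients[["z"]],
                 tolerance = 1e-9)
    expect_equal(sqrt(fitz$vcov["z", "z"]), sqrt(fit$vcov["z", "z"]),
                 tolerance = 1e-9)

    xflip <- dplyr::mutate(sites,
                           ref_count = sites$alt_count,
                           alt_count = sites$ref_count,
                           paternal_allele =
                             ifelse(paternal_allele == "ref", "alt", "ref"))
    fitx <- fit_quasipoisson(build_design(xflip))
    expect_equal(fitx$coefficients[["z"]], fit$coefficients[["z"]],
                 tolerance = 1e-9)
  }
})

test_that("intercept collinearity is structural and po ignores the redundant basis", {
  withr::local_seed(9)
  sites <- make_gene_sites(6, 4)
  d <- build_design(sites, rel_threshold = 0)   # keep every singular vector
  expect_equal(d$q, d$m)
  fit <- fit_quasipoisson(d)
  expect_true(length(fit$dropped_columns) >= 1L)

  # permuting the v columns changes which redundant column is dropped,
  # never the parent-of-origin estimate
  d2 <- d
  perm <- c(3, 1, 4, 2)
  d2$v <- d$v[, perm]
  fit2 <- fit_quasipoisson(d2)
  expect_equal(fit2$coefficients[["z"]], fit$coefficients[["z"]],
               tolerance = 1e-8)
  expect_equal(fit2$vcov["z", "z"], fit$vcov["z", "z"], tolerance = 1e-8)
})

test_that("scores, testability and classification follow the thresholds", {
  fake_fit <- list(gene_id = "g", coefficients = c("(Intercept)" = 1, z = 2),
                   vcov = matrix(0.25, 1, 1, dimnames = list("z", "z")),
                   converged = TRUE, n_clusters = 10L, n_obs = 40L,
                   n_snps = 2L)
  res <- pofo_score(fake_fit)
  expect_equal(res$po_z, 4)
  expect_equal(res$direction, "paternal")

  few <- fake_fit; few$n_clusters <- 2L
  res2 <- pofo_score(few, min_subjects = 3L)
  expect_false(res2$testable)
  expect_equal(res2$untestable_reason, "too_few_subjects")

  expect_equal(classify_pofo(3.5, 6), "strong_paternal")
  expect_equal(classify_pofo(-1.2, -4), "significant_maternal")
  expect_equal(classify_pofo(4, 2), "not_significant")
  expect_equal(classify_pofo(NA, NA, testable = FALSE), "untestable")
})

test_that("fold change is exp(|po|)", {
  expect_equal(fold_change(0), 1)
  expect_equal(fold_change(log(10)), 10)
  expect_equal(fold_change(-log(10)), 10)
  expect_gte(fold_change(3), 20)
})

test_that("pofo_test reports untestable genes with their reason", {
  withr::local_seed(12)
  ok <- make_gene_sites(6, 2, po = 1, gene_id = "gOK")
  few <- make_gene_sites(2, 2, gene_id = "gFew")
  unphased <- dplyr::mutate(make_gene_sites(5, 2, gene_id = "gUnphased"),
                            paternal_allele = "unknown")
  res <- pofo_test(dplyr::bind_rows(ok, few, unphased))
  expect_equal(nrow(res), 3L)
  expect_true(res$testable[res$gene_id == "gOK"])
  expect_equal(res$untestable_reason[res$gene_id == "gFew"],
               "too_few_subjects")
  expect_equal(res$untestable_reason[res$gene_id == "gUnphased"],
               "no_phased_snps")
  expect_equal(res$class[!res$testable], rep("untestable", 2))
  # z-score is the ratio of the reported estimate and standard error
  ok_row <- res[res$gene_id == "gOK", ]
  expect_equal(ok_row$po_z, ok_row$po / ok_row$po_se)
})
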