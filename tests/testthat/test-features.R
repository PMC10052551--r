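test_that("methylation fold change is the eps-protected tumor/normal ratio", {
  om <- make_om(matrix(c(0.6, 0.3, 0.5), 3, 4), matrix(c(0.3, 0.3, 0), 3, 2),
                type = "methylation")
  fc <- methylation_fold_change(om)
  expect_equal(unname(fc[1]), 2, tolerance = 1e-4)
  expect_equal(unname(fc[2]), 1, tolerance = 1e-4)
  # zero normal mean: pseudocount keeps it finite at ~value/1e-6
  expect_equal(unname(fc[3]), (0.5 + 1e-6) / 1e-6, tolerance = 1e-6)
  expect_true(all(is.finite(fc)))
})

test_that("expression fold change is log2 with exact zero for unmeasured genes", {
  om <- make_om(matrix(c(5, 8, NA), 3, 3), matrix(c(5, 2, NA), 3, 3))
  fc <- expression_fold_change(om)
  expect_equal(unname(fc[1]), 0, tolerance = 1e-6)
  expect_equal(unname(fc[2]), 2, tolerance = 1e-5)
  expect_identical(unname(fc[3]), 0)          # all-missing gene: exactly 0
  expect_equal(unname(expression_fold_change(om, log2 = FALSE)[2]), 4,
               tolerance = 1e-5)
})

test_that("DE flag direction follows forced shifts and is mostly 0 under the null", {
  set.seed(11)
  base <- matrix(rnorm(3 * 20, 10), 3, 20)
  up <- base; up[1, ] <- up[1, ] + 50; up[2, ] <- up[2, ] - 50
  om <- make_om(up, base)
  flag <- de_significance_flag(om)
  expect_identical(unname(flag[1]), 1L)
  expect_identical(unname(flag[2]), -1L)

  # type-I behavior: identical distributions -> flag 0 for >= 90% of genes
  set.seed(12)
  ng <- 1000
  om0 <- make_om(matrix(rnorm(ng * 15), ng, 15),
                 matrix(rnorm(ng * 15), ng, 15))
  f0 <- de_significance_flag(om0, alpha = 0.05)
  expect_gte(mean(f0 == 0), 0.9)
})

test_that("Grubbs critical value matches an independent t-quantile inversion", {
  # invert the t CDF by root finding so the route differs from qt()
  t_quantile <- function(p, df)
    uniroot(function(x) stats::pt(x, df) - p, c(-500, 500),
            tol = 1e-12)$root
  for (n in c(3, 5, 10, 50, 200)) {
    t <- t_quantile(1 - 0.05 / (2 * n), n - 2)
    expected <- (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
    expect_equal(grubbs_critical_value(n), expected, tolerance = 1e-6)
  }
  gp <- grubbs_critical_value(3:200)
  expect_true(all(diff(gp) > 0))                       # monotone in n
  expect_gt(grubbs_critical_value(10, 0.01), grubbs_critical_value(10, 0.05))
  expect_error(grubbs_critical_value(2), "n >= 3")
})

test_that("outlier matrix flags only signed upper-tail excursions", {
  set.seed(4)
  n <- 50
  tum <- matrix(rnorm(3 * n, 10, 1), 3, n)
  tum[1, 7] <- 10 + 6 * sd(tum[1, -7])   # one far-high sample
  tum[2, ] <- 5                          # constant gene
  tum[3, 9] <- 10 - 8 * 1                # far BELOW mean: must stay 0
  om <- make_om(tum, matrix(rnorm(3 * 4, 10), 3, 4))
  o <- outlier_matrix(om)
  expect_equal(unname(o[1, 7]), 1)
  expect_equal(sum(o[2, ]), 0)           # zero-SD rule
  expect_equal(unname(o[3, 9]), 0)       # one-sided rule
  expect_equal(gene_outlier_count(o), rowSums(o))
  # oracle equality of the count on a random binary matrix
  set.seed(5)
  m <- matrix(rbinom(600, 1, 0.3), 20, 30)
  brute <- vapply(seq_len(20), function(i) sum(m[i, ] == 1), numeric(1))
  expect_equal(unname(gene_outlier_count(m)), brute)
})

test_that("mutation frequency counts distinct samples and VAF averages records", {
  mt <- make_muts(gene = c("A", "A", "A", "A", "A", "B"),
                  sample = c("S1", "S1", "S1", "S1", "S1", "S2"),
                  ref = "C", alt = "T",
                  alt_depth = c(30, 30, 30, 30, 30, 50),
                  total_depth = 100)
  mf <- mutation_frequency(mt, sprintf("S%d", 1:10), c("A", "B", "C"))
  expect_equal(unname(mf), c(0.1, 0.1, 0))   # 5 records, 1 distinct sample
  v <- gene_vaf(make_muts(gene = c("A", "A"), sample = c("S1", "S2"),
                          ref = "C", alt = "T", alt_depth = c(30, 50),
                          total_depth = c(100, 100)),
                c("A", "Z"))
  expect_equal(unname(v), c(0.4, 0))
  expect_true(all(mf >= 0 & mf <= 1) && all(v >= 0 & v <= 1))
})

test_that("base-conversion counts follow the fixed 12-class order, SNVs only", {
  mt <- make_muts(gene = c("A", "A", "A", "B"), sample = paste0("S", 1:4),
                  ref = c("C", "C", "A", "AC"), alt = c("T", "T", "G", "A"),
                  alt_depth = 1, total_depth = 10)
  bc <- base_conversion_counts(mt, c("A", "B"))
  expect_equal(ncol(bc), 12L)
  expect_equal(colnames(bc)[1:3], c("C>A", "C>T", "C>G"))
  expect_equal(unname(bc["A", "C>T"]), 2L)
  expect_equal(unname(bc["A", "A>G"]), 1L)
  expect_equal(sum(bc["B", ]), 0L)           # indel contributes nothing
})

test_that("CNV rate follows the event-count ratio with the pseudo-event fallback", {
  om <- make_om(matrix(c(2, 1, 3), 3, 2) * rep(1, each = 3),
                matrix(c(1, 1, 0), 3, 2), type = "cnv")
  r <- cnv_rate(om)
  expect_equal(unname(r[1]), (4 * 2) / (2 * 2))   # 2.0
  expect_equal(unname(r[2]), 1)
  expect_equal(unname(r[3]), (6 * 2) / (1 * 2))   # pseudo-event denominator
})

test_that("covariate attachment aligns, median-imputes and enforces 11 columns", {
  set.seed(6)
  cov <- matrix(rnorm(55), 5, 11,
                dimnames = list(paste0("g", 1:5), gatsage:::COVARIATE_NAMES))
  out <- attach_covariates(cov, c("g2", "zzz"))
  expect_equal(out["g2", ], cov["g2", ])
  expect_equal(unname(out["zzz", ]), unname(apply(cov, 2, median)))
  expect_equal(ncol(out), 11L)
  expect_error(attach_covariates(cov[, 1:10], "g1"), "11")
})

test_that("min-max normalization maps to [0,1], zeroes constants, is idempotent", {
  m <- cbind(a = c(0, 5, 10), b = c(3, 3, 3), c = c(-1, 0, 1))
  nm <- normalize_features(m)
  expect_equal(unname(nm[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(nm[, "b"]), c(0, 0, 0))
  expect_equal(normalize_features(nm), nm)
  expect_error(normalize_features(cbind(x = c(1, Inf))), "x")
})

test_that("assembled matrix has the 36-column schema with fixed partition", {
  sim <- small_sim()
  fm <- compute_features(sim$bundle, sim$graph, sim$cprg)
  expect_equal(ncol(fm$values), 36L)
  expect_equal(unname(table(fm$schema$block)[c("genomic", "transcriptomic",
                                               "epigenomic", "network")]),
               array(c(26L, 3L, 1L, 6L)), ignore_attr = TRUE)
  expect_true(all(fm$values >= 0 & fm$values <= 1))
  expect_identical(colnames(fm$values), feature_schema()$name)
  g <- matrix(0, 2, 26); t3 <- matrix(0, 2, 3); e <- matrix(0, 2, 1)
  rownames(g) <- rownames(t3) <- rownames(e) <- c("a", "b")
  expect_error(assemble_feature_matrix(g, t3, e, NULL), "network")
})

test_that("features are invariant under sample permutation", {
  sim <- small_sim()
  b <- sim$bundle
  fm1 <- compute_features(b, sim$graph, sim$cprg)
  perm <- function(om) {
    set.seed(99); p <- sample(ncol(om$values))
    omics_matrix(om$values[, p], om$group[p], om$type)
  }
  b2 <- b
  b2$expression <- perm(b$expression)
  b2$methylation <- perm(b$methylation)
  b2$cnv <- perm(b$cnv)
  fm2 <- compute_features(b2, sim$graph, sim$cprg)
  expect_equal(fm2$values, fm1$values, tolerance = 1e-12)
})
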