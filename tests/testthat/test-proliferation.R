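test_that("core-gene selection recovers a planted coexpression factor", {
  set.seed(11)
  ns <- 80
  latent <- rnorm(ns)
  tum <- rbind(
    # genes 1-20: noisy copies of one latent factor
    t(sapply(1:20, function(i) latent * runif(1, 0.8, 1.2) +
               rnorm(ns, sd = 0.3))),
    # genes 21-30: independent noise
    matrix(rnorm(10 * ns), 10, ns))
  genes <- sprintf("c%02d", 1:30)
  om <- make_om(tum, matrix(rnorm(30 * 4), 30, 4), genes = genes)
  pm <- select_core_genes(om, genes, rho_threshold = 0.4, k = 20)
  expect_setequal(pm$core_genes, genes[1:20])
  expect_length(pm$core_genes, 20L)
  expect_length(pm$theta, ns)
  expect_error(select_core_genes(om, genes, rho_threshold = 1.01),
               "relax|significant")
})

test_that("theta has the closed form and matches a numeric optimizer", {
  S_mean <- c(1, 2, 3, 4)
  expect_equal(sample_theta(S_mean, S_mean), 1)
  expect_equal(sample_theta(2 * S_mean, S_mean), 0.5)
  expect_warning(th0 <- sample_theta(rep(0, 4), S_mean), "zero")
  expect_equal(th0, 0)
  for (seed in 1:10) {
    set.seed(seed)
    S <- rnorm(20); Sm <- rnorm(20)
    num <- unname(coef(lm(Sm ~ 0 + S)))   # QR-based least squares
    expect_equal(sample_theta(S, Sm), num, tolerance = 1e-8)
    # scale consistency: c * S -> theta / c
    expect_equal(sample_theta(3 * S, Sm), sample_theta(S, Sm) / 3,
                 tolerance = 1e-12)
  }
})

test_that("mutation association controls type-I error and has power", {
  theta_of <- function(x) setNames(x, sprintf("s%03d", seq_along(x)))
  pm <- list(theta = NULL)
  run <- function(thetaM, thetaU) {
    th <- theta_of(c(thetaM, thetaU))
    pm <- structure(list(core_genes = letters[1:20], S_mean = NULL,
                         theta = th), class = "proliferation_model")
    mt <- make_muts(gene = "CAND",
                    sample = names(th)[seq_along(thetaM)],
                    ref = "C", alt = "T", alt_depth = 1, total_depth = 10)
    mutation_association(pm, mt, "CAND")
  }
  set.seed(41)
  null_p <- replicate(500, run(rnorm(100), rnorm(100))$p_value)
  expect_lte(mean(null_p < 0.05), 0.075)
  set.seed(42)
  pow_p <- replicate(500, run(rnorm(50, 1, 0.5), rnorm(50, 0, 0.5))$p_value)
  expect_gte(mean(pow_p < 0.05), 0.95)
  # partition and degenerate-group contracts
  res <- run(rnorm(30), rnorm(70))
  expect_equal(res$M_size + res$U_size, 100L)
  th <- theta_of(rnorm(10))
  pm2 <- structure(list(theta = th), class = "proliferation_model")
  mt2 <- make_muts(gene = "X", sample = names(th), ref = "C", alt = "T",
                   alt_depth = 1, total_depth = 10)
  resd <- mutation_association(pm2, mt2, "X")
  expect_true(resd$degenerate); expect_equal(resd$p_value, 1)
})

test_that("NPCD screen drops known drivers and flags a planted theta shift", {
  set.seed(51)
  samples <- sprintf("s%03d", 1:100)
  theta <- setNames(rnorm(100), samples)
  mut_samples <- names(sort(theta, decreasing = TRUE))[1:30]  # top-theta
  pm <- structure(list(core_genes = letters[1:20], S_mean = NULL,
                       theta = theta), class = "proliferation_model")
  mt <- make_muts(gene = rep(c("HIT", "NULLG"), c(30, 30)),
                  sample = c(mut_samples, sample(samples, 30)),
                  ref = "C", alt = "T", alt_depth = 1, total_depth = 10)
  scores <- data.frame(gene = c("HIT", "NULLG", "KNOWN", paste0("g", 1:5)),
                       p_driver = c(0.99, 0.98, 0.97, runif(5, 0, 0.5)))
  res <- call_npcds(scores, known_drivers = "KNOWN", pm, mt, top_n = 3)
  expect_false("KNOWN" %in% res$gene)
  expect_true(res$is_npcd[res$gene == "HIT"])
  expect_equal(length(intersect(res$gene, "KNOWN")), 0L)
  # all-known top list gives an empty result
  res2 <- call_npcds(scores[3, , drop = FALSE], "KNOWN", pm, mt, top_n = 1)
  expect_equal(nrow(res2), 0L)
})
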