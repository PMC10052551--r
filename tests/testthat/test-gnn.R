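make_params_gat <- function(n_in, n_out, seed = 1) {
  set.seed(seed)
  list(W = matrix(rnorm(n_in * n_out, sd = 0.5), n_in, n_out),
       a = rnorm(2 * n_out, sd = 0.5), b = rnorm(n_out, sd = 0.1))
}
make_params_sage <- function(n_in, n_out, seed = 2) {
  set.seed(seed)
  list(W = matrix(rnorm(2 * n_in * n_out, sd = 0.5), 2 * n_in, n_out),
       b = rnorm(n_out, sd = 0.1))
}

test_that("GAT layer matches the dense softmax oracle on small graphs", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(4:8, 1)
    adj <- matrix(FALSE, n, n)
    for (e in seq_len(n + 2)) {
      ij <- sample(n, 2)
      adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- TRUE
    }
    genes <- paste0("v", seq_len(n))
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(genes, NULL))
    el <- which(adj & upper.tri(adj), arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(cbind(genes[el[, 1]], genes[el[, 2]]),
                                     directed = FALSE)
    # keep isolated vertices in the graph too
    g <- igraph::add_vertices(g, n - igraph::vcount(g),
                              name = setdiff(genes, igraph::V(g)$name))
    par <- make_params_gat(3, 4, seed)
    got <- gat_forward(X, g, par)
    want <- dense_gat(X, adj, par$W, par$a, par$b)
    expect_equal(unname(got), unname(want$H), tolerance = 1e-6,
                 ignore_attr = TRUE)
    # attention rows sum to 1
    at <- attr(got, "attention")
    sums <- tapply(at$alpha, at$i, sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
})

test_that("attention is symmetric over identical neighbors", {
  g <- igraph::graph_from_edgelist(cbind(c("c", "c"), c("n1", "n2")),
                                   directed = FALSE)
  X <- rbind(c = c(1, 2), n1 = c(3, 4), n2 = c(3, 4))
  got <- gat_forward(X, g, make_params_gat(2, 3))
  at <- attr(got, "attention")
  a1 <- at$alpha[at$i == "c" & at$j == "n1"]
  a2 <- at$alpha[at$i == "c" & at$j == "n2"]
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("GraphSAGE layer matches the dense concat oracle; isolates use zero", {
  for (seed in 4:6) {
    set.seed(seed)
    n <- 6
    adj <- matrix(FALSE, n, n)
    for (e in 1:7) {
      ij <- sample(n, 2)
      adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- TRUE
    }
    adj[5, ] <- adj[, 5] <- FALSE            # isolated node
    genes <- paste0("v", 1:n)
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(genes, NULL))
    el <- which(adj & upper.tri(adj), arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(cbind(genes[el[, 1]], genes[el[, 2]]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g),
                              name = setdiff(genes, igraph::V(g)$name))
    par <- make_params_sage(3, 4, seed)
    got <- sage_forward(X, g, par)
    want <- dense_sage(X, adj, par$W, par$b)
    expect_equal(unname(got), unname(want), tolerance = 1e-6,
                 ignore_attr = TRUE)
    # identical neighbor features aggregate to exactly that feature
    Xc <- X; Xc[adj[1, ], ] <- rep(X[2, ], each = sum(adj[1, ]))
  }
  # mean of constant neighbors is the constant itself
  g2 <- igraph::graph_from_edgelist(cbind(c("v", "v"), c("a", "b")),
                                    directed = FALSE)
  X2 <- rbind(v = c(1, 1), a = c(2, 3), b = c(2, 3))
  id <- list(W = diag(4)[, 1:4], b = rep(0, 4))
  out <- sage_forward(X2, g2, list(W = rbind(matrix(0, 2, 2), diag(2)),
                                   b = c(0, 0)), activation = "identity")
  expect_equal(unname(out["v", ]), c(2, 3))
})

test_that("cross-entropy matches closed forms and hand sums", {
  p <- setNames(c(0.9, 0.2, 0.5), c("a", "b", "c"))
  y <- setNames(c(1, 0, 1), c("a", "b", "c"))
  want <- -(log(0.9) + log(0.8) + log(0.5)) / 3
  expect_equal(cross_entropy(p, y), want, tolerance = 1e-12)
  expect_equal(cross_entropy(setNames(rep(0.5, 4), letters[1:4]),
                             setNames(c(1, 0, 1, 0), letters[1:4])),
               log(2), tolerance = 1e-12)
  perfect <- cross_entropy(setNames(c(1, 0), c("a", "b")),
                           setNames(c(1, 0), c("a", "b")))
  expect_lt(perfect, 1e-5)
  expect_error(cross_entropy(p, setNames(numeric(0), character(0))),
               "labeled")
})

test_that("softmax head rows sum to 1 and widths follow the config", {
  sim <- small_sim()
  fm <- compute_features(sim$bundle, sim$graph, sim$cprg)
  cfg <- gatsage_config(gat_out = 64, sage1_out = 128, epochs = 3, seed = 7)
  fit <- gatsage(fm, sim$graph, sim$labels, cfg)
  expect_equal(dim(fit$params$gat$W), c(36L, 64L))
  expect_equal(dim(fit$params$sage1$W), c(128L, 128L))
  expect_equal(dim(fit$params$sage2$W), c(256L, 2L))
  pr <- predict(fit)
  expect_true(all(pr$p_driver >= 0 & pr$p_driver <= 1))
})

test_that("same seed reproduces the fit exactly; scores are equivariant", {
  sim <- small_sim()
  fm <- compute_features(sim$bundle, sim$graph, sim$cprg)
  cfg <- small_config(epochs = 20)
  f1 <- gatsage(fm, sim$graph, sim$labels, cfg)
  f2 <- gatsage(fm, sim$graph, sim$labels, cfg)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$loss_history, f2$loss_history)

  # permuting gene order permutes the forward-pass outputs identically
  set.seed(31)
  perm <- sample(nrow(fm$values))
  p1 <- predict(f1, features = fm$values, graph = sim$graph)
  p2 <- predict(f1, features = fm$values[perm, ], graph = sim$graph)
  expect_equal(p2$p_driver[match(p1$gene, p2$gene)], p1$p_driver,
               tolerance = 1e-10)
})

test_that("training fits a linearly separable fixture to low loss", {
  sim <- small_sim()
  fm <- compute_features(sim$bundle, sim$graph, sim$cprg)
  cfg <- small_config(seed = 7, epochs = 200)
  fit <- gatsage(fm, sim$graph, sim$labels, cfg)
  expect_lt(fit$loss_history[200], 0.1)
  # 50-epoch window means decline monotonically
  w <- vapply(1:4, function(k)
    mean(fit$loss_history[(50 * k - 49):(50 * k)]), numeric(1))
  expect_true(all(diff(w) < 0.02))
  expect_gt(fit$test_ap, 0.5)
})

test_that("pseudolabel mode trains and stays deterministic", {
  sim <- small_sim()
  fm <- compute_features(sim$bundle, sim$graph, sim$cprg)
  cfg <- small_config(epochs = 10)
  f1 <- gatsage(fm, sim$graph, sim$labels, cfg, pseudolabels = TRUE)
  f2 <- gatsage(fm, sim$graph, sim$labels, cfg, pseudolabels = TRUE)
  expect_identical(f1$scores, f2$scores)
  expect_true(all(is.finite(f1$loss_history)))
})
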