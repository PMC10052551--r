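# Independent brute-force oracles and small fixture builders shared by the
# suite. These deliberately use naive dense loops so they stay independent
# of the package's sparse implementations.

# Dense single-head graph-attention forward on a small graph.
# adj: logical adjacency WITHOUT self-loops; a self-loop is always added.
dense_gat <- function(X, adj, W, a, b, slope = 0.2) {
  n <- nrow(X)
  Z <- X %*% W
  d <- ncol(Z)
  H <- matrix(0, n, d)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- sort(unique(c(i, which(adj[i, ]))))
    s <- vapply(nb, function(j) {
      v <- sum(a * c(Z[i, ], Z[j, ]))
      if (v > 0) v else slope * v
    }, numeric(1))
    e <- exp(s - max(s))
    al <- e / sum(e)
    A[i, nb] <- al
    agg <- rep(0, d)
    for (k in seq_along(nb)) agg <- agg + al[k] * Z[nb[k], ]
    u <- agg + b
    H[i, ] <- ifelse(u > 0, u, exp(u) - 1)
  }
  rownames(H) <- rownames(X)
  list(H = H, alpha = A)
}

# Dense GraphSAGE mean-aggregate + concat forward.
dense_sage <- function(X, adj, W, b, act = c("relu", "identity")) {
  act <- match.arg(act)
  n <- nrow(X)
  out <- NULL
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    hN <- if (length(nb)) colMeans(X[nb, , drop = FALSE]) else
      rep(0, ncol(X))
    p <- as.numeric(c(X[i, ], hN) %*% W) + b
    if (act == "relu") p <- pmax(p, 0)
    out <- rbind(out, p)
  }
  rownames(out) <- rownames(X)
  out
}

# Direct 11-point interpolated AP from scores/labels, computed by explicit
# enumeration of thresholds and a literal right-max over the recall grid.
ap_direct <- function(scores, y) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pr <- t(vapply(thr, function(t) {
    pred <- scores >= t
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    c(precision = tp / (tp + fp), recall = tp / sum(y == 1))
  }, numeric(2)))
  grid <- seq(0, 1, by = 0.1)
  ps <- vapply(grid, function(r) {
    ok <- pr[, "recall"] >= r - 1e-12
    if (!any(ok)) 0 else max(pr[ok, "precision"])
  }, numeric(1))
  mean(ps)
}

# Exhaustive (mutated gene, outlying gene, patient) triple enumeration.
bipartite_brute <- function(muts, om, edge_list) {
  genes <- rownames(om); patients <- colnames(om)
  out <- NULL
  for (p in patients) {
    mg <- unique(muts$gene[muts$sample == p])
    og <- genes[om[, p] > 0]
    for (i in mg) for (j in og) {
      hit <- any((edge_list[, 1] == i & edge_list[, 2] == j) |
                   (edge_list[, 1] == j & edge_list[, 2] == i))
      if (hit) out <- rbind(out, data.frame(left = i, right = j,
                                            patient = p,
                                            stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) data.frame(left = character(0), right = character(0),
                               patient = character(0)) else out
}

# Small omics matrix from explicit tumor/normal blocks.
make_om <- function(tum, nor, genes = NULL, type = "expression") {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(tum)))
  rownames(tum) <- rownames(nor) <- genes
  colnames(tum) <- sprintf("T%d", seq_len(ncol(tum)))
  colnames(nor) <- sprintf("N%d", seq_len(ncol(nor)))
  v <- cbind(tum, nor)
  grp <- setNames(rep(c("tumor", "normal"), c(ncol(tum), ncol(nor))),
                  colnames(v))
  omics_matrix(v, grp, type)
}

make_muts <- function(...) {
  mutation_table(data.frame(..., stringsAsFactors = FALSE))
}

small_sim <- function(seed = 7, ...) {
  simulate_bundle(simulation_spec(n_genes = 300, n_tumor = 60,
                                  n_normal = 10, n_drivers = 15,
                                  n_cprg = 40, seed = seed, ...))
}

small_config <- function(seed = 7, epochs = 60, ...)
  gatsage_config(gat_out = 16, sage1_out = 32, epochs = epochs,
                 seed = seed, ...)
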