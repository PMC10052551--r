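# Graph neural network: one graph-attention layer, two GraphSAGE layers,
# two-way softmax head. Forward and backward passes are written directly
# against sparse adjacency structures (Matrix); training is full-graph
# Adam on cross-entropy over labeled genes only (semisupervised: unlabeled
# genes shape the message passing but not the loss).

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(x))
relu <- function(x) pmax(x, 0)

act_fun <- function(name) switch(name,
  elu = elu, relu = relu, identity = identity,
  stop("unknown activation: ", name))

row_softmax <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# Sparse structures tied to a fixed gene ordering:
#  - An: row-normalized adjacency (mean aggregator; zero rows for isolates)
#  - GAT edge list with self-loops (ei attends over ej), plus the n x E
#    one-hot incidence matrices used for grouped softmax sums.
graph_structures <- function(graph, genes) {
  n <- length(genes)
  vs <- igraph::V(graph)$name
  missing <- setdiff(genes, vs)
  el <- igraph::as_edgelist(graph)
  el <- el[el[, 1] %in% genes & el[, 2] %in% genes, , drop = FALSE]
  i <- match(el[, 1], genes); j <- match(el[, 2], genes)
  An <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                             dims = c(n, n))
  deg <- Matrix::rowSums(An)
  sc <- ifelse(deg > 0, 1 / deg, 0)
  An <- Matrix::Diagonal(x = sc) %*% An
  ei <- c(i, j, seq_len(n)); ej <- c(j, i, seq_len(n))  # + self loops
  ord <- order(ei, ej)
  ei <- ei[ord]; ej <- ej[ord]
  E <- length(ei)
  Si <- Matrix::sparseMatrix(i = ei, j = seq_len(E), x = 1, dims = c(n, E))
  Sj <- Matrix::sparseMatrix(i = ej, j = seq_len(E), x = 1, dims = c(n, E))
  grp <- factor(ei, levels = seq_len(n))
  list(n = n, genes = genes, An = An, ei = ei, ej = ej, E = E,
       Si = Si, Sj = Sj, grp = grp, n_missing = length(missing))
}

gat_attention <- function(Z, gs, a_vec, slope) {
  d <- ncol(Z)
  q <- as.numeric(Z %*% a_vec[seq_len(d)])
  r <- as.numeric(Z %*% a_vec[d + seq_len(d)])
  s_raw <- q[gs$ei] + r[gs$ej]
  s <- leaky_relu(s_raw, slope)
  smax <- tapply(s, gs$grp, max)
  e <- exp(s - smax[gs$ei])
  denom <- as.numeric(gs$Si %*% e)
  alpha <- as.numeric(e / denom[gs$ei])
  list(alpha = alpha, s_raw = s_raw)
}

#' Graph-attention layer forward pass
#'
#' Computes single-head attention coefficients
#' `a_ij = softmax_j LeakyReLU(a^T [W h_i || W h_j])` over each node's
#' neighborhood (self-loop included so isolated nodes attend to
#' themselves), then `h_i' = sigma(sum_j a_ij W h_j)` with sigma = ELU.
#'
#' @param h node feature matrix (nodes x in_dim), rownames = gene ids.
#' @param graph PPI [igraph::graph].
#' @param params list with `W` (in_dim x out_dim), `a` (length 2*out_dim)
#'   and `b` (length out_dim).
#' @param leaky_slope negative slope of the LeakyReLU (default 0.2).
#' @param activation output nonlinearity (default `"elu"`).
#' @return embedding matrix (nodes x out_dim); attribute `attention` holds
#'   a data.frame (i, j, alpha) of the coefficients.
#' @export
gat_forward <- function(h, graph, params, leaky_slope = 0.2,
                        activation = "elu") {
  gs <- graph_structures(graph, rownames(h))
  Z <- h %*% params$W
  at <- gat_attention(Z, gs, params$a, leaky_slope)
  M <- Matrix::sparseMatrix(i = gs$ei, j = gs$ej, x = at$alpha,
                            dims = c(gs$n, gs$n))
  U <- as.matrix(M %*% Z)
  U <- sweep(U, 2, params$b, "+")
  out <- act_fun(activation)(U)
  rownames(out) <- rownames(h)
  attr(out, "attention") <- data.frame(i = gs$genes[gs$ei],
                                       j = gs$genes[gs$ej],
                                       alpha = at$alpha)
  out
}

#' GraphSAGE layer forward pass
#'
#' Mean-aggregates neighbor embeddings (`h_N(v)`), concatenates them with
#' the node's own embedding and applies a linear map and nonlinearity:
#' `h_v = sigma(W [h_v || h_N(v)])`. Neighborless nodes aggregate a zero
#' vector. By default the full neighborhood is used; `sample_size` draws a
#' fixed-size uniform sample without replacement instead.
#'
#' @param h node feature matrix (nodes x in_dim), rownames = gene ids.
#' @param graph PPI [igraph::graph].
#' @param params list with `W` ((2*in_dim) x out_dim) and `b`
#'   (length out_dim).
#' @param sample_size optional neighbor sample size (default: all).
#' @param activation output nonlinearity (default `"relu"`).
#' @return embedding matrix (nodes x out_dim).
#' @export
sage_forward <- function(h, graph, params, sample_size = NULL,
                         activation = "relu") {
  genes <- rownames(h)
  gs <- graph_structures(graph, genes)
  An <- gs$An
  if (!is.null(sample_size)) {
    nb <- lapply(seq_len(gs$n), function(v) {
      x <- setdiff(gs$ej[gs$ei == v], v)
      if (length(x) > sample_size) sample(x, sample_size) else x
    })
    ii <- rep(seq_len(gs$n), lengths(nb))
    jj <- unlist(nb)
    An <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(gs$n, gs$n))
    deg <- Matrix::rowSums(An)
    An <- Matrix::Diagonal(x = ifelse(deg > 0, 1 / deg, 0)) %*% An
  }
  hN <- as.matrix(An %*% h)
  P <- cbind(h, hN) %*% params$W
  P <- sweep(P, 2, params$b, "+")
  out <- act_fun(activation)(P)
  rownames(out) <- genes
  out
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_params <- function(n_feat, config) {
  list(
    gat = list(W = glorot(n_feat, config$gat_out),
               a = runif(2 * config$gat_out, -0.1, 0.1),
               b = numeric(config$gat_out)),
    sage1 = list(W = glorot(2 * config$gat_out, config$sage1_out),
                 b = numeric(config$sage1_out)),
    sage2 = list(W = glorot(2 * config$sage1_out, config$sage2_out),
                 b = numeric(config$sage2_out)))
}

# One full forward pass; keeps intermediates for backprop when train=TRUE.
model_forward <- function(X, gs, params, config, drop1 = NULL,
                          drop2 = NULL) {
  Z <- X %*% params$gat$W
  at <- gat_attention(Z, gs, params$gat$a, config$leaky_slope)
  M <- Matrix::sparseMatrix(i = gs$ei, j = gs$ej, x = at$alpha,
                            dims = c(gs$n, gs$n))
  U <- sweep(as.matrix(M %*% Z), 2, params$gat$b, "+")
  H1 <- elu(U)
  H1d <- if (is.null(drop1)) H1 else H1 * drop1
  C1 <- cbind(H1d, as.matrix(gs$An %*% H1d))
  P <- sweep(C1 %*% params$sage1$W, 2, params$sage1$b, "+")
  H2 <- relu(P)
  H2d <- if (is.null(drop2)) H2 else H2 * drop2
  C2 <- cbind(H2d, as.matrix(gs$An %*% H2d))
  O <- sweep(C2 %*% params$sage2$W, 2, params$sage2$b, "+")
  probs <- row_softmax(O)
  list(Z = Z, at = at, M = M, U = U, H1 = H1, C1 = C1, P = P, H2 = H2,
       C2 = C2, O = O, probs = probs)
}

model_backward <- function(X, gs, params, config, fw, dO,
                           drop1 = NULL, drop2 = NULL) {
  g <- list()
  g$sage2 <- list(W = t(fw$C2) %*% dO, b = colSums(dO))
  dC2 <- dO %*% t(params$sage2$W)
  d1 <- ncol(fw$H2)
  dH2 <- dC2[, seq_len(d1), drop = FALSE] +
    as.matrix(Matrix::t(gs$An) %*% dC2[, d1 + seq_len(d1), drop = FALSE])
  if (!is.null(drop2)) dH2 <- dH2 * drop2
  dP <- dH2 * (fw$P > 0)
  g$sage1 <- list(W = t(fw$C1) %*% dP, b = colSums(dP))
  dC1 <- dP %*% t(params$sage1$W)
  d0 <- ncol(fw$H1)
  dH1 <- dC1[, seq_len(d0), drop = FALSE] +
    as.matrix(Matrix::t(gs$An) %*% dC1[, d0 + seq_len(d0), drop = FALSE])
  if (!is.null(drop1)) dH1 <- dH1 * drop1
  dU <- dH1 * elu_grad(fw$U)
  dZ <- as.matrix(Matrix::t(fw$M) %*% dU)
  # gradient through the attention coefficients
  alpha <- fw$at$alpha
  dMe <- rowSums(dU[gs$ei, , drop = FALSE] * fw$Z[gs$ej, , drop = FALSE])
  t1 <- as.numeric(gs$Si %*% (alpha * dMe))
  dSe <- alpha * (dMe - t1[gs$ei])
  gph <- dSe * ifelse(fw$at$s_raw > 0, 1, config$leaky_slope)
  dq <- as.numeric(gs$Si %*% gph)
  dr <- as.numeric(gs$Sj %*% gph)
  d <- ncol(fw$Z)
  a1 <- params$gat$a[seq_len(d)]; a2 <- params$gat$a[d + seq_len(d)]
  dZ <- dZ + outer(dq, a1) + outer(dr, a2)
  da <- c(as.numeric(t(fw$Z) %*% dq), as.numeric(t(fw$Z) %*% dr))
  g$gat <- list(W = t(X) %*% dZ, a = da, b = colSums(dU))
  g
}

#' Cross-entropy loss over labeled genes
#'
#' `L = (1/N) sum_g -[y_g log p_g + (1 - y_g) log(1 - p_g)]` over the given
#' genes; probabilities are clamped to \[1e-7, 1-1e-7\].
#'
#' @param p named numeric vector of driver probabilities.
#' @param y named 0/1 vector (1 = driver) for the genes entering the loss.
#' @return scalar loss.
#' @export
cross_entropy <- function(p, y) {
  if (!length(y)) stop("cross-entropy needs at least one labeled gene")
  p <- pmin(pmax(p[names(y)], 1e-7), 1 - 1e-7)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

adam_step <- function(param, grad, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8, t = 1) {
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mh <- state$m / (1 - b1^t)
  vh <- state$v / (1 - b2^t)
  list(param = param - lr * mh / (sqrt(vh) + eps), state = state)
}

stratified_split <- function(y, train_fraction) {
  train <- character(0)
  for (cls in unique(y)) {
    g <- names(y)[y == cls]
    k <- max(1L, round(train_fraction * length(g)))
    train <- c(train, sample(g, k))
  }
  list(train = train, test = setdiff(names(y), train))
}

#' Fit the GAT + GraphSAGE driver-gene classifier
#'
#' Trains the three-layer graph network (graph attention, two GraphSAGE
#' layers, two-way softmax head) on the normalized genes x 36 feature
#' matrix over the PPI graph. Labeled genes are split stratified into
#' train/test (default 70/30); the cross-entropy loss runs over training
#' genes only, while unlabeled genes take part in message passing. The
#' optimizer is Adam with L2 weight decay; dropout is applied between
#' layers during training. All randomness derives from `config$seed`.
#'
#' @param features a `gene_feature_matrix` (or plain numeric matrix with
#'   gene rownames).
#' @param graph PPI [igraph::graph].
#' @param labels a `label_set` from [assign_labels()].
#' @param config a [gatsage_config()].
#' @param pseudolabels if `TRUE`, unlabeled genes enter the loss with
#'   random fair-coin labels (seeded) instead of being excluded.
#' @return object of class `gatsage`: trained parameters, per-gene score
#'   table (`scores`), train/test gene split, held-out average precision
#'   (`test_ap`), and the per-epoch loss history.
#' @seealso [predict.gatsage()], [interpolated_ap()]
#' @export
gatsage <- function(features, graph, labels, config = gatsage_config(),
                    pseudolabels = FALSE) {
  X <- if (inherits(features, "gene_feature_matrix")) features$values
       else as.matrix(features)
  genes <- rownames(X)
  stopifnot(!is.null(genes))
  lab <- labels$label[genes]
  y_all <- setNames(ifelse(lab == "positive", 1L, 0L), genes)
  labeled <- genes[lab %in% c("positive", "negative")]
  if (length(labeled) < 10)
    stop("need at least 10 labeled genes, got ", length(labeled))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  gs <- graph_structures(graph, genes)
  if (gs$n_missing)
    message(gs$n_missing, " gene(s) absent from the graph treated as isolated")
  split <- stratified_split(y_all[labeled], config$train_fraction)
  loss_genes <- split$train
  y <- y_all
  if (pseudolabels) {
    unl <- genes[lab == "unlabeled"]
    y[unl] <- pseudolabel(unl, seed = config$seed + 1L)
    loss_genes <- c(loss_genes, unl)
  }
  train_idx <- match(loss_genes, genes)
  Y <- cbind(1 - y[loss_genes], y[loss_genes])
  N <- length(loss_genes)

  params <- init_params(ncol(X), config)
  adam <- lapply(params, function(layer)
    lapply(layer, function(p) list(m = p * 0, v = p * 0)))
  loss_hist <- numeric(config$epochs)
  keep <- 1 - config$dropout

  for (ep in seq_len(config$epochs)) {
    drop1 <- if (config$dropout > 0)
      matrix(rbinom(gs$n * config$gat_out, 1, keep) / keep,
             gs$n, config$gat_out) else NULL
    drop2 <- if (config$dropout > 0)
      matrix(rbinom(gs$n * config$sage1_out, 1, keep) / keep,
             gs$n, config$sage1_out) else NULL
    fw <- model_forward(X, gs, params, config, drop1, drop2)
    p_drv <- setNames(fw$probs[, 2], genes)
    loss <- cross_entropy(p_drv, setNames(y[loss_genes], loss_genes))
    if (!is.finite(loss))
      stop("training diverged (non-finite loss) at epoch ", ep,
           " with seed ", config$seed)
    loss_hist[ep] <- loss
    dO <- matrix(0, gs$n, 2)
    dO[train_idx, ] <- (fw$probs[train_idx, , drop = FALSE] - Y) / N
    grads <- model_backward(X, gs, params, config, fw, dO, drop1, drop2)
    for (layer in names(params)) {
      for (pn in names(params[[layer]])) {
        gmat <- as.matrix(grads[[layer]][[pn]])
        gmat <- if (pn == "b") as.numeric(grads[[layer]][[pn]]) else
          gmat + config$weight_decay * params[[layer]][[pn]]
        if (pn == "a") gmat <- as.numeric(gmat)
        st <- adam_step(params[[layer]][[pn]], gmat,
                        adam[[layer]][[pn]], config$learning_rate, t = ep)
        params[[layer]][[pn]] <- st$param
        adam[[layer]][[pn]] <- st$state
      }
    }
  }

  fw <- model_forward(X, gs, params, config)
  scores <- data.frame(gene = genes, p_driver = fw$probs[, 2],
                       label = ifelse(fw$probs[, 2] > fw$probs[, 1],
                                      "driver", "passenger"),
                       stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  test_ap <- NA_real_
  if (length(split$test) && any(y_all[split$test] == 1) &&
      any(y_all[split$test] == 0)) {
    p_test <- setNames(fw$probs[match(split$test, genes), 2], split$test)
    test_ap <- interpolated_ap(smooth_pr(pr_curve(p_test,
                                                  y_all[split$test])))
  }
  structure(list(params = params, config = config, scores = scores,
                 split = split, test_ap = test_ap,
                 loss_history = loss_hist, labels = labels,
                 genes = genes, graph = graph),
            class = "gatsage")
}

#' @export
print.gatsage <- function(x, ...) {
  cat(sprintf(paste0("GAT+GraphSAGE driver-gene classifier (%s)\n",
                     "  %d genes, widths %d/%d/%d, %d epochs\n",
                     "  final loss %.4f, held-out AP %s\n"),
              x$config$tumor_type, length(x$genes), x$config$gat_out,
              x$config$sage1_out, x$config$sage2_out, x$config$epochs,
              x$loss_history[length(x$loss_history)],
              ifelse(is.na(x$test_ap), "NA", sprintf("%.3f", x$test_ap))))
  invisible(x)
}

#' @export
summary.gatsage <- function(object, ...) {
  lab <- object$labels$label[object$genes]
  out <- list(
    tumor_type = object$config$tumor_type,
    n_genes = length(object$genes),
    n_positive = sum(lab == "positive"),
    n_negative = sum(lab == "negative"),
    n_unlabeled = sum(lab == "unlabeled"),
    n_train = length(object$split$train),
    n_test = length(object$split$test),
    test_ap = object$test_ap,
    final_loss = object$loss_history[length(object$loss_history)],
    top_genes = head(object$scores[order(-object$scores$p_driver), ], 10))
  class(out) <- "summary.gatsage"
  out
}

#' @export
print.summary.gatsage <- function(x, ...) {
  cat(sprintf("Genes: %d (pos %d / neg %d / unlabeled %d)\n",
              x$n_genes, x$n_positive, x$n_negative, x$n_unlabeled))
  cat(sprintf("Split: %d train / %d test; held-out AP %.3f; final loss %.4f\n",
              x$n_train, x$n_test, x$test_ap, x$final_loss))
  cat("Top-scoring genes:\n")
  print(x$top_genes, row.names = FALSE)
  invisible(x)
}

#' @export
coef.gatsage <- function(object, ...) object$params

#' @export
fitted.gatsage <- function(object, ...)
  setNames(object$scores$p_driver, object$scores$gene)

#' Score genes with a trained model
#'
#' Runs the deterministic forward pass (no dropout) on a feature matrix and
#' graph; defaults to the training inputs.
#'
#' @param object a fitted `gatsage` model.
#' @param features optional new feature matrix (genes x 36).
#' @param graph optional new PPI graph.
#' @param ... unused.
#' @return data.frame (gene, p_driver, label).
#' @export
predict.gatsage <- function(object, features = NULL, graph = NULL, ...) {
  if (is.null(features) && is.null(graph)) return(object$scores)
  X <- if (inherits(features, "gene_feature_matrix")) features$values
       else as.matrix(features)
  g <- if (is.null(graph)) object$graph else graph
  gs <- graph_structures(g, rownames(X))
  fw <- model_forward(X, gs, object$params, object$config)
  data.frame(gene = rownames(X), p_driver = fw$probs[, 2],
             label = ifelse(fw$probs[, 2] > fw$probs[, 1],
                            "driver", "passenger"),
             stringsAsFactors = FALSE)
}

#' Plot training loss and the held-out precision-recall curve
#' @param x a fitted `gatsage` model.
#' @param ... passed to [plot()].
#' @export
plot.gatsage <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$loss_history, type = "l", xlab = "epoch",
       ylab = "cross-entropy loss", main = "training loss", ...)
  y <- setNames(ifelse(x$labels$label[x$split$test] == "positive", 1, 0),
                x$split$test)
  p <- fitted(x)[x$split$test]
  cur <- smooth_pr(pr_curve(p, y))
  plot(cur$recall, cur$precision, type = "s", xlim = c(0, 1),
       ylim = c(0, 1), xlab = "recall", ylab = "precision",
       main = sprintf("held-out PR (AP = %.3f)", x$test_ap), ...)
  invisible(x)
}

#' Write a model's score table to TSV
#' @param model fitted `gatsage` object.
#' @param path output TSV.
#' @export
write_score_table <- function(model, path) {
  write.table(model$scores, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
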