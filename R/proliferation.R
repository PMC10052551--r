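# Cell-proliferation validation of candidate drivers: pick a core set of
# tightly coexpressed proliferation genes, summarize each tumor sample's
# proliferation activity by a single regression coefficient theta, and test
# whether samples mutated in a candidate gene show shifted theta.

#' Select proliferation core genes and compute per-sample activity
#'
#' Among the cell-proliferation-related genes (CPRGs) present in the
#' expression matrix, every pair is tested for coexpression over tumor
#' samples (Spearman; a pair counts when |rho| >= `rho_threshold` and
#' p < `p_cutoff`). Genes are ranked by their number of significant
#' partners (ties: mean |rho|, then gene symbol) and the top `k` become the
#' core set. Each tumor sample's proliferation activity theta is the
#' no-intercept least-squares coefficient regressing the core-gene mean
#' expression vector on the sample's core-gene expression (see
#' [sample_theta()]).
#'
#' @param expr expression [omics_matrix()].
#' @param cprg character vector of CPRG symbols.
#' @param rho_threshold absolute Spearman cutoff (default 0.4).
#' @param p_cutoff coexpression p-value cutoff (default 1e-3).
#' @param k core-set size (default 20).
#' @return list of class `proliferation_model`: `core_genes`, `S_mean`
#'   (mean core-gene expression across tumor samples), `theta` (named
#'   vector over tumor samples).
#' @export
select_core_genes <- function(expr, cprg, rho_threshold = 0.4,
                              p_cutoff = 1e-3, k = 20L) {
  tum <- expr$values[, expr$group == "tumor", drop = FALSE]
  genes <- intersect(cprg, rownames(tum))
  if (length(genes) < k)
    stop("need at least ", k, " CPRGs in the expression matrix, have ",
         length(genes))
  m <- t(tum[genes, , drop = FALSE])
  n <- ncol(m)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  # t-approximation p-value for Spearman's rho
  ns <- nrow(m)
  tstat <- rho * sqrt((ns - 2) / pmax(1 - rho^2, 1e-12))
  pval <- 2 * stats::pt(abs(tstat), df = ns - 2, lower.tail = FALSE)
  diag(rho) <- 0; diag(pval) <- 1
  sig <- abs(rho) >= rho_threshold & pval < p_cutoff
  partners <- rowSums(sig)
  if (sum(partners >= 1) < k)
    stop("fewer than ", k, " CPRGs have a significantly coexpressed ",
         "partner; relax rho_threshold or p_cutoff")
  mean_abs <- rowSums(abs(rho) * sig) / pmax(partners, 1)
  ord <- order(-partners, -mean_abs, genes)
  core <- genes[ord][seq_len(k)]
  S <- tum[core, , drop = FALSE]
  S_mean <- rowMeans(S, na.rm = TRUE)
  theta <- apply(S, 2, sample_theta, S_mean = S_mean)
  structure(list(core_genes = core, S_mean = S_mean, theta = theta),
            class = "proliferation_model")
}

#' @export
print.proliferation_model <- function(x, ...) {
  cat(sprintf("<proliferation_model> %d core genes, theta over %d samples\n",
              length(x$core_genes), length(x$theta)))
  invisible(x)
}

#' Per-sample proliferation activity theta
#'
#' The scalar minimizing `sum_i (S_mean(i) - theta * S(i))^2`, i.e. the
#' no-intercept regression coefficient `theta = (S . S_mean) / (S . S)` of
#' the core-gene mean vector on the sample's core-gene expression. An
#' all-zero sample gives theta = 0 with a warning.
#'
#' @param S the sample's core-gene expression vector.
#' @param S_mean mean core-gene expression vector across samples.
#' @return scalar theta.
#' @export
sample_theta <- function(S, S_mean) {
  ss <- sum(S * S)
  if (ss == 0) {
    warning("all-zero core-gene vector; theta set to 0")
    return(0)
  }
  sum(S * S_mean) / ss
}

#' Test a candidate gene's mutations against proliferation activity
#'
#' Splits tumor samples into mutated (M: >= 1 mutation record for the gene)
#' and unmutated (U) groups and compares their theta distributions with a
#' two-sided Wilcoxon rank-sum test (exact when both groups have <= 20
#' samples and no ties; normal approximation otherwise). A candidate with
#' p < 0.05 is flagged a newly predicted cancer driver (NPCD).
#'
#' @param pm a `proliferation_model`.
#' @param muts a `mutation_table`.
#' @param gene candidate gene symbol.
#' @param alpha NPCD significance cutoff (default 0.05).
#' @return one-row data.frame: `gene`, `M_size`, `U_size`, `median_M`,
#'   `median_U`, `p_value`, `is_npcd`, `degenerate`.
#' @export
mutation_association <- function(pm, muts, gene, alpha = 0.05) {
  samples <- names(pm$theta)
  mut_samples <- unique(muts$sample[muts$gene == gene])
  M <- intersect(samples, mut_samples)
  U <- setdiff(samples, M)
  if (!length(M) || !length(U))
    return(data.frame(gene = gene, M_size = length(M), U_size = length(U),
                      median_M = ifelse(length(M), median(pm$theta[M]), NA),
                      median_U = ifelse(length(U), median(pm$theta[U]), NA),
                      p_value = 1, is_npcd = FALSE, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  exact <- length(M) <= 20 && length(U) <= 20
  p <- suppressWarnings(
    wilcox.test(pm$theta[M], pm$theta[U], exact = exact)$p.value)
  data.frame(gene = gene, M_size = length(M), U_size = length(U),
             median_M = median(pm$theta[M]), median_U = median(pm$theta[U]),
             p_value = p, is_npcd = p < alpha, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Screen top-scoring genes for newly predicted cancer drivers
#'
#' Takes the `top_n` genes by driver probability, drops those already in
#' the known-driver catalogue, and runs [mutation_association()] on each
#' remaining candidate; the output is sorted by p-value.
#'
#' @param scores data.frame (gene, p_driver) — e.g. a fitted model's
#'   `$scores`.
#' @param known_drivers character vector of catalogued driver genes.
#' @param pm a `proliferation_model`.
#' @param muts a `mutation_table`.
#' @param top_n number of top-scoring genes screened (default 20).
#' @param alpha NPCD cutoff (default 0.05).
#' @return data.frame of per-candidate results (possibly 0 rows).
#' @export
call_npcds <- function(scores, known_drivers, pm, muts, top_n = 20L,
                       alpha = 0.05) {
  top <- scores$gene[order(-scores$p_driver)][seq_len(min(top_n,
                                                          nrow(scores)))]
  cand <- setdiff(top, known_drivers)
  if (!length(cand))
    return(data.frame(gene = character(0), M_size = integer(0),
                      U_size = integer(0), median_M = numeric(0),
                      median_U = numeric(0), p_value = numeric(0),
                      is_npcd = logical(0), degenerate = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, lapply(cand, function(g)
    mutation_association(pm, muts, g, alpha)))
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}
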