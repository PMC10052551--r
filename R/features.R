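# Feature engine: the 30 per-gene omics features plus assembly of the final
# genes x 36 matrix. All group means skip missing values; eps protects
# ratios against empty/zero groups.

EPS <- 1e-6

BASE_CONVERSIONS <- c("C>A", "C>T", "C>G", "A>T", "A>C", "A>G",
                      "G>C", "G>A", "G>T", "T>A", "T>G", "T>C")

#' The fixed 36-column feature schema
#'
#' Column order is a package constant: 26 genomic features (mutation
#' frequency, variant allele fraction, 11 covariates, 12 base-conversion
#' counts, CNV rate), 3 transcriptomic (expression log2 fold change,
#' differential-expression flag, outlier count), 1 epigenomic (methylation
#' fold change) and 6 network-derived (4 bipartite-graph features, degree,
#' betweenness).
#'
#' @return data.frame with columns `name` and `block`.
#' @export
feature_schema <- function() {
  data.frame(
    name = c("mutation_frequency", "vaf", COVARIATE_NAMES,
             paste0("conv_", gsub(">", "_", BASE_CONVERSIONS)), "cnv_rate",
             "expr_fold_change", "de_flag", "outlier_count",
             "methylation_fold_change",
             "bipartite_E", "bipartite_LCPRG", "bipartite_CPRG", "NSC",
             "degree", "betweenness"),
    block = c(rep("genomic", 26), rep("transcriptomic", 3), "epigenomic",
              rep("network", 6)),
    stringsAsFactors = FALSE)
}

group_means <- function(om) {
  tum <- om$values[, om$group == "tumor", drop = FALSE]
  nor <- om$values[, om$group == "normal", drop = FALSE]
  list(tumor = rowMeans(tum, na.rm = TRUE),
       normal = rowMeans(nor, na.rm = TRUE))
}

#' Methylation fold change between tumor and normal means
#'
#' Per gene, the ratio of the mean tumor beta to the mean normal beta, with
#' a pseudocount of 1e-6 on both sides; no log is taken. Genes with
#' all-missing values in either group get 0.
#'
#' @param meth methylation [omics_matrix()].
#' @return named numeric vector per gene.
#' @export
methylation_fold_change <- function(meth) {
  gm <- group_means(meth)
  out <- (gm$tumor + EPS) / (gm$normal + EPS)
  out[!is.finite(gm$tumor) | !is.finite(gm$normal)] <- 0
  out
}

#' Expression log2 fold change between tumor and normal means
#'
#' log2((mean tumor + 1e-6) / (mean normal + 1e-6)); genes not measured in
#' either group are set to 0 exactly.
#'
#' @param expr expression [omics_matrix()].
#' @param log2 set `FALSE` for the plain protected ratio.
#' @return named numeric vector per gene.
#' @export
expression_fold_change <- function(expr, log2 = TRUE) {
  gm <- group_means(expr)
  ratio <- (gm$tumor + EPS) / (gm$normal + EPS)
  out <- if (log2) base::log2(ratio) else ratio
  out[!is.finite(gm$tumor) | !is.finite(gm$normal)] <- 0
  out
}

#' Ternary differential-expression flag from a Wilcoxon rank-sum test
#'
#' Two-sided test of tumor vs normal expression per gene. Non-significant
#' genes get 0; significant genes get +1 when the tumor mean exceeds the
#' normal mean and -1 otherwise. Groups with fewer than two non-missing
#' values yield 0 with a warning.
#'
#' @param expr expression [omics_matrix()].
#' @param alpha significance level (default 0.05).
#' @return named integer vector in \{-1, 0, 1\}.
#' @export
de_significance_flag <- function(expr, alpha = 0.05) {
  tum <- expr$values[, expr$group == "tumor", drop = FALSE]
  nor <- expr$values[, expr$group == "normal", drop = FALSE]
  n <- nrow(tum)
  out <- integer(n)
  warned <- FALSE
  for (i in seq_len(n)) {
    x <- tum[i, ][is.finite(tum[i, ])]
    y <- nor[i, ][is.finite(nor[i, ])]
    if (length(x) < 2 || length(y) < 2) {
      warned <- TRUE
      next
    }
    p <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    if (is.na(p) || p >= alpha) next
    out[i] <- if (mean(y) < mean(x)) 1L else -1L
  }
  if (warned) warning("genes with <2 values in a group flagged 0")
  names(out) <- rownames(expr$values)
  out
}

#' One-sided Grubbs critical value
#'
#' G_p(N) = ((N-1)/sqrt(N)) * sqrt(t^2 / (N-2+t^2)), with t the upper
#' alpha/(2N) quantile of Student's t on N-2 degrees of freedom. A z-score
#' above this bound marks a sample as an expression outlier for the gene.
#'
#' @param n number of samples (>= 3).
#' @param alpha significance level (default 0.05).
#' @return scalar critical value.
#' @export
grubbs_critical_value <- function(n, alpha = 0.05) {
  if (any(n < 3)) stop("Grubbs critical value needs n >= 3")
  t <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Patient-outlier matrix from the Grubbs test
#'
#' Per gene, z-scores each tumor sample against the mean and SD over tumor
#' samples and marks 1 where the signed score exceeds the Grubbs critical
#' value (upper tail only). Genes with zero SD give an all-zero row.
#'
#' @param expr expression [omics_matrix()] with at least 3 tumor samples.
#' @param alpha Grubbs significance level.
#' @return binary matrix, genes x tumor samples.
#' @export
outlier_matrix <- function(expr, alpha = 0.05) {
  tum <- expr$values[, expr$group == "tumor", drop = FALSE]
  n <- ncol(tum)
  if (n < 3) stop("outlier matrix needs >= 3 tumor samples")
  mu <- rowMeans(tum, na.rm = TRUE)
  s <- apply(tum, 1, sd, na.rm = TRUE)
  g <- (tum - mu) / s
  crit <- grubbs_critical_value(n, alpha)
  out <- (g > crit) + 0
  out[!is.finite(out)] <- 0
  out[s == 0 | !is.finite(s), ] <- 0
  out
}

#' Per-gene outlier count
#' @param om binary outlier matrix from [outlier_matrix()].
#' @return named integer vector of row sums.
#' @export
gene_outlier_count <- function(om) rowSums(om)

#' Mutation frequency per gene
#'
#' Fraction of tumor samples carrying at least one mutation record for the
#' gene (distinct samples, not records).
#'
#' @param muts a `mutation_table`.
#' @param tumor_samples character vector of tumor sample barcodes.
#' @param gene_ids genes to report (default: genes present in `muts`).
#' @return named numeric vector in \[0,1\].
#' @export
mutation_frequency <- function(muts, tumor_samples,
                               gene_ids = unique(muts$gene)) {
  if (!length(tumor_samples)) stop("tumor_samples must be non-empty")
  m <- muts[muts$sample %in% tumor_samples, , drop = FALSE]
  hits <- unique(m[, c("gene", "sample")])
  cnt <- table(factor(hits$gene, levels = gene_ids))
  setNames(as.numeric(cnt) / length(tumor_samples), gene_ids)
}

#' Mean variant allele fraction per gene
#'
#' Mean over the gene's mutation records of alt depth / total depth;
#' unmutated genes get 0.
#'
#' @inheritParams mutation_frequency
#' @return named numeric vector in \[0,1\].
#' @export
gene_vaf <- function(muts, gene_ids = unique(muts$gene)) {
  vaf <- muts$alt_depth / muts$total_depth
  agg <- tapply(vaf, factor(muts$gene, levels = gene_ids), mean)
  out <- as.numeric(agg)
  out[is.na(out)] <- 0
  setNames(out, gene_ids)
}

#' Base-conversion counts per gene (12 columns)
#'
#' Counts the gene's SNV records in each of the 12 ordered substitution
#' classes C>A, C>T, C>G, A>T, A>C, A>G, G>C, G>A, G>T, T>A, T>G, T>C.
#' Non-SNV records contribute nothing.
#'
#' @inheritParams mutation_frequency
#' @return integer matrix, genes x 12.
#' @export
base_conversion_counts <- function(muts, gene_ids = unique(muts$gene)) {
  snv <- muts[muts$is_snv, , drop = FALSE]
  cls <- paste0(snv$ref, ">", snv$alt)
  tab <- table(factor(snv$gene, levels = gene_ids),
               factor(cls, levels = BASE_CONVERSIONS))
  m <- matrix(as.integer(tab), nrow = length(gene_ids),
              dimnames = list(gene_ids, BASE_CONVERSIONS))
  m
}

#' Copy-number variation rate per gene
#'
#' (sum over tumor samples of |call| x n_normal) divided by (sum over
#' normal samples of |call| x n_tumor). A gene with zero normal events
#' gets one pseudo-event in the normal sum so the rate stays finite.
#'
#' @param cnv CNV [omics_matrix()].
#' @return named numeric vector per gene.
#' @export
cnv_rate <- function(cnv) {
  tum <- abs(cnv$values[, cnv$group == "tumor", drop = FALSE])
  nor <- abs(cnv$values[, cnv$group == "normal", drop = FALSE])
  m <- ncol(tum); n <- ncol(nor)
  ts <- rowSums(tum, na.rm = TRUE)
  ns <- rowSums(nor, na.rm = TRUE)
  ns[ns == 0] <- 1
  (ts * n) / (ns * m)
}

#' Align the 11-covariate table to a gene universe
#'
#' Genes absent from the table are imputed with the per-covariate median.
#'
#' @param cov matrix from [read_covariate_table()] (11 columns).
#' @param gene_ids target gene order.
#' @return numeric matrix, length(gene_ids) x 11.
#' @export
attach_covariates <- function(cov, gene_ids) {
  if (ncol(cov) != 11)
    stop("covariate table must have exactly 11 columns")
  out <- matrix(NA_real_, length(gene_ids), 11,
                dimnames = list(gene_ids, colnames(cov)))
  hit <- intersect(gene_ids, rownames(cov))
  out[hit, ] <- cov[hit, ]
  med <- apply(cov, 2, median, na.rm = TRUE)
  for (j in seq_len(11)) out[is.na(out[, j]), j] <- med[j]
  out
}

#' Min-max normalize a feature matrix
#'
#' Each feature (column) is rescaled to \[0,1\] across genes:
#' (x - min) / (max - min). Constant features map to all-zero. Idempotent
#' on already-normalized input.
#'
#' @param raw numeric matrix, genes x features.
#' @return matrix of the same shape with all entries in \[0,1\].
#' @export
normalize_features <- function(raw) {
  bad <- which(!apply(raw, 2, function(x) all(is.finite(x))))
  if (length(bad))
    stop("non-finite values in feature(s): ",
         paste(colnames(raw)[bad], collapse = ", "))
  lo <- apply(raw, 2, min)
  hi <- apply(raw, 2, max)
  rng <- hi - lo
  out <- sweep(raw, 2, lo, "-")
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  out
}

#' Assemble and normalize the genes x 36 feature matrix
#'
#' Concatenates the feature blocks in the fixed schema order (see
#' [feature_schema()]) and applies [normalize_features()]. All blocks must
#' cover the same gene universe in the same order.
#'
#' @param genomic genes x 26 matrix (mutation frequency, VAF,
#'   11 covariates, 12 conversions, CNV rate).
#' @param transcriptomic genes x 3 matrix (fold change, DE flag,
#'   outlier count).
#' @param epigenomic genes x 1 matrix (methylation fold change).
#' @param network genes x 6 matrix (4 bipartite features, degree,
#'   betweenness).
#' @return list of class `gene_feature_matrix` with elements `values`
#'   (normalized genes x 36 matrix) and `schema`.
#' @export
assemble_feature_matrix <- function(genomic, transcriptomic, epigenomic,
                                    network) {
  blocks <- list(genomic = genomic, transcriptomic = transcriptomic,
                 epigenomic = epigenomic, network = network)
  widths <- c(genomic = 26L, transcriptomic = 3L, epigenomic = 1L,
              network = 6L)
  for (nm in names(widths)) {
    if (is.null(blocks[[nm]]))
      stop("missing feature block: ", nm)
    blocks[[nm]] <- as.matrix(blocks[[nm]])
    if (ncol(blocks[[nm]]) != widths[[nm]])
      stop(nm, " block must have ", widths[[nm]], " columns, got ",
           ncol(blocks[[nm]]))
  }
  genes <- rownames(blocks$genomic)
  for (nm in names(blocks))
    if (!identical(rownames(blocks[[nm]]), genes))
      stop("gene ids of block '", nm, "' do not match the genomic block")
  raw <- do.call(cbind, unname(blocks))
  schema <- feature_schema()
  colnames(raw) <- schema$name
  stopifnot(ncol(raw) == 36)
  structure(list(values = normalize_features(raw), schema = schema),
            class = "gene_feature_matrix")
}

#' @export
print.gene_feature_matrix <- function(x, ...) {
  cat(sprintf("<gene_feature_matrix> %d genes x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", unique(x$schema$block),
                            table(x$schema$block)[unique(x$schema$block)]),
                    collapse = ", ")))
  invisible(x)
}

#' Write a feature matrix and its schema manifest to TSV
#' @param fm a `gene_feature_matrix`.
#' @param path output TSV; the schema manifest goes to
#'   `paste0(path, ".schema.tsv")`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(gene = rownames(fm$values), fm$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fm$schema, paste0(path, ".schema.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compute the full genes x 36 feature matrix from an omics bundle
#'
#' Convenience wrapper running the whole feature engine: the 26 genomic,
#' 3 transcriptomic and 1 epigenomic features from the omics tables, the
#' mutation-outlier bipartite features and the network centralities, then
#' assembly + min-max normalization.
#'
#' @param bundle an `omics_bundle` (see [simulate_bundle()] for the layout).
#' @param graph PPI [igraph::graph].
#' @param cprg character vector of cell-proliferation-related genes.
#' @param centrality_graph optional second network for degree/betweenness
#'   (defaults to `graph`).
#' @param alpha significance level shared by the DE flag and Grubbs test.
#' @return a `gene_feature_matrix`.
#' @export
compute_features <- function(bundle, graph, cprg,
                             centrality_graph = graph, alpha = 0.05) {
  expr <- bundle$expression
  genes <- rownames(expr$values)
  tums <- tumor_samples(expr)

  om <- outlier_matrix(expr, alpha)
  genomic <- cbind(
    mutation_frequency(bundle$mutations, tums, genes),
    gene_vaf(bundle$mutations, genes),
    attach_covariates(bundle$covariates, genes),
    base_conversion_counts(bundle$mutations, genes),
    cnv_rate(bundle$cnv)[genes])
  transcriptomic <- cbind(
    expression_fold_change(expr),
    de_significance_flag(expr, alpha),
    gene_outlier_count(om))
  epigenomic <- cbind(methylation_fold_change(bundle$methylation)[genes])
  rownames(epigenomic) <- genes

  bg <- build_bipartite(bundle$mutations, om, graph)
  bf <- bipartite_features(bg, cprg, tums, genes)
  cf <- centrality_features(centrality_graph, genes)
  network <- cbind(bf, cf)

  rownames(genomic) <- genes
  rownames(transcriptomic) <- genes
  rownames(network) <- genes
  assemble_feature_matrix(genomic, transcriptomic, epigenomic, network)
}
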