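#' @importFrom stats median qt wilcox.test cor cor.test rnorm rbinom rpois
#'   runif rbeta quantile setNames complete.cases sd
#' @importFrom utils read.delim write.table head
NULL

#' Construct a gene-by-sample omics matrix
#'
#' The common container for expression, methylation and copy-number tables:
#' a numeric matrix with gene symbols as row names, sample barcodes as column
#' names, and a tumor/normal group assignment per sample. Missing values are
#' encoded as `NA`; all group means downstream are computed over present
#' values only.
#'
#' @param values numeric matrix, genes x samples, with dimnames.
#' @param group named character vector mapping every sample to `"tumor"` or
#'   `"normal"`.
#' @param type one of `"expression"`, `"methylation"`, `"cnv"`; switches
#'   type-specific validation (methylation beta in \[0,1\], CNV integer calls).
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, group,
                         type = c("expression", "methylation", "cnv")) {
  type <- match.arg(type)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  missing_grp <- setdiff(colnames(values), names(group))
  if (length(missing_grp))
    stop("samples with no tumor/normal group: ",
         paste(missing_grp, collapse = ", "))
  group <- group[colnames(values)]
  if (!all(group %in% c("tumor", "normal")))
    stop("groups must be 'tumor' or 'normal'")
  if (type == "methylation") {
    v <- values[is.finite(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("methylation beta values must lie in [0,1]")
  }
  if (type == "cnv") {
    v <- values[is.finite(values)]
    if (length(v) && any(v != round(v)))
      stop("CNV calls must be integer-valued")
  }
  structure(list(values = values, group = group, type = type),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix:%s> %d genes x %d samples (%d tumor, %d normal)\n",
              x$type, nrow(x$values), ncol(x$values),
              sum(x$group == "tumor"), sum(x$group == "normal")))
  invisible(x)
}

tumor_samples  <- function(om) names(om$group)[om$group == "tumor"]
normal_samples <- function(om) names(om$group)[om$group == "normal"]

read_group_map <- function(path) {
  g <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(g) < 2) stop("group map needs two columns: sample, group")
  setNames(trimws(g[[2]]), trimws(g[[1]]))
}

read_matrix_tsv <- function(path, group_map, type) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  genes <- trimws(as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(df[, -1, drop = FALSE], 2,
                        function(col) all(is.na(col) | !is.na(suppressWarnings(as.numeric(col))))))
    stop("non-numeric cell(s) in column(s): ",
         paste(colnames(df)[-1][bad], collapse = ", "))
  }
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing duplicated gene rows by mean: ",
            paste(dup, collapse = ", "))
    m <- rowsum(m, group = genes, reorder = FALSE, na.rm = TRUE) /
      as.vector(rowsum((!is.na(m)) + 0, group = genes, reorder = FALSE))
    m[!is.finite(m)] <- NA_real_
  }
  grp <- if (is.character(group_map) && length(group_map) == 1 &&
             file.exists(group_map)) read_group_map(group_map) else group_map
  omics_matrix(m, grp, type = type)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample barcodes with gene symbols in the first
#' column. Duplicated gene rows are collapsed by their mean with a warning.
#'
#' @param path TSV file path.
#' @param group_map either a two-column TSV path (sample, group) or a named
#'   character vector sample -> `"tumor"`/`"normal"`.
#' @return an [omics_matrix()] of type `"expression"`.
#' @export
read_expression_matrix <- function(path, group_map)
  read_matrix_tsv(path, group_map, "expression")

#' Read a gene-level methylation beta matrix from TSV
#' @inheritParams read_expression_matrix
#' @return an [omics_matrix()] of type `"methylation"`.
#' @export
read_methylation_matrix <- function(path, group_map)
  read_matrix_tsv(path, group_map, "methylation")

#' Read a GISTIC-style integer CNV call matrix from TSV
#' @inheritParams read_expression_matrix
#' @return an [omics_matrix()] of type `"cnv"`.
#' @export
read_cnv_matrix <- function(path, group_map)
  read_matrix_tsv(path, group_map, "cnv")

#' Write an omics matrix back to TSV
#' @param om an [omics_matrix()].
#' @param path output TSV path.
#' @export
write_omics_matrix <- function(om, path) {
  df <- data.frame(gene = rownames(om$values), om$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# The 11 MutSigCV-style mutational-heterogeneity covariates, fixed order.
COVARIATE_NAMES <- c(
  "replication_time", "noncoding_mutation_rate", "local_gc_content",
  "hic_compartment", "local_gene_density", "wgs_mean_depth",
  "wgs_percent_20x", "capture_on_target_rate", "capture_mean_depth",
  "capture_pct200", "capture_mean_percentgc")

#' Read the gene covariate table (11 mutational-heterogeneity columns)
#'
#' @param path TSV with gene symbols in the first column and exactly 11
#'   numeric covariate columns (replication time, noncoding mutation rate,
#'   local GC content, HiC compartment, local gene density, WGS mean depth,
#'   WGS percent 20x, capture on-target rate, capture mean depth, capture
#'   pct200, capture mean percent GC).
#' @return numeric matrix, genes x 11, with the canonical column names.
#' @export
read_covariate_table <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (ncol(m) != 11)
    stop("covariate table must have exactly 11 covariate columns, got ",
         ncol(m))
  rownames(m) <- trimws(as.character(df[[1]]))
  colnames(m) <- COVARIATE_NAMES
  storage.mode(m) <- "double"
  m
}

#' Read a MAF-dialect somatic mutation table
#'
#' Accepts either plain column names (`gene`, `sample`, `ref`, `alt`,
#' `alt_depth`, `total_depth`) or the MAF dialect (`Hugo_Symbol`,
#' `Tumor_Sample_Barcode`, `Reference_Allele`, `Tumor_Seq_Allele2`,
#' `t_alt_count`, `t_depth`). Rows whose alleles are not single A/C/G/T
#' bases (indels, multi-base substitutions) are retained for mutation
#' frequency and VAF but flagged `is_snv = FALSE` so they never enter
#' base-conversion counting. Rows with `alt_depth > total_depth` are
#' rejected with a warning.
#'
#' @param path TSV file path.
#' @return a `data.frame` of class `mutation_table` with columns
#'   `gene`, `sample`, `ref`, `alt`, `alt_depth`, `total_depth`, `is_snv`;
#'   attribute `n_rejected` counts dropped rows.
#' @export
read_mutation_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
    stop("mutation table missing a required column (tried: ",
         paste(c(...), collapse = ", "), ")")
  }
  out <- data.frame(
    gene = trimws(as.character(pick("gene", "Hugo_Symbol"))),
    sample = trimws(as.character(pick("sample", "Tumor_Sample_Barcode"))),
    ref = toupper(trimws(as.character(pick("ref", "Reference_Allele")))),
    alt = toupper(trimws(as.character(pick("alt", "Tumor_Seq_Allele2")))),
    alt_depth = as.integer(pick("alt_depth", "t_alt_count")),
    total_depth = as.integer(pick("total_depth", "t_depth")),
    stringsAsFactors = FALSE)
  mutation_table(out)
}

#' Construct/validate a mutation table
#' @param df data.frame with columns `gene`, `sample`, `ref`, `alt`,
#'   `alt_depth`, `total_depth`.
#' @return validated `mutation_table` (see [read_mutation_table()]).
#' @export
mutation_table <- function(df) {
  bad <- which(df$alt_depth > df$total_depth | df$total_depth <= 0 |
                 df$alt_depth < 0)
  if (length(bad)) {
    warning(length(bad), " mutation record(s) rejected (alt depth exceeds ",
            "total depth or non-positive depth)")
    df <- df[-bad, , drop = FALSE]
  }
  bases <- c("A", "C", "G", "T")
  df$is_snv <- df$ref %in% bases & df$alt %in% bases & df$ref != df$alt
  rownames(df) <- NULL
  structure(df, class = c("mutation_table", "data.frame"),
            n_rejected = length(bad))
}

#' Read a scored PPI edge list and build the interaction graph
#'
#' Keeps edges whose confidence score is strictly greater than `threshold`.
#' Both the 0-1 and the STRING 0-1000 score scales are accepted: if any
#' score exceeds 1 the file is treated as 0-1000 and the threshold is
#' multiplied by 1000. Self-loops are dropped; duplicated pairs are merged
#' keeping the maximum score. Unscored two-column files keep every edge.
#'
#' @param path two- or three-column TSV (geneA, geneB\[, score\]).
#' @param threshold score cutoff on the 0-1 scale (default 0.9).
#' @return an undirected simple [igraph::graph] with vertex `name`s and an
#'   edge attribute `score` when scores were present.
#' @export
read_ppi_edges <- function(path, threshold = 0.9) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("PPI edge list needs at least two columns")
  a <- trimws(as.character(df[[1]])); b <- trimws(as.character(df[[2]]))
  if (ncol(df) >= 3) {
    score <- as.numeric(df[[3]])
    thr <- if (any(score > 1, na.rm = TRUE)) threshold * 1000 else threshold
    keep <- !is.na(score) & score > thr
    a <- a[keep]; b <- b[keep]; score <- score[keep]
  } else score <- NULL
  ppi_graph(a, b, score)
}

#' Build a PPI graph from edge endpoint vectors
#' @param a,b character vectors of endpoints.
#' @param score optional numeric edge scores.
#' @return simple undirected igraph; duplicate pairs keep the max score.
#' @export
ppi_graph <- function(a, b, score = NULL) {
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  if (!is.null(score)) score <- score[keep]
  if (!length(a)) stop("no surviving edges: the PPI graph would be empty")
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  first <- !duplicated(key)
  g <- igraph::graph_from_edgelist(cbind(lo[first], hi[first]),
                                   directed = FALSE)
  if (!is.null(score)) {
    agg <- tapply(score, key, max)
    igraph::E(g)$score <- as.numeric(agg[key[first]])
  }
  g
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: tab-separated lines `name<TAB>description<TAB>gene...`.
#' @return named list of character vectors (de-duplicated, order-preserving).
#'   Lines with fewer than three fields are skipped with a warning.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(list())
  }
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      warning("skipping GMT line with fewer than 3 fields")
      next
    }
    out[[trimws(f[1])]] <- unique(trimws(f[-(1:2)]))
  }
  out
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run configuration for a tumor-type analysis
#'
#' Bundles the tunable parameters of the whole pipeline: graph-layer widths
#' (the two-way softmax head is fixed), training hyperparameters, the PPI
#' score cutoff, and the thresholds of the labeling and proliferation steps.
#'
#' @param tumor_type free-text identifier.
#' @param gat_out,sage1_out widths of the attention layer and first
#'   GraphSAGE layer (the defaults mirror a typical 36/64, 64/128, 128/2
#'   configuration).
#' @param train_fraction fraction of labeled genes used for training
#'   (default 0.7, stratified by label).
#' @param learning_rate,epochs,dropout,weight_decay Adam training knobs.
#' @param leaky_slope negative slope of the attention LeakyReLU.
#' @param string_score_threshold PPI confidence cutoff (edges kept strictly
#'   above it).
#' @param spearman_threshold absolute Spearman rho above which a gene is
#'   considered expression-associated with a known driver (labeling) or two
#'   proliferation genes coexpressed (default 0.8 / see
#'   [select_core_genes()]).
#' @param correlation_p_cutoff p-value cutoff for coexpression calls.
#' @param n_core_genes number of proliferation core genes (default 20).
#' @param n_candidates top-scoring genes screened for new drivers
#'   (default 20).
#' @param seed root random seed; every stochastic stage derives from it.
#' @return a list of class `gatsage_config`.
#' @export
gatsage_config <- function(tumor_type = "synthetic",
                           gat_out = 64L, sage1_out = 128L,
                           train_fraction = 0.7,
                           learning_rate = 0.01, epochs = 200L,
                           dropout = 0.5, weight_decay = 5e-4,
                           leaky_slope = 0.2,
                           string_score_threshold = 0.9,
                           spearman_threshold = 0.8,
                           correlation_p_cutoff = 1e-3,
                           n_core_genes = 20L,
                           n_candidates = 20L,
                           seed = 1L) {
  stopifnot(gat_out > 0, sage1_out > 0,
            train_fraction > 0, train_fraction < 1,
            learning_rate > 0, epochs >= 1,
            dropout >= 0, dropout < 1)
  structure(list(
    tumor_type = tumor_type, gat_out = as.integer(gat_out),
    sage1_out = as.integer(sage1_out), sage2_out = 2L,
    train_fraction = train_fraction, learning_rate = learning_rate,
    epochs = as.integer(epochs), dropout = dropout,
    weight_decay = weight_decay, leaky_slope = leaky_slope,
    string_score_threshold = string_score_threshold,
    spearman_threshold = spearman_threshold,
    correlation_p_cutoff = correlation_p_cutoff,
    n_core_genes = as.integer(n_core_genes),
    n_candidates = as.integer(n_candidates),
    seed = as.integer(seed)), class = "gatsage_config")
}
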