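# Synthetic multiomics generator with planted driver signal. The defaults
# define the package's reference study conditions: 2000 genes measured in
# 200 tumor and 30 normal samples, 50 planted drivers with elevated
# mutation rate (0.25 vs 0.02), a +1.5 log2 tumor expression shift, a
# +0.15 methylation beta shift, CNV enrichment and preferential wiring to
# network hubs; 160 proliferation genes share one latent expression factor.

#' Specification of a synthetic multiomics study
#'
#' @param n_genes,n_tumor,n_normal cohort dimensions.
#' @param n_drivers number of planted driver genes.
#' @param driver_mutation_rate,passenger_mutation_rate per-gene-per-sample
#'   Bernoulli mutation probabilities in tumor samples.
#' @param driver_expression_shift tumor expression shift of drivers, in
#'   log2 units.
#' @param driver_methylation_shift tumor methylation shift of drivers, in
#'   beta units.
#' @param driver_cnv_rate,passenger_cnv_rate per-gene-per-tumor-sample
#'   probability of a copy-number event (|call| >= 1).
#' @param n_cprg number of cell-proliferation-related genes sharing one
#'   latent expression factor.
#' @param hub_attachment preferential-attachment parameter (edges added
#'   per new node) of the synthetic PPI graph.
#' @param wire_drivers_to_hubs also connect each driver to high-degree
#'   hubs (default `TRUE`); disable to test the feature-only regime.
#' @param negative_fraction fraction of non-drivers labeled negative
#'   (default 0.7); the rest stay unlabeled.
#' @param seed integer seed; identical seeds give byte-identical bundles.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 2000L, n_tumor = 200L,
                            n_normal = 30L, n_drivers = 50L,
                            driver_mutation_rate = 0.25,
                            passenger_mutation_rate = 0.02,
                            driver_expression_shift = 1.5,
                            driver_methylation_shift = 0.15,
                            driver_cnv_rate = 0.4,
                            passenger_cnv_rate = 0.05,
                            n_cprg = 160L, hub_attachment = 3L,
                            wire_drivers_to_hubs = TRUE,
                            negative_fraction = 0.7,
                            seed = 7L) {
  if (n_drivers >= n_genes) stop("n_drivers must be smaller than n_genes")
  stopifnot(driver_mutation_rate > 0, driver_mutation_rate < 1,
            passenger_mutation_rate > 0, passenger_mutation_rate < 1,
            n_cprg < n_genes, n_tumor >= 3, n_normal >= 1)
  structure(as.list(environment()), class = "simulation_spec")
}

#' Simulate a complete multiomics bundle with planted drivers
#'
#' Generates internally consistent expression (log-normal), methylation
#' (Beta), SNV mutation records (Bernoulli occurrence; read depths
#' Poisson(100), alt reads Binomial(depth, 0.3)), GISTIC-style CNV calls,
#' 11 standard-normal covariates, a preferential-attachment PPI graph with
#' drivers wired toward hubs, a semisupervised label set and a CPRG list.
#'
#' @param spec a [simulation_spec()].
#' @return list of class `sim_bundle` with elements `bundle` (the
#'   `omics_bundle`: expression, methylation, cnv, mutations, covariates),
#'   `graph`, `labels`, `cprg`, `truth` (planted drivers) and `spec`.
#' @export
simulate_bundle <- function(spec = simulation_spec()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_genes
  genes <- sprintf("G%04d", seq_len(n))
  tums <- sprintf("T%03d", seq_len(spec$n_tumor))
  nors <- sprintf("N%03d", seq_len(spec$n_normal))
  samples <- c(tums, nors)
  group <- setNames(rep(c("tumor", "normal"),
                        c(spec$n_tumor, spec$n_normal)), samples)
  drivers <- sort(sample(genes, spec$n_drivers))
  cprg <- sort(sample(setdiff(genes, drivers), spec$n_cprg))

  # expression: log-normal baseline; drivers shifted in tumors; CPRGs share
  # a latent per-tumor-sample proliferation factor
  base_mu <- rnorm(n, mean = 4, sd = 1)
  expr <- matrix(exp(rnorm(n * length(samples), mean = base_mu, sd = 0.5)),
                 n, length(samples), dimnames = list(genes, samples))
  is_drv <- genes %in% drivers
  expr[is_drv, tums] <- expr[is_drv, tums] *
    2^spec$driver_expression_shift
  latent <- rnorm(spec$n_tumor)
  loading <- runif(spec$n_cprg, 0.6, 1)
  expr[cprg, tums] <- expr[cprg, tums] *
    exp(outer(loading, latent))

  # methylation: Beta around a per-gene baseline; drivers shifted in tumors
  mmean <- runif(n, 0.2, 0.8)
  mu_mat <- matrix(mmean, n, length(samples))
  mu_mat[is_drv, seq_along(tums)] <-
    pmin(0.95, mu_mat[is_drv, seq_along(tums)] +
           spec$driver_methylation_shift)
  conc <- 50
  meth <- matrix(rbeta(n * length(samples), mu_mat * conc,
                       (1 - mu_mat) * conc),
                 n, length(samples), dimnames = list(genes, samples))

  # mutations: Bernoulli occurrence per gene x tumor sample
  rate <- ifelse(is_drv, spec$driver_mutation_rate,
                 spec$passenger_mutation_rate)
  occ <- matrix(rbinom(n * spec$n_tumor, 1, rate), n, spec$n_tumor)
  idx <- which(occ == 1, arr.ind = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nrow(idx), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  total <- pmax(10L, rpois(nrow(idx), 100))
  altd <- pmax(1L, rbinom(nrow(idx), total, 0.3))
  muts <- mutation_table(data.frame(
    gene = genes[idx[, 1]], sample = tums[idx[, 2]],
    ref = ref, alt = unname(alt), alt_depth = altd, total_depth = total,
    stringsAsFactors = FALSE))

  # CNV: sparse integer calls, drivers enriched in tumors
  p_event <- matrix(0.02, n, length(samples))
  p_event[, seq_along(tums)] <- ifelse(is_drv, spec$driver_cnv_rate,
                                       spec$passenger_cnv_rate)
  ev <- matrix(rbinom(n * length(samples), 1, p_event), n, length(samples))
  mag <- matrix(sample(c(1, 2), n * length(samples), TRUE,
                       prob = c(0.7, 0.3)), n, length(samples))
  sgn <- matrix(sample(c(-1, 1), n * length(samples), TRUE),
                n, length(samples))
  cnv <- ev * mag * sgn
  dimnames(cnv) <- list(genes, samples)

  cov <- matrix(rnorm(n * 11), n, 11,
                dimnames = list(genes, COVARIATE_NAMES))

  # PPI: preferential attachment; drivers additionally wired to hubs
  g <- igraph::sample_pa(n, m = spec$hub_attachment, directed = FALSE)
  igraph::V(g)$name <- sample(genes)
  if (spec$wire_drivers_to_hubs) {
    deg <- igraph::degree(g)
    hubs <- names(sort(deg, decreasing = TRUE))[seq_len(max(10, n %/% 20))]
    extra <- unlist(lapply(drivers, function(d)
      rbind(d, sample(setdiff(hubs, d), spec$hub_attachment))))
    g <- igraph::add_edges(g, extra)
  }
  g <- igraph::simplify(g)
  igraph::E(g)$score <- round(runif(igraph::ecount(g), 0.901, 0.999), 4)

  # labels: drivers positive; a fraction of non-drivers negative
  non_drv <- setdiff(genes, drivers)
  negatives <- sort(sample(non_drv,
                           round(spec$negative_fraction * length(non_drv))))
  label <- setNames(rep("unlabeled", n), genes)
  label[negatives] <- "negative"
  label[drivers] <- "positive"
  prov <- setNames(rep("simulated_exclusion", n), genes)
  prov[negatives] <- "simulated_negative"
  prov[drivers] <- "driver_list"
  labels <- structure(list(label = label, provenance = prov),
                      class = "label_set")

  bundle <- structure(list(
    expression = omics_matrix(expr, group, "expression"),
    methylation = omics_matrix(meth, group, "methylation"),
    cnv = omics_matrix(cnv, group, "cnv"),
    mutations = muts, covariates = cov), class = "omics_bundle")
  structure(list(bundle = bundle, graph = g, labels = labels, cprg = cprg,
                 truth = drivers, spec = spec), class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(paste0("<sim_bundle> %d genes, %d tumor + %d normal samples, ",
                     "%d planted drivers, %d PPI edges\n"),
              x$spec$n_genes, x$spec$n_tumor, x$spec$n_normal,
              x$spec$n_drivers, igraph::ecount(x$graph)))
  invisible(x)
}

fmt_num_df <- function(m) {
  df <- data.frame(gene = rownames(m), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- sprintf("%.17g", m[, j])
  df
}

#' Write a simulated bundle as a standard-format fixture directory
#'
#' Lays out the TSV / MAF-dialect / GMT files exactly as the readers expect
#' and writes a `manifest.tsv` listing every file with its row count.
#'
#' @param sim a `sim_bundle` from [simulate_bundle()].
#' @param dir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, the manifest data.frame.
#' @export
write_fixture <- function(sim, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("directory ", dir, " is non-empty; set overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- sim$bundle
  paths <- c(expression = "expression.tsv", methylation = "methylation.tsv",
             cnv = "cnv.tsv", groups = "sample_groups.tsv",
             covariates = "covariates.tsv", mutations = "mutations.tsv",
             ppi = "ppi_edges.tsv", gene_sets = "gene_sets.gmt",
             labels = "labels.tsv")
  f <- function(nm) file.path(dir, paths[[nm]])
  for (nm in c("expression", "methylation", "cnv")) {
    df <- fmt_num_df(b[[nm]]$values)
    write.table(df, f(nm), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(data.frame(sample = names(b$expression$group),
                         group = unname(b$expression$group)),
              f("groups"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fmt_num_df(b$covariates), f("covariates"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mafs <- data.frame(Hugo_Symbol = b$mutations$gene,
                     Tumor_Sample_Barcode = b$mutations$sample,
                     Reference_Allele = b$mutations$ref,
                     Tumor_Seq_Allele2 = b$mutations$alt,
                     t_alt_count = b$mutations$alt_depth,
                     t_depth = b$mutations$total_depth)
  write.table(mafs, f("mutations"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  el <- igraph::as_edgelist(sim$graph)
  write.table(data.frame(geneA = el[, 1], geneB = el[, 2],
                         score = sprintf("%.4f", igraph::E(sim$graph)$score)),
              f("ppi"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_sets(list(known_drivers = sim$truth, CPRG = sim$cprg),
                  f("gene_sets"))
  write_label_set(sim$labels, f("labels"))
  counts <- vapply(paths, function(p)
    length(readLines(file.path(dir, p), warn = FALSE)), integer(1))
  manifest <- data.frame(file = unname(paths), rows = unname(counts),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a fixture directory back into a simulated bundle
#'
#' Inverse of [write_fixture()]; reconstructs the omics bundle, PPI graph,
#' labels and gene sets from the standard-format files.
#'
#' @param dir fixture directory.
#' @param string_score_threshold PPI score cutoff applied on read
#'   (default 0.9).
#' @return a list shaped like [simulate_bundle()] output (without `spec`).
#' @export
read_fixture <- function(dir, string_score_threshold = 0.9) {
  f <- function(p) file.path(dir, p)
  grp <- read_group_map(f("sample_groups.tsv"))
  sets <- read_gene_sets(f("gene_sets.gmt"))
  lab_df <- read.delim(f("labels.tsv"), stringsAsFactors = FALSE)
  labels <- structure(list(
    label = setNames(lab_df$label, lab_df$gene),
    provenance = setNames(lab_df$provenance, lab_df$gene)),
    class = "label_set")
  bundle <- structure(list(
    expression = read_expression_matrix(f("expression.tsv"), grp),
    methylation = read_methylation_matrix(f("methylation.tsv"), grp),
    cnv = read_cnv_matrix(f("cnv.tsv"), grp),
    mutations = read_mutation_table(f("mutations.tsv")),
    covariates = read_covariate_table(f("covariates.tsv"))),
    class = "omics_bundle")
  list(bundle = bundle,
       graph = read_ppi_edges(f("ppi_edges.tsv"), string_score_threshold),
       labels = labels, cprg = sets$CPRG, truth = sets$known_drivers)
}
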