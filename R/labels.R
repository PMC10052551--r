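# Semisupervised label assignment: positives from a curated driver list,
# negatives from what is left after five exclusion rules, everything
# excluded (but not positive) stays unlabeled and only participates in
# message passing.

#' Assign positive / negative / unlabeled gene labels
#'
#' Positives are the supplied high-confidence driver list. From the
#' remaining genes, five categories are excluded before calling negatives:
#' (1) genes whose expression is associated with a positive gene
#' (|Spearman rho| >= `corr_threshold` over tumor samples, computed here),
#' and (2-5) the supplied list-based exclusion sets (cancer-pathway genes
#' and drivers from external catalogues), consumed as gene lists. Excluded
#' non-positive genes are `unlabeled`; everything else is `negative`.
#'
#' @param universe character vector of all genes.
#' @param positives character vector of known driver genes.
#' @param exclusion_sets named list of character vectors (rules 2-5).
#' @param expr expression [omics_matrix()] used for the correlation rule;
#'   `NULL` skips rule 1.
#' @param corr_threshold absolute Spearman cutoff (default 0.8).
#' @return list of class `label_set`: `label` (named character in
#'   \{"positive","negative","unlabeled"\}) and `provenance` (named character:
#'   which rule fired).
#' @export
assign_labels <- function(universe, positives, exclusion_sets = list(),
                          expr = NULL, corr_threshold = 0.8) {
  universe <- unique(universe)
  if (!length(positives)) stop("positive gene list is empty")
  outside <- setdiff(positives, universe)
  if (length(outside)) {
    warning("positives not in the gene universe dropped: ",
            paste(outside, collapse = ", "))
    positives <- intersect(positives, universe)
    if (!length(positives)) stop("no positives remain inside the universe")
  }
  label <- setNames(rep("negative", length(universe)), universe)
  prov <- setNames(rep("", length(universe)), universe)

  excluded <- character(0)
  if (!is.null(expr)) {
    tum <- expr$values[, expr$group == "tumor", drop = FALSE]
    pos_in <- intersect(positives, rownames(tum))
    others <- setdiff(intersect(universe, rownames(tum)), positives)
    if (length(pos_in) && length(others)) {
      rho <- suppressWarnings(
        cor(t(tum[others, , drop = FALSE]), t(tum[pos_in, , drop = FALSE]),
            method = "spearman"))
      hit <- others[apply(abs(rho) >= corr_threshold, 1, any, na.rm = TRUE)]
      excluded <- union(excluded, hit)
      prov[hit] <- "driver_coexpression"
    }
  }
  for (nm in names(exclusion_sets)) {
    hit <- setdiff(intersect(exclusion_sets[[nm]], universe),
                   c(positives, excluded))
    excluded <- union(excluded, hit)
    prov[hit] <- nm
  }
  excluded <- setdiff(excluded, positives)
  label[excluded] <- "unlabeled"
  label[positives] <- "positive"
  prov[positives] <- "driver_list"
  structure(list(label = label, provenance = prov), class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat("<label_set>", paste(sprintf("%s:%d", names(table(x$label)),
                                   table(x$label)), collapse = " "), "\n")
  invisible(x)
}

#' Random pseudolabels for unlabeled genes
#'
#' Fair-coin 0/1 labels, seeded. Only consulted when the optional
#' pseudolabel training mode is enabled; the default training excludes
#' unlabeled genes from the loss entirely.
#'
#' @param genes character vector of unlabeled genes.
#' @param seed integer seed.
#' @return named integer vector in \{0,1\}.
#' @export
pseudolabel <- function(genes, seed = 1L) {
  if (!length(genes)) return(setNames(integer(0), character(0)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  setNames(rbinom(length(genes), 1L, 0.5), genes)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a label set to TSV
#' @param labels a `label_set`.
#' @param path output TSV path.
#' @export
write_label_set <- function(labels, path) {
  df <- data.frame(gene = names(labels$label), label = labels$label,
                   provenance = labels$provenance, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
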