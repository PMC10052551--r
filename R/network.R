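# Mutation-outlier bipartite graph and PPI centralities.
#
# A bipartite edge (i, j, p) exists when gene i is mutated in patient p,
# gene j is an expression outlier in patient p, and (i, j) is a PPI edge.
# The edge set is materialized as a triple table; feature extraction
# aggregates it per mutated (left-partition) gene.

#' Build the mutation-outlier bipartite graph
#'
#' Enumerates every (mutated gene i, outlying gene j, patient p) triple such
#' that i carries a mutation record in p, j is flagged in the patient-outlier
#' matrix for p, and i-j is an edge of the PPI graph. Self pairs never occur
#' because the PPI graph is simple.
#'
#' @param muts a `mutation_table`.
#' @param om binary outlier matrix (genes x tumor samples) from
#'   [outlier_matrix()].
#' @param ppi PPI [igraph::graph].
#' @return data.frame of class `bipartite_graph` with columns
#'   `left` (mutated gene), `right` (outlying gene), `patient`.
#' @export
build_bipartite <- function(muts, om, ppi) {
  patients <- colnames(om)
  genes <- rownames(om)
  vs <- igraph::V(ppi)$name
  el <- igraph::as_edgelist(ppi)
  # both orientations: either endpoint can be the mutated side
  pairs <- rbind(el, el[, 2:1, drop = FALSE])
  colnames(pairs) <- c("left", "right")
  m <- unique(muts[muts$sample %in% patients, c("gene", "sample")])
  out <- data.frame(left = character(0), right = character(0),
                    patient = character(0), stringsAsFactors = FALSE)
  if (nrow(m)) {
    # mutation indicator aligned to outlier-matrix patients
    mut <- matrix(FALSE, length(genes), length(patients),
                  dimnames = list(genes, patients))
    hit <- m$gene %in% genes
    mut[cbind(m$gene[hit], m$sample[hit])] <- TRUE
    ok <- pairs[, "left"] %in% genes & pairs[, "right"] %in% genes
    pairs <- pairs[ok, , drop = FALSE]
    if (nrow(pairs)) {
      cond <- mut[pairs[, "left"], , drop = FALSE] &
        om[pairs[, "right"], , drop = FALSE] > 0
      idx <- which(cond, arr.ind = TRUE)
      if (nrow(idx))
        out <- data.frame(left = pairs[idx[, 1], "left"],
                          right = pairs[idx[, 1], "right"],
                          patient = patients[idx[, 2]],
                          stringsAsFactors = FALSE)
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("bipartite_graph", "data.frame"))
}

#' Per-gene bipartite features (4 columns)
#'
#' For each gene as the mutated (left) partition member: `bipartite_E`,
#' the number of bipartite edges; `bipartite_LCPRG`, those edges whose
#' outlying partner is a cell-proliferation-related gene; `bipartite_CPRG`,
#' the gene's own CPRG membership (0/1); `NSC`, the number of distinct
#' patients covered by its edges.
#'
#' @param bg a `bipartite_graph` from [build_bipartite()].
#' @param cprg character vector of CPRG symbols.
#' @param tums tumor sample barcodes (bounds NSC).
#' @param gene_ids genes to report.
#' @return numeric matrix, genes x 4.
#' @export
bipartite_features <- function(bg, cprg, tums, gene_ids) {
  f <- factor(bg$left, levels = gene_ids)
  E <- as.integer(table(f))
  L <- as.integer(table(f[bg$right %in% cprg]))
  nsc <- tapply(bg$patient, f, function(p) length(unique(p)))
  nsc <- as.integer(ifelse(is.na(nsc), 0L, nsc))
  out <- cbind(bipartite_E = E, bipartite_LCPRG = L,
               bipartite_CPRG = as.integer(gene_ids %in% cprg),
               NSC = nsc)
  rownames(out) <- gene_ids
  stopifnot(all(out[, "bipartite_LCPRG"] <= out[, "bipartite_E"]),
            all(out[, "NSC"] <= length(tums)))
  out
}

#' Degree and normalized betweenness centrality
#'
#' Degree is the incident edge count; betweenness is shortest-path
#' betweenness normalized by (n-1)(n-2)/2 so it lies in \[0,1\]. Genes
#' absent from the network get (0, 0).
#'
#' @param net [igraph::graph].
#' @param gene_ids genes to report.
#' @return numeric matrix, genes x 2 (`degree`, `betweenness`).
#' @export
centrality_features <- function(net, gene_ids) {
  vs <- igraph::V(net)$name
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, normalized = TRUE)
  out <- cbind(degree = 0, betweenness = 0)[rep(1, length(gene_ids)), ,
                                            drop = FALSE]
  rownames(out) <- gene_ids
  hit <- intersect(gene_ids, vs)
  out[hit, "degree"] <- deg[hit]
  out[hit, "betweenness"] <- btw[hit]
  out
}
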