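# Precision-recall evaluation: curve construction with tie grouping,
# right-max smoothing, and the 11-point interpolated average precision
# (mean of smoothed precision at recall 0, 0.1, ..., 1.0).

#' Precision-recall curve
#'
#' One point per distinct score threshold, descending; tied scores are
#' grouped into a single point so the curve does not depend on the order of
#' ties. Precision at recall 0 (empty prediction set) is defined as 1.
#'
#' @param scores named numeric vector of predicted driver probabilities.
#' @param y named 0/1 vector (1 = positive) over the same genes.
#' @return data.frame of class `pr_curve` with columns `threshold`, `TP`,
#'   `FP`, `FN`, `precision`, `recall`.
#' @export
pr_curve <- function(scores, y) {
  y <- y[names(scores)]
  if (!any(y == 1)) stop("PR curve needs at least one positive")
  ord <- order(-scores)
  s <- scores[ord]; yy <- y[ord]
  grp <- !duplicated(s)           # first index of each distinct threshold
  tp <- cumsum(yy); fp <- cumsum(1 - yy)
  last <- c(which(grp)[-1] - 1L, length(s))  # last index per tie group
  P <- sum(y == 1)
  TP <- tp[last]; FP <- fp[last]; FN <- P - TP
  out <- data.frame(threshold = s[grp], TP = TP, FP = FP, FN = FN,
                    precision = TP / (TP + FP), recall = TP / P)
  rownames(out) <- NULL
  structure(out, class = c("pr_curve", "data.frame"))
}

#' Right-max smoothing of a PR curve
#'
#' Replaces each precision value by the maximum precision at any recall
#' greater than or equal to it, making precision non-increasing in recall.
#'
#' @param curve a `pr_curve`.
#' @return the smoothed `pr_curve` (same columns).
#' @export
smooth_pr <- function(curve) {
  curve$precision <- rev(cummax(rev(curve$precision)))
  curve
}

#' 11-point interpolated average precision
#'
#' Mean of the smoothed precision evaluated at recall 0, 0.1, ..., 1.0.
#' At recall 0 the global maximum precision is used; grid points beyond
#' the maximum achieved recall contribute 0.
#'
#' @param curve a (smoothed) `pr_curve`; unsmoothed curves are smoothed
#'   first.
#' @return scalar AP in \[0,1\].
#' @export
interpolated_ap <- function(curve) {
  curve <- smooth_pr(curve)
  grid <- seq(0, 1, by = 0.1)
  p_at <- vapply(grid, function(r) {
    ok <- curve$recall >= r - 1e-12
    if (!any(ok)) 0 else max(curve$precision[ok])
  }, numeric(1))
  mean(p_at)
}

#' Write a PR curve and its AP to TSV
#' @param curve a `pr_curve`.
#' @param path output TSV path; the AP goes to `paste0(path, ".summary.tsv")`.
#' @export
write_pr_curve <- function(curve, path) {
  write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(metric = "interpolated_ap_11pt",
                         value = interpolated_ap(curve)),
              paste0(path, ".summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
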