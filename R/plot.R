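#' Heatmap of differentially methylated sites by subtype
#'
#' Plots tumor M-values restricted to the sites any modification path
#' marks as changed (a row of `W` equal to 1), with samples ordered by
#' subtype so the per-subtype methylation blocks are visible. A left
#' annotation bar shows the subtype of each sample.
#'
#' @param data A [paired_methylation()] object.
#' @param W Binary s x m modification matrix (true or fitted).
#' @param labels Integer subtype per sample (true or fitted).
#' @param max_sites Cap on plotted sites (evenly subsampled beyond it).
#' @param ... Passed on to [pheatmap::pheatmap()].
#' @return The `pheatmap` object, invisibly.
#' @export
plot_signature_heatmap <- function(data, W, labels, max_sites = 2000L, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotting requires the 'pheatmap' package")
  stopifnot(inherits(data, "baysub_data"))
  W <- binmat(W, "W")
  keep <- which(colSums(W) > 0L)
  if (length(keep) == 0L) stop("no differentially methylated sites in 'W'")
  if (length(keep) > max_sites)
    keep <- keep[seq(1L, length(keep), length.out = max_sites)]
  ord <- order(labels)
  mat <- data$Y[ord, keep, drop = FALSE]
  ann <- data.frame(subtype = factor(labels[ord]),
                    row.names = rownames(mat))
  ph <- pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                           annotation_row = ann, show_colnames = FALSE,
                           show_rownames = FALSE, ...)
  invisible(ph)
}
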