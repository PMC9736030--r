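# expression: FPKM-threshold filters, row scaling for heatmaps, and a simple
# fold-change differential-expression rule. The expressed / highly-expressed
# thresholds (FPKM >= 1 and >= 20) are the family-survey conventions; the
# differential rule (fold change with a pseudo-count and an FPKM floor) is a
# package convention, fully configurable.

check_matrix <- function(m) {
  abort_if(!is.matrix(m) || !is.numeric(m), "expected a numeric matrix")
  abort_if(nrow(m) == 0L || ncol(m) == 0L, "empty expression matrix")
  abort_if(any(m < 0), "FPKM values must be non-negative")
  abort_if(is.null(rownames(m)) || anyDuplicated(rownames(m)) > 0L,
           "rows must carry unique gene ids")
  abort_if(is.null(colnames(m)) || anyDuplicated(colnames(m)) > 0L,
           "columns must carry unique sample ids")
  invisible(m)
}

#' Expressed gene sets
#'
#' @param m FPKM matrix (genes x samples, named dimensions).
#' @param threshold expression cutoff (default FPKM >= 1).
#' @return list with `any_tissue` (genes with max >= threshold) and
#'   `all_tissues` (genes with min >= threshold).
#' @export
expressed_genes <- function(m, threshold = 1) {
  check_matrix(m)
  list(any_tissue = rownames(m)[apply(m, 1L, max) >= threshold],
       all_tissues = rownames(m)[apply(m, 1L, min) >= threshold])
}

#' Highly expressed and tissue-preferential gene sets
#'
#' A gene is highly expressed in a tissue iff its FPKM there is >= threshold,
#' and tissue-preferential there iff that tissue additionally attains the
#' row maximum (ties: preferential in every argmax tissue).
#'
#' @param m FPKM matrix.
#' @param threshold high-expression cutoff (default FPKM >= 20).
#' @return list with `high` and `preferential`, each a named list of gene-id
#'   vectors per tissue (column).
#' @export
highly_expressed <- function(m, threshold = 20) {
  check_matrix(m)
  rowmax <- apply(m, 1L, max)
  high <- lapply(colnames(m), function(t) rownames(m)[m[, t] >= threshold])
  pref <- lapply(colnames(m), function(t) {
    rownames(m)[m[, t] >= threshold & m[, t] == rowmax]
  })
  list(high = stats::setNames(high, colnames(m)),
       preferential = stats::setNames(pref, colnames(m)))
}

#' Row-wise z-scaling (heatmap "scale row")
#'
#' Each row is transformed to (x - mean) / sd (sample sd); constant rows map
#' to all zeros. Ranks within each row are unchanged.
#'
#' @param m FPKM matrix with >= 2 samples.
#' @return matrix of the same shape.
#' @export
row_scale <- function(m) {
  check_matrix(m)
  abort_if(ncol(m) < 2L, "row_scale() needs >= 2 samples")
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  out <- (m - mu) / ifelse(sd == 0, 1, sd)
  out[sd == 0, ] <- 0
  out
}

#' Fold-change differential-expression call
#'
#' up iff treated/(control + eps) >= min_fc and treated >= min_fpkm;
#' down iff control/(treated + eps) >= min_fc and control >= min_fpkm;
#' unchanged otherwise.
#'
#' @param control,treated paired FPKM vectors (same genes, same order).
#' @param min_fc minimum fold change (default 2).
#' @param min_fpkm expression floor on the higher condition (default 1).
#' @param eps pseudo-FPKM guarding division by zero (default 0.01).
#' @return character vector of "up"/"down"/"unchanged" (named if the inputs
#'   are).
#' @export
differential_call <- function(control, treated, min_fc = 2, min_fpkm = 1,
                              eps = 0.01) {
  abort_if(length(control) != length(treated),
           "control and treated must have equal length")
  up <- treated / (control + eps) >= min_fc & treated >= min_fpkm
  down <- control / (treated + eps) >= min_fc & control >= min_fpkm
  out <- ifelse(up, "up", ifelse(down, "down", "unchanged"))
  names(out) <- names(control) %||% names(treated)
  out
}

#' Average replicate columns
#'
#' @param m FPKM matrix.
#' @param replicate_map named character vector: column -> replicate-group
#'   label.
#' @return matrix with one column per replicate group (column means).
#' @export
average_replicates <- function(m, replicate_map) {
  check_matrix(m)
  abort_if(!all(colnames(m) %in% names(replicate_map)),
           "replicate_map must cover every column")
  groups <- unique(replicate_map[colnames(m)])
  out <- vapply(groups, function(g) {
    cols <- colnames(m)[replicate_map[colnames(m)] == g]
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  dimnames(out) <- list(rownames(m), groups)
  out
}

#' Heatmap of a row-scaled expression matrix
#'
#' Thin wrapper over pheatmap on [row_scale()] output; requires the pheatmap
#' package (Suggests).
#'
#' @param m FPKM matrix.
#' @param ... passed to `pheatmap::pheatmap`.
#' @return the pheatmap object, invisibly.
#' @export
plot_expression_heatmap <- function(m, ...) {
  abort_if(!requireNamespace("pheatmap", quietly = TRUE),
           "plot_expression_heatmap() needs the 'pheatmap' package")
  p <- pheatmap::pheatmap(row_scale(m), cluster_cols = FALSE, ...)
  invisible(p)
}
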