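#' Remove low-count genes and cells
#'
#' Single-pass cleaning filter: genes whose row total is below
#' `min_gene_total` are dropped first, then cells whose column total over the
#' remaining genes is below `min_cell_total`. Spike-in rows are exempt from
#' the gene filter by default so that small spike-in panels survive. The
#' defaults match the thresholds recommended for hierarchical Bayesian
#' normalization (gene totals < 10, cell totals < 10000).
#'
#' A second application may remove further rows (dropping cells can push a
#' gene's total below threshold); the filter is deliberately one-pass, with
#' `iterate = TRUE` available to run to a fixed point.
#'
#' @param cm A [count_matrix()].
#' @param min_gene_total Minimum row total for a gene to be kept.
#' @param min_cell_total Minimum column total (over kept genes) for a cell.
#' @param exempt_spikeins Keep spike-in rows regardless of their totals.
#' @param iterate Repeat the two filters until no further removals.
#' @return A cleaned `count_matrix` with attributes `kept_genes` and
#'   `kept_cells` (integer maps into the input rows/columns).
#' @export
clean_counts <- function(cm, min_gene_total = 10, min_cell_total = 10000,
                         exempt_spikeins = TRUE, iterate = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  keep_g <- seq_len(nrow(cm$counts))
  keep_c <- seq_len(ncol(cm$counts))
  cur <- cm
  repeat {
    gene_tot <- rowSums(cur$counts)
    g <- gene_tot >= min_gene_total
    if (exempt_spikeins) g <- g | cur$is_spikein
    if (!any(g)) stop("cleaning removed every gene", call. = FALSE)
    cell_tot <- colSums(cur$counts[g, , drop = FALSE])
    cc <- cell_tot >= min_cell_total
    if (!any(cc)) stop("cleaning removed every cell", call. = FALSE)
    keep_g <- keep_g[g]
    keep_c <- keep_c[cc]
    nxt <- subset_counts(cur, genes = which(g), cells = which(cc))
    done <- !iterate || (all(g) && all(cc))
    cur <- nxt
    if (done) break
  }
  attr(cur, "kept_genes") <- keep_g
  attr(cur, "kept_cells") <- keep_c
  cur
}

#' Fragments per kilobase of transcript per million mapped reads
#'
#' FPKM_ij = counts_ij * 1e9 / (gene_length_i * column_total_j). Column
#' totals are those of the supplied (typically cleaned) matrix. Invariant to
#' uniform scaling of a cell's counts; scaling a single gene's count by k
#' with totals held fixed scales its FPKM by k.
#'
#' @param cm A [count_matrix()] with `gene_lengths` present.
#' @return Real genes x cells matrix of FPKM values.
#' @export
compute_fpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$gene_lengths)) {
    stop("gene lengths are required for FPKM", call. = FALSE)
  }
  totals <- colSums(cm$counts)
  if (any(totals == 0)) {
    stop("zero column total for cell '", cm$cell_ids[which(totals == 0)[1]],
         "'", call. = FALSE)
  }
  sweep(cm$counts / cm$gene_lengths, 2, totals, "/") * 1e9
}
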