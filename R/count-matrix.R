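#' Gene-by-cell count matrix container
#'
#' The central data structure of the package: a dense genes x cells matrix of
#' non-negative integer read/UMI counts plus row/column metadata. Spike-in
#' rows (synthetic control transcripts added in known, equal amounts to every
#' cell's lysate) are flagged so the spike-in based normalization methods can
#' find them; per-cell condition labels and per-gene transcript lengths are
#' optional.
#'
#' @param counts Numeric matrix, genes in rows and cells in columns. All
#'   entries must be finite, non-negative and integral.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to the matrix rownames.
#' @param cell_ids Character vector of unique cell identifiers, one per
#'   column. Defaults to the matrix colnames.
#' @param is_spikein Logical vector flagging spike-in rows. Defaults to all
#'   `FALSE`.
#' @param condition Optional per-cell condition (cell type / group) labels.
#' @param gene_lengths Optional positive per-gene transcript lengths in bp,
#'   required for FPKM computation.
#'
#' @return An object of class `count_matrix`.
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 7L), nrow = 2,
#'             dimnames = list(c("geneA", "ERCC-00001"), c("c1", "c2")))
#' cm <- count_matrix(m, is_spikein = c(FALSE, TRUE))
#' dim(cm)
count_matrix <- function(counts,
                         gene_ids = rownames(counts),
                         cell_ids = colnames(counts),
                         is_spikein = rep(FALSE, nrow(counts)),
                         condition = NULL,
                         gene_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  storage.mode(counts) <- "double"
  x <- structure(
    list(
      counts = counts,
      gene_ids = gene_ids,
      cell_ids = cell_ids,
      is_spikein = as.logical(is_spikein),
      condition = if (!is.null(condition)) as.character(condition) else NULL,
      gene_lengths = if (!is.null(gene_lengths)) as.numeric(gene_lengths) else NULL
    ),
    class = "count_matrix"
  )
  validate_count_matrix(x)
}

validate_count_matrix <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  if (nrow(counts) != length(x$gene_ids)) {
    stop("count matrix has ", nrow(counts), " rows but ", length(x$gene_ids),
         " gene ids", call. = FALSE)
  }
  if (ncol(counts) != length(x$cell_ids)) {
    stop("count matrix has ", ncol(counts), " columns but ", length(x$cell_ids),
         " cell ids", call. = FALSE)
  }
  if (anyDuplicated(x$gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(x$gene_ids[duplicated(x$gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$cell_ids)) {
    stop("duplicate cell ids: ",
         paste(unique(x$cell_ids[duplicated(x$cell_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(x$is_spikein) != nrow(counts)) {
    stop("`is_spikein` must have one entry per gene", call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("counts must be non-negative integers; offending entry at gene '",
         x$gene_ids[bad[1, 1]], "', cell '", x$cell_ids[bad[1, 2]], "' (value ",
         counts[bad[1, , drop = FALSE]], ")", call. = FALSE)
  }
  if (!is.null(x$condition) && length(x$condition) != ncol(counts)) {
    stop("`condition` must have one label per cell", call. = FALSE)
  }
  if (!is.null(x$gene_lengths)) {
    if (length(x$gene_lengths) != nrow(counts)) {
      stop("`gene_lengths` must have one entry per gene", call. = FALSE)
    }
    if (any(!is.finite(x$gene_lengths) | x$gene_lengths <= 0)) {
      stop("`gene_lengths` must all be positive", call. = FALSE)
    }
  }
  dimnames(x$counts) <- list(x$gene_ids, x$cell_ids)
  x
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells (", sum(x$is_spikein), " spike-in rows)\n", sep = "")
  if (!is.null(x$condition)) {
    tab <- table(x$condition)
    cat("  conditions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$gene_lengths)) cat("  gene lengths: present\n")
  invisible(x)
}

#' Subset a count matrix by gene and/or cell index
#'
#' Keeps all metadata aligned with the retained rows and columns.
#'
#' @param x A `count_matrix`.
#' @param genes Integer or logical index over genes (rows).
#' @param cells Integer or logical index over cells (columns).
#' @return A `count_matrix` restricted to the selected genes and cells.
#' @export
subset_counts <- function(x, genes = seq_len(nrow(x$counts)),
                          cells = seq_len(ncol(x$counts))) {
  stopifnot(inherits(x, "count_matrix"))
  count_matrix(
    x$counts[genes, cells, drop = FALSE],
    gene_ids = x$gene_ids[genes],
    cell_ids = x$cell_ids[cells],
    is_spikein = x$is_spikein[genes],
    condition = if (!is.null(x$condition)) x$condition[cells] else NULL,
    gene_lengths = if (!is.null(x$gene_lengths)) x$gene_lengths[genes] else NULL
  )
}

#' Normalized expression matrix container
#'
#' Output container shared by every normalization method: a real-valued
#' genes x cells matrix, the method that produced it, whether values are on a
#' log or linear scale, optional per-cell size factors, and a map from output
#' rows back to rows of the input count matrix (methods may drop genes).
#'
#' @param values Real genes x cells matrix; all entries must be finite.
#' @param method Character tag naming the method.
#' @param scale Either `"log"` or `"linear"`.
#' @param gene_ids,cell_ids Identifiers carried over from the input.
#' @param size_factors Optional positive per-cell factors used by the method.
#' @param kept_gene_index Integer map: output row -> input row.
#' @param is_spikein Optional logical flag per output row.
#'
#' @return An object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, method, scale,
                              gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              size_factors = NULL,
                              kept_gene_index = seq_len(nrow(values)),
                              is_spikein = NULL) {
  values <- as.matrix(values)
  scale <- match.arg(scale, c("log", "linear"))
  if (any(!is.finite(values))) {
    stop("normalized values must all be finite", call. = FALSE)
  }
  if (!is.null(size_factors)) {
    if (length(size_factors) != ncol(values) || any(size_factors <= 0)) {
      stop("size factors must be positive, one per cell", call. = FALSE)
    }
  }
  kept_gene_index <- as.integer(kept_gene_index)
  if (anyDuplicated(kept_gene_index)) {
    stop("kept_gene_index must be injective", call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(values)))
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(
      values = values,
      method = method,
      scale = scale,
      gene_ids = as.character(gene_ids),
      cell_ids = as.character(cell_ids),
      size_factors = size_factors,
      kept_gene_index = kept_gene_index,
      is_spikein = is_spikein
    ),
    class = "normalized_matrix"
  )
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("<normalized_matrix> method=", x$method, ", scale=", x$scale, ", ",
      nrow(x$values), " genes x ", ncol(x$values), " cells\n", sep = "")
  invisible(x)
}

#' Column totals of a count matrix
#'
#' @param x A `count_matrix`.
#' @param biological_only Drop spike-in rows before summing.
#' @return Named numeric vector of per-cell totals.
#' @export
cell_totals <- function(x, biological_only = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  m <- if (biological_only) x$counts[!x$is_spikein, , drop = FALSE] else x$counts
  colSums(m)
}
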