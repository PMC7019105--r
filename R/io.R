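#' Read a dense tab-delimited count matrix
#'
#' Expects a header row of cell ids, a first column of gene ids, and an
#' integer body. Rows whose gene id starts with `spikein_prefix` are flagged
#' as spike-ins.
#'
#' @param path Path to the TSV file.
#' @param spikein_prefix Gene-id prefix marking spike-in rows.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(path, spikein_prefix = "ERCC-") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("no data rows in ", path, call. = FALSE)
  if (ncol(raw) < 2) stop("no cell columns in ", path, call. = FALSE)
  gene_ids <- raw[[1]]
  cell_ids <- colnames(raw)[-1]
  body <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(as.numeric(body))
  m <- matrix(vals, nrow = nrow(body), ncol = ncol(body))
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop("non-integer or negative count '", body[i, j], "' at gene '",
         gene_ids[i], "', cell '", cell_ids[j], "'", call. = FALSE)
  }
  count_matrix(m, gene_ids = gene_ids, cell_ids = cell_ids,
               is_spikein = startsWith(gene_ids, spikein_prefix))
}

#' Write a count matrix as dense TSV
#'
#' Inverse of [read_counts_tsv()]; the first column holds gene ids, the
#' header row cell ids.
#'
#' @param cm A `count_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 10X-style MatrixMarket count directory
#'
#' Expects the standard triplet layout: `matrix.mtx`, a gene/feature TSV
#' (`genes.tsv` or `features.tsv`, id in the first column) and
#' `barcodes.tsv`. MatrixMarket indices are 1-based; the result is a dense
#' gene-by-cell matrix.
#'
#' @param dir Directory containing the three files.
#' @param spikein_prefix Gene-id prefix marking spike-in rows.
#' @return A [count_matrix()].
#' @export
read_counts_mtx <- function(dir, spikein_prefix = "ERCC-") {
  mtx_path <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx_path)) stop("no matrix.mtx in ", dir, call. = FALSE)
  gene_path <- file.path(dir, "genes.tsv")
  if (!file.exists(gene_path)) gene_path <- file.path(dir, "features.tsv")
  if (!file.exists(gene_path)) {
    stop("no genes.tsv or features.tsv in ", dir, call. = FALSE)
  }
  bc_path <- file.path(dir, "barcodes.tsv")
  if (!file.exists(bc_path)) stop("no barcodes.tsv in ", dir, call. = FALSE)

  m <- Matrix::readMM(mtx_path)
  genes <- utils::read.delim(gene_path, header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bc_path, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(genes) != nrow(m)) {
    stop("gene file has ", nrow(genes), " rows but matrix declares ",
         nrow(m), " rows", call. = FALSE)
  }
  if (length(barcodes) != ncol(m)) {
    stop("barcodes file has ", length(barcodes),
         " lines but matrix declares ", ncol(m), " columns", call. = FALSE)
  }
  gene_ids <- genes[[1]]
  count_matrix(as.matrix(m), gene_ids = gene_ids, cell_ids = barcodes,
               is_spikein = startsWith(gene_ids, spikein_prefix))
}

#' Write a count matrix in the 10X MatrixMarket triplet layout
#'
#' @param cm A `count_matrix`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(cm$gene_ids, cm$gene_ids),
                     file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(cm$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a spike-in concentration reference table
#'
#' Tab-delimited table mapping spike-in ids to known concentrations (e.g. the
#' ERCC control mix, attomoles/uL). Column names are configurable because
#' vendor tables vary.
#'
#' @param path Path to the TSV file.
#' @param id_col,conc_col Names of the id and concentration columns.
#' @param unit Free-text unit recorded as metadata.
#' @return A tibble of class `spikein_reference` with columns `spikein_id`
#'   and `concentration`, and a `unit` attribute.
#' @export
read_spikein_reference <- function(path, id_col = "spikein_id",
                                   conc_col = "concentration",
                                   unit = "attomoles/uL") {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!all(c(id_col, conc_col) %in% colnames(df))) {
    stop("expected columns '", id_col, "' and '", conc_col, "' in ", path,
         call. = FALSE)
  }
  spikein_reference(df[[id_col]], df[[conc_col]], unit = unit)
}

#' Construct a spike-in reference from vectors
#'
#' @param spikein_id Character ids, unique.
#' @param concentration Positive known concentrations.
#' @param unit Concentration unit recorded as metadata.
#' @return A tibble of class `spikein_reference`.
#' @export
spikein_reference <- function(spikein_id, concentration,
                              unit = "attomoles/uL") {
  spikein_id <- as.character(spikein_id)
  concentration <- as.numeric(concentration)
  if (anyDuplicated(spikein_id)) {
    stop("duplicate spike-in ids: ",
         paste(unique(spikein_id[duplicated(spikein_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.finite(concentration) | concentration <= 0
  if (any(bad)) {
    stop("non-positive or missing concentration for spike-in '",
         spikein_id[which(bad)[1]], "'", call. = FALSE)
  }
  out <- tibble::tibble(spikein_id = spikein_id,
                        concentration = concentration)
  attr(out, "unit") <- unit
  class(out) <- c("spikein_reference", class(out))
  out
}

#' Read per-cell condition labels
#'
#' Two-column TSV (`cell_id`, `condition`) attached to a count matrix by id.
#'
#' @param cm A `count_matrix`.
#' @param path Path to the labels TSV.
#' @return The `count_matrix` with its `condition` field populated.
#' @export
read_labels_tsv <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "condition") %in% colnames(df))) {
    stop("labels file must have columns cell_id and condition", call. = FALSE)
  }
  idx <- match(cm$cell_ids, df$cell_id)
  if (anyNA(idx)) {
    stop("no label for cell '", cm$cell_ids[which(is.na(idx))[1]], "'",
         call. = FALSE)
  }
  cm$condition <- as.character(df$condition[idx])
  validate_count_matrix(cm)
}

#' Write a normalized matrix as TSV
#'
#' The first line is a comment header recording the method and scale
#' (`# method=<m> scale=<s>`); the body mirrors the dense count TSV layout.
#' Values survive a read-back round trip to within 1e-12.
#'
#' @param nm A `normalized_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normalized <- function(nm, path) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (any(!is.finite(nm$values))) {
    stop("refusing to write non-finite normalized values", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method=", nm$method, " scale=", nm$scale), con)
  df <- data.frame(gene_id = nm$gene_ids,
                   format(nm$values, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("gene_id", nm$cell_ids)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a normalized matrix written by [write_normalized()]
#'
#' @param path Path to the TSV file.
#' @return A `normalized_matrix`.
#' @export
read_normalized <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "# method=")) {
    stop("missing method/scale header in ", path, call. = FALSE)
  }
  fields <- strsplit(sub("^# ", "", header), " ")[[1]]
  kv <- strsplit(fields, "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- utils::read.delim(path, header = TRUE, skip = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  normalized_matrix(vals, method = meta[["method"]], scale = meta[["scale"]],
                    gene_ids = df[[1]], cell_ids = colnames(df)[-1])
}
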