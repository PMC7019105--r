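#' Pooled size-factor deconvolution normalization
#'
#' Estimates per-cell size factors by deconvolving robust pool-level
#' factors. Cells are ordered by library size t_j and arranged on a ring so
#' that sliding-window pools have comparable library sizes. For each pool
#' S_k the per-gene pooled adjusted expression V_ik = sum_{j in S_k}
#' X_ij / t_j is compared with the all-cell average U_i = mean_j X_ij / t_j,
#' and the pool factor is the median over expressed genes of the ratio
#' R_ik = V_ik / U_i — a robust summary that cancels the (never estimated)
#' latent non-DE expectation of each gene. Every pool contributes one linear
#' equation sum_{j in S_k} z_j = R_k in the per-cell unknowns
#' z_j (proportional to theta_j / t_j); low-weight per-cell library-size
#' rows z_j = 1 make the stacked system full rank, and weighted least
#' squares solves for all cells at once. Size factors theta_j = z_j * t_j
#' are rescaled to mean 1 and divide the counts.
#'
#' @param cm A [count_matrix()] or plain non-negative matrix.
#' @param pool_sizes Sliding-window pool sizes; default the ladder
#'   21, 26, ..., up to min(101, n_cells).
#' @param min_cells Below this cell count a warning is emitted (the
#'   deconvolution is designed for at least 20 cells).
#' @param aug_weight Weight of the library-size augmentation rows relative
#'   to the pool rows.
#' @return A linear-scale [normalized_matrix()] with `size_factors` set and
#'   a `scran_pools` fit object in attribute `pools`.
#' @export
normalize_scran <- function(cm, pool_sizes = NULL, min_cells = 20,
                            aug_weight = 0.001) {
  X <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  gene_ids <- rownames(X) %||% paste0("gene_", seq_len(nrow(X)))
  cell_ids <- colnames(X) %||% paste0("cell_", seq_len(ncol(X)))
  n <- ncol(X)
  if (n < min_cells) {
    warning("only ", n, " cells; pooled deconvolution is designed for at ",
            "least ", min_cells, " cells")
  }
  t_j <- colSums(X)
  if (any(t_j == 0)) {
    stop("zero column total for cell '", cell_ids[which(t_j == 0)[1]], "'",
         call. = FALSE)
  }
  if (is.null(pool_sizes)) {
    hi <- min(101, n)
    pool_sizes <- if (hi >= 21) seq(21, hi, by = 5) else
      unique(pmax(2, c(n %/% 2, n - 1)))
  }
  pool_sizes <- unique(pmin(as.integer(pool_sizes), n))
  pool_sizes <- pool_sizes[pool_sizes >= 2]
  if (length(pool_sizes) == 0) stop("no usable pool sizes", call. = FALSE)

  adj <- sweep(X, 2, t_j, "/")
  U <- rowMeans(adj)
  expressed <- U > 0
  if (!any(expressed)) stop("no expressed genes", call. = FALSE)
  adj_e <- adj[expressed, , drop = FALSE]
  U_e <- U[expressed]

  ring <- order(t_j)
  # sliding-window pool sums via cumulative sums over the doubled ring
  max_s <- max(pool_sizes)
  doubled <- adj_e[, c(ring, ring[seq_len(max_s)]), drop = FALSE]
  cs <- cbind(0, t(apply(doubled, 1, cumsum)))
  memberships <- vector("list", length(pool_sizes) * n)
  rhs <- numeric(length(pool_sizes) * n)
  k <- 0
  for (s in pool_sizes) {
    V <- cs[, seq_len(n) + s, drop = FALSE] - cs[, seq_len(n), drop = FALSE]
    R <- V / U_e
    for (p in seq_len(n)) {
      k <- k + 1
      memberships[[k]] <- ring[((p - 1 + seq_len(s) - 1) %% n) + 1]
      rhs[k] <- stats::median(R[, p])
    }
  }
  n_pool <- length(memberships)
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n_pool), lengths(memberships)),
    j = unlist(memberships),
    x = 1, dims = c(n_pool, n)
  )
  A <- rbind(A, aug_weight * Matrix::Diagonal(n))
  b <- c(rhs, rep(aug_weight, n))
  xtx <- as.matrix(Matrix::crossprod(A))
  z <- tryCatch(drop(solve(xtx, as.numeric(Matrix::crossprod(A, b)))),
                error = function(e) {
                  stop("singular deconvolution system even after ",
                       "augmentation", call. = FALSE)
                })
  if (any(!is.finite(z) | z <= 0)) {
    stop("non-positive deconvolved factor for cell '",
         cell_ids[which(!is.finite(z) | z <= 0)[1]],
         "'; consider stricter gene filtering", call. = FALSE)
  }
  theta <- z * t_j
  sf <- theta / mean(theta)
  Y <- sweep(X, 2, sf, "/")
  fit <- structure(
    list(pool_memberships = memberships, pool_ratio_factor = rhs,
         solution = z, t = t_j, pool_sizes = pool_sizes,
         aug_weight = aug_weight),
    class = "scran_pools"
  )
  nm <- normalized_matrix(Y, method = "scran", scale = "linear",
                          gene_ids = gene_ids, cell_ids = cell_ids,
                          size_factors = sf,
                          is_spikein = if (inherits(cm, "count_matrix"))
                            cm$is_spikein else NULL)
  attr(nm, "pools") <- fit
  nm
}

#' @export
print.scran_pools <- function(x, ...) {
  cat("<scran_pools> ", length(x$pool_memberships), " pools (sizes ",
      paste(x$pool_sizes, collapse = ", "), ") over ", length(x$t),
      " cells\n", sep = "")
  invisible(x)
}
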