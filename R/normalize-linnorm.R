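#' Stable-gene linear-model normalization
#'
#' Normalizes via per-cell linear models anchored on stable genes. Counts are
#' first put on a relative scale R_ij = X_ij / colsum_j, then re-scaled by
#' lambda (the median of total counts across cells) and logged:
#' G_ij = ln(lambda * R_ij). Stable genes — expressed in (nearly) every cell
#' with the lowest variance of G across cells — define per-gene anchors
#' z_i = mean_j G_ij, and each cell's ordinary least-squares fit of z on G
#' over the stable genes gives a slope/intercept (a_j, b_j). A normalization
#' strength c in \[0, 1\] interpolates between no correction (c = 0) and the
#' full fitted correction (c = 1):
#' a_j' = c(a_j - 1) + 1, b_j' = c * b_j, B_ij = exp(a_j' G_ij + b_j') on
#' nonzero entries (zeros stay zero), and Y_ij = ln(B_ij + 1).
#'
#' At c = 0 the output equals simple library-size normalization with scale
#' factor lambda.
#'
#' @param cm A [count_matrix()] with positive column totals.
#' @param c Normalization strength in \[0, 1\]; default 0.5.
#' @param stable_fraction Fraction of eligible genes (lowest G-variance)
#'   kept as stable genes.
#' @param min_nonzero_fraction Minimum fraction of cells in which a gene
#'   must be nonzero to be eligible as stable.
#' @return A list with `normalized` (a log-scale [normalized_matrix()]) and
#'   `fit` (a `linnorm_fit` recording lambda, the stable gene set, per-cell
#'   slopes/intercepts, and the R/G matrices).
#' @export
normalize_linnorm <- function(cm, c = 0.5, stable_fraction = 0.3,
                              min_nonzero_fraction = 1.0) {
  stopifnot(inherits(cm, "count_matrix"))
  if (c < 0 || c > 1) {
    stop("normalization strength c must be in [0, 1]", call. = FALSE)
  }
  totals <- colSums(cm$counts)
  if (any(totals == 0)) {
    stop("zero column total for cell '", cm$cell_ids[which(totals == 0)[1]],
         "'", call. = FALSE)
  }
  X <- cm$counts
  n <- ncol(X)
  R <- sweep(X, 2, totals, "/")
  lambda_ <- stats::median(totals)
  nz <- X > 0
  G <- matrix(NA_real_, nrow(X), n, dimnames = dimnames(X))
  G[nz] <- log(lambda_ * R[nz])

  eligible <- rowMeans(nz) >= min_nonzero_fraction
  if (!any(eligible)) {
    stop("no stable-gene candidates; lower `min_nonzero_fraction`",
         call. = FALSE)
  }
  gvar <- apply(G[eligible, , drop = FALSE], 1, stats::var, na.rm = TRUE)
  k <- max(2L, ceiling(stable_fraction * sum(eligible)))
  stable <- which(eligible)[order(gvar)[seq_len(min(k, sum(eligible)))]]
  Gs <- G[stable, , drop = FALSE]
  # stable genes are nonzero in >= min_nonzero_fraction of cells; any
  # remaining NA would break the per-cell OLS, so insist on complete rows
  if (min_nonzero_fraction >= 1 && anyNA(Gs)) {
    stop("stable genes must be nonzero in every cell", call. = FALSE)
  }
  zbar <- rowMeans(Gs, na.rm = TRUE)

  a <- numeric(n)
  b <- numeric(n)
  for (j in seq_len(n)) {
    ok <- !is.na(Gs[, j])
    if (sum(ok) < 2) {
      stop("cell '", cm$cell_ids[j],
           "' expresses fewer than two stable genes", call. = FALSE)
    }
    g <- Gs[ok, j]
    z <- zbar[ok]
    a[j] <- stats::cov(g, z) / stats::var(g)
    b[j] <- mean(z) - a[j] * mean(g)
  }
  a_upd <- c * (a - 1) + 1
  b_upd <- b * c

  B <- matrix(0, nrow(X), n, dimnames = dimnames(X))
  B[nz] <- exp(sweep(G, 2, a_upd, "*")[nz] +
                 matrix(b_upd, nrow(X), n, byrow = TRUE)[nz])
  Y <- log1p(B)
  fit <- structure(
    list(lambda = lambda_, stable_genes = stable, a = a, b = b, c = c,
         a_updated = a_upd, b_updated = b_upd, zbar = zbar, R = R, G = G),
    class = "linnorm_fit"
  )
  list(
    normalized = normalized_matrix(Y, method = "linnorm", scale = "log",
                                   gene_ids = cm$gene_ids,
                                   cell_ids = cm$cell_ids,
                                   is_spikein = cm$is_spikein),
    fit = fit
  )
}

#' @export
print.linnorm_fit <- function(x, ...) {
  cat("<linnorm_fit> lambda=", format(x$lambda), ", ",
      length(x$stable_genes), " stable genes, c=", x$c, "\n", sep = "")
  invisible(x)
}
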