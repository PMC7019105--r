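#' Quantile-regression count-depth normalization
#'
#' Removes the count-depth relationship — the slope of log expression on log
#' sequencing depth — group by group rather than with a single global
#' factor. Per gene, the relationship is the slope of a degree-1 median
#' quantile regression of log nonzero counts X_ij on log depth D_j. Genes
#' are partitioned into K equal-size groups by slope quantiles; within a
#' group, a grid of quantile levels tau and polynomial degrees d is searched
#' for the fit of pooled expression on depth whose own count-depth slope
#' (the slope of a median degree-1 regression through the fitted values)
#' best matches the modal gene slope of the group. The selected fit defines
#' per-cell scale factors SF_j = exp(fitted value at D_j) / exp(tau*-
#' quantile of the group's pooled log expression), and normalized counts are
#' Y_ij = count_ij / SF_j (zeros stay zero).
#'
#' Starting from K = 1, normalization is verified by re-estimating slope
#' modes within `n_check_pools` equal-size expression pools of the
#' normalized data; if any |mode| exceeds `slope_mode_threshold` the
#' normalization is deemed insufficient and K is incremented, up to `K_max`
#' (then the best K is returned with a warning flag in the fit).
#'
#' When the library sizes are (near-)equal — log depths spanning less than
#' 0.05 — there is no count-depth relationship to remove and slope
#' estimates against a near-constant regressor are pure noise, so the
#' method returns the identity normalization, accepted at K = 1 with the
#' `degenerate_depth` flag set in the fit.
#'
#' Genes nonzero in fewer than `min_nonzero` cells are excluded from fitting
#' and passed through scaled by the factor of the group with the nearest
#' median expression; they are flagged in the fit.
#'
#' @param cm A [count_matrix()], [normalized_matrix()] or plain non-negative
#'   matrix.
#' @param n_check_pools Number of equal-size gene pools in the verification
#'   step.
#' @param slope_mode_threshold Acceptance threshold on |slope mode|.
#' @param quantile_grid Candidate quantile levels tau.
#' @param degree_grid Candidate polynomial degrees d.
#' @param min_nonzero Minimum nonzero cells for a gene to enter the fit.
#' @param K_max Maximum number of gene groups tried.
#' @return A list with `normalized` (a linear-scale [normalized_matrix()])
#'   and `fit` (an `scnorm_fit` with K, group assignment, gene slopes,
#'   per-group tau*/d*/eta coefficients, the per-cell-per-group scale
#'   factors, the verification modes, and an `accepted` flag).
#' @export
normalize_scnorm <- function(cm, n_check_pools = 10,
                             slope_mode_threshold = 0.1,
                             quantile_grid = seq(0.05, 0.95, by = 0.05),
                             degree_grid = 1:3,
                             min_nonzero = 10, K_max = 10) {
  X <- if (inherits(cm, "count_matrix")) cm$counts
       else if (inherits(cm, "normalized_matrix")) cm$values
       else as.matrix(cm)
  gene_ids <- rownames(X) %||% paste0("gene_", seq_len(nrow(X)))
  cell_ids <- colnames(X) %||% paste0("cell_", seq_len(ncol(X)))
  is_spike <- if (inherits(cm, "count_matrix")) cm$is_spikein else NULL
  if (any(X < 0)) stop("negative expression values", call. = FALSE)
  totals <- colSums(X)
  if (any(totals == 0)) stop("zero column total", call. = FALSE)
  D <- log(totals)
  # degenerate depth: with (near-)equal library sizes there is no
  # count-depth relationship to remove, and slope estimates against a
  # near-constant regressor are pure noise; return the identity
  if (diff(range(D)) < 0.05) {
    fit <- structure(
      list(K = 1L, group_assignment = rep(1L, nrow(X)),
           gene_slope = stats::setNames(rep(NA_real_, nrow(X)), gene_ids),
           retained_genes = seq_len(nrow(X)), filtered_genes = integer(0),
           groups = list(list(tau_star = NA_real_, d_star = NA_integer_,
                              beta = NA_real_, eta = c(NA_real_, 0),
                              slope_mode = 0, anchor = NA_real_)),
           size_factor = matrix(1, ncol(X), 1),
           check_modes = 0, accepted = TRUE,
           slope_mode_threshold = slope_mode_threshold,
           degenerate_depth = TRUE),
      class = "scnorm_fit"
    )
    nm <- normalized_matrix(X, method = "scnorm", scale = "linear",
                            gene_ids = gene_ids, cell_ids = cell_ids,
                            is_spikein = is_spike)
    return(list(normalized = nm, fit = fit))
  }
  nz <- X > 0
  logX <- matrix(NA_real_, nrow(X), ncol(X))
  logX[nz] <- log(X[nz])

  retained <- which(rowSums(nz) >= min_nonzero)
  if (length(retained) < 2) {
    stop("fewer than two genes pass the nonzero-cell filter", call. = FALSE)
  }
  filtered <- setdiff(seq_len(nrow(X)), retained)
  slopes <- batch_median_slopes(logX[retained, , drop = FALSE], D,
                                nz[retained, , drop = FALSE])
  ok_slope <- is.finite(slopes)
  retained <- retained[ok_slope]
  slopes <- slopes[ok_slope]
  gene_med <- apply(logX, 1, stats::median, na.rm = TRUE)
  gene_med[is.na(gene_med)] <- -Inf

  best <- NULL
  for (K in seq_len(K_max)) {
    if (length(retained) < K) {
      stop("fewer retained genes than groups (K = ", K, ")", call. = FALSE)
    }
    res <- scnorm_fit_k(X, logX, nz, D, retained, slopes, K,
                        quantile_grid, degree_grid, gene_med, filtered)
    modes <- scnorm_check_modes(res$Y, D, retained, n_check_pools)
    res$check_modes <- modes
    res$K <- K
    if (all(abs(modes) <= slope_mode_threshold)) {
      res$accepted <- TRUE
      best <- res
      break
    }
    if (is.null(best) || max(abs(modes)) < max(abs(best$check_modes))) {
      res$accepted <- FALSE
      best <- res
    }
  }
  if (!best$accepted) {
    warning("count-depth modes still exceed ", slope_mode_threshold,
            " at K_max = ", K_max, "; returning best K = ", best$K)
  }
  fit <- structure(
    list(K = best$K, group_assignment = best$group_assignment,
         gene_slope = stats::setNames(slopes, gene_ids[retained]),
         retained_genes = retained, filtered_genes = filtered,
         groups = best$groups, size_factor = best$size_factor,
         check_modes = best$check_modes, accepted = best$accepted,
         slope_mode_threshold = slope_mode_threshold),
    class = "scnorm_fit"
  )
  nm <- normalized_matrix(best$Y, method = "scnorm", scale = "linear",
                          gene_ids = gene_ids, cell_ids = cell_ids,
                          is_spikein = is_spike)
  list(normalized = nm, fit = fit)
}

# One pass of group partitioning, (tau, d) search, and scaling for a given K.
scnorm_fit_k <- function(X, logX, nz, D, retained, slopes, K,
                         quantile_grid, degree_grid, gene_med, filtered) {
  ord <- order(slopes)
  grp_of_sorted <- ceiling(seq_along(ord) * K / length(ord))
  group_assignment <- integer(length(retained))
  group_assignment[ord] <- grp_of_sorted

  Y <- X
  size_factor <- matrix(NA_real_, ncol(X), K)
  groups <- vector("list", K)
  group_med <- numeric(K)
  for (k in seq_len(K)) {
    g_idx <- retained[group_assignment == k]
    pool_mask <- nz[g_idx, , drop = FALSE]
    y_pool <- logX[g_idx, , drop = FALSE][pool_mask]
    x_pool <- matrix(D, length(g_idx), ncol(X), byrow = TRUE)[pool_mask]
    target <- mode_of_slopes(slopes[group_assignment == k])
    best_fit <- NULL
    for (d in degree_grid) {
      if (length(y_pool) < d + 2) next
      warm <- NULL
      for (tau in quantile_grid) {
        # warm-start each tau from the previous fit of the same degree and
        # skip the expensive polish: the fit only steers the (tau, d)
        # selection and the per-cell scale factors, for which IRLS accuracy
        # is ample
        beta <- tryCatch(
          quantile_regression(y_pool, x_pool, tau = tau, degree = d,
                              max_iter = 30, polish = FALSE, init = warm),
          error = function(e) NULL)
        if (is.null(beta)) next
        warm <- beta
        fitted_cells <- drop(cbind(1, stats::poly(D, degree = d, raw = TRUE,
                                                  simple = TRUE)) %*% beta)
        eta <- quantile_regression(fitted_cells, D, tau = 0.5, degree = 1)
        score <- abs(eta[2] - target)
        if (is.null(best_fit) || score < best_fit$score) {
          best_fit <- list(tau_star = tau, d_star = d, beta = beta,
                           eta = eta, score = score,
                           fitted_cells = fitted_cells)
        }
      }
    }
    if (is.null(best_fit)) {
      stop("no admissible quantile fit for group ", k, call. = FALSE)
    }
    anchor <- stats::quantile(y_pool, probs = best_fit$tau_star, names = FALSE)
    SF <- exp(best_fit$fitted_cells) / exp(anchor)
    size_factor[, k] <- SF
    Y[g_idx, ] <- sweep(X[g_idx, , drop = FALSE], 2, SF, "/")
    group_med[k] <- stats::median(gene_med[g_idx], na.rm = TRUE)
    groups[[k]] <- list(tau_star = best_fit$tau_star, d_star = best_fit$d_star,
                        beta = best_fit$beta, eta = best_fit$eta,
                        slope_mode = target, anchor = anchor)
  }
  if (length(filtered) > 0) {
    nearest <- vapply(gene_med[filtered],
                      function(m) which.min(abs(group_med - m)), 1L)
    for (i in seq_along(filtered)) {
      Y[filtered[i], ] <- X[filtered[i], ] / size_factor[, nearest[i]]
    }
  }
  list(Y = Y, group_assignment = group_assignment, groups = groups,
       size_factor = size_factor)
}

# Verification: slope modes within equal-size expression pools of the
# normalized data.
scnorm_check_modes <- function(Y, D, retained, n_check_pools) {
  nzY <- Y > 0
  logY <- matrix(NA_real_, nrow(Y), ncol(Y))
  logY[nzY] <- log(Y[nzY])
  med <- apply(logY[retained, , drop = FALSE], 1, stats::median, na.rm = TRUE)
  n_pools <- max(1L, min(n_check_pools, length(retained) %/% 3))
  ord <- order(med)
  pool_of_sorted <- ceiling(seq_along(ord) * n_pools / length(ord))
  pool <- integer(length(retained))
  pool[ord] <- pool_of_sorted
  sl <- batch_median_slopes(logY[retained, , drop = FALSE], D,
                            nzY[retained, , drop = FALSE])
  vapply(seq_len(n_pools), function(p) {
    s <- sl[pool == p]
    s <- s[is.finite(s)]
    if (length(s) == 0) 0 else mode_of_slopes(s)
  }, 1.0)
}

#' @export
print.scnorm_fit <- function(x, ...) {
  cat("<scnorm_fit> K=", x$K, " (", if (x$accepted) "accepted" else
      "K_max reached", "), max |check mode| = ",
      format(max(abs(x$check_modes)), digits = 3), "\n", sep = "")
  invisible(x)
}
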