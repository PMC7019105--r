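#' Simple library-size normalization
#'
#' The baseline global-scaling method: divide each count by its cell's
#' column total, multiply by a fixed scale factor, and natural-log transform
#' with log(x + 1). Y_ij = ln(X_ij * scale_factor / colsum_j + 1).
#'
#' @param cm A [count_matrix()].
#' @param scale_factor Positive scale factor (default 10000).
#' @return A [normalized_matrix()] on the log scale.
#' @export
normalize_simple <- function(cm, scale_factor = 10000) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- colSums(cm$counts)
  if (any(totals == 0)) {
    stop("zero column total for cell '", cm$cell_ids[which(totals == 0)[1]],
         "'", call. = FALSE)
  }
  vals <- log1p(sweep(cm$counts, 2, scale_factor / totals, "*"))
  normalized_matrix(vals, method = "simple", scale = "log",
                    gene_ids = cm$gene_ids, cell_ids = cm$cell_ids,
                    size_factors = totals / scale_factor,
                    is_spikein = cm$is_spikein)
}

#' Spike-in depth normalization with Poisson resampling
#'
#' Estimates each cell's sequencing depth from its spike-in rows alone,
#' assuming every cell received the same quantity of spike-in molecules: the
#' depth factor is the cell's spike-in column total divided by the geometric
#' mean of spike-in totals across cells. In `expected` mode counts are
#' simply divided by the depth factor; in `resample` mode (the method's
#' native behaviour) each output entry is the mean of seeded Poisson draws
#' with mean X_ij / d_j. Spike-in rows are carried through under the same
#' rule and stay flagged.
#'
#' @param cm A [count_matrix()] with at least one spike-in row and a
#'   positive spike-in total in every cell.
#' @param mode `"resample"` (default) or `"expected"`.
#' @param n_resamples Number of Poisson draws averaged in resample mode.
#' @param seed Integer seed for the resampling draws.
#' @return A [normalized_matrix()] on the linear scale.
#' @export
normalize_samstrt <- function(cm, mode = c("resample", "expected"),
                              n_resamples = 20, seed = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  mode <- match.arg(mode)
  if (!any(cm$is_spikein)) {
    stop("spike-in rows are required for spike-in depth normalization",
         call. = FALSE)
  }
  spike_tot <- colSums(cm$counts[cm$is_spikein, , drop = FALSE])
  if (any(spike_tot == 0)) {
    stop("zero spike-in total for cell '",
         cm$cell_ids[which(spike_tot == 0)[1]], "'", call. = FALSE)
  }
  d <- spike_tot / exp(mean(log(spike_tot)))
  expected <- sweep(cm$counts, 2, d, "/")
  vals <- if (mode == "expected") {
    expected
  } else {
    withr::with_seed(seed, {
      acc <- matrix(0, nrow(expected), ncol(expected))
      for (r in seq_len(n_resamples)) {
        acc <- acc + stats::rpois(length(expected), expected)
      }
      acc / n_resamples
    })
  }
  normalized_matrix(vals, method = "samstrt", scale = "linear",
                    gene_ids = cm$gene_ids, cell_ids = cm$cell_ids,
                    size_factors = d, is_spikein = cm$is_spikein)
}
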