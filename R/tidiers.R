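#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-repeat kappa samples of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return A tibble with columns `method`, `repeat_id`, `kappa`.
#' @export
tidy.evaluation_report <- function(x, ...) x$kappa

#' One-row-per-method summary of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return A tibble with per-method median, mean and sd of kappa.
#' @export
glance.evaluation_report <- function(x, ...) {
  x$kappa |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(median_kappa = stats::median(.data$kappa),
                     mean_kappa = mean(.data$kappa),
                     sd_kappa = stats::sd(.data$kappa),
                     n_repeats = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$median_kappa))
}

#' Kappa distribution plot for an evaluation report
#'
#' Boxplots of the per-repeat Cohen's kappa values by method, ordered by
#' median.
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  tbl <- object$kappa |>
    dplyr::mutate(method = stats::reorder(.data$method, .data$kappa,
                                          FUN = stats::median))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$method, y = .data$kappa)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Cohen's kappa",
                  title = "Classification agreement by normalization method") +
    ggplot2::theme_minimal()
}

#' Tidy posterior medians of the hierarchical Poisson-Gamma fit
#'
#' @param x A `basics_fit`.
#' @param ... Unused.
#' @return A long tibble of per-gene and per-cell parameter estimates.
#' @export
tidy.basics_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(parameter = "mu", id = x$gene_ids, estimate = x$mu),
    tibble::tibble(parameter = "delta", id = x$gene_ids, estimate = x$delta),
    tibble::tibble(parameter = "phi", id = x$cell_ids, estimate = x$phi),
    tibble::tibble(parameter = "s", id = x$cell_ids, estimate = x$s),
    tibble::tibble(parameter = "nu", id = x$cell_ids, estimate = x$nu)
  )
}

#' @export
glance.basics_fit <- function(x, ...) {
  tibble::tibble(theta = x$theta, n_genes = length(x$mu),
                 n_spikeins = sum(x$is_spikein), n_cells = length(x$phi),
                 n_kept_draws = x$diagnostics$n_kept,
                 theta_ess = x$diagnostics$theta_ess)
}

#' @export
tidy.grm_fit <- function(x, ...) {
  tibble::tibble(term = paste0("beta_", seq_along(x$beta) - 1),
                 estimate = x$beta,
                 std_error = sqrt(pmax(diag(x$vcov), 0)))
}

#' @export
glance.grm_fit <- function(x, ...) {
  tibble::tibble(degree = x$degree, shape = x$shape,
                 fit_score = x$fit_score, n_spikes = x$n_spikes)
}

#' @export
tidy.scnorm_fit <- function(x, ...) {
  purrr::imap_dfr(x$groups, function(g, k) {
    tibble::tibble(group = as.integer(k), tau_star = g$tau_star,
                   d_star = g$d_star, slope_mode = g$slope_mode,
                   eta_slope = g$eta[2])
  })
}

#' @export
glance.scnorm_fit <- function(x, ...) {
  tibble::tibble(K = x$K, accepted = x$accepted,
                 max_check_mode = max(abs(x$check_modes)),
                 n_retained = length(x$retained_genes),
                 n_filtered = length(x$filtered_genes))
}

#' @export
tidy.linnorm_fit <- function(x, ...) {
  tibble::tibble(cell = seq_along(x$a), a = x$a, b = x$b,
                 a_updated = x$a_updated, b_updated = x$b_updated)
}

#' @export
glance.linnorm_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_stable = length(x$stable_genes),
                 c = x$c)
}

#' @export
tidy.scran_pools <- function(x, ...) {
  tibble::tibble(pool = seq_along(x$pool_memberships),
                 size = lengths(x$pool_memberships),
                 ratio_factor = x$pool_ratio_factor)
}

#' @export
glance.scran_pools <- function(x, ...) {
  tibble::tibble(n_pools = length(x$pool_memberships),
                 n_cells = length(x$t),
                 min_factor = min(x$solution), max_factor = max(x$solution))
}

#' @importFrom dplyr .data
NULL
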