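#' Fit the hierarchical Poisson-Gamma normalization model by MCMC
#'
#' Jointly models spike-in and biological rows of a cleaned count matrix:
#' spike-in counts are Poisson(nu_j * mu_i) where nu_j is a latent per-cell
#' capture effect drawn around the capture-efficiency constant s_j with
#' technical-noise parameter theta (Gamma(1/theta, rate 1/(s_j theta)));
#' biological counts additionally carry the cell-size factor phi_j and a
#' gene-level Gamma(1/delta_i, 1/delta_i) biological random effect, which is
#' marginalized analytically into a negative binomial with size 1/delta_i
#' and mean phi_j * nu_j * mu_i. A Metropolis-within-Gibbs sampler (compiled
#' code, adaptive random-walk proposals on the log scale) draws from the
#' posterior under log-normal(center, 2^2) priors on mu_i (empirically
#' centered at the mean log initial estimate, separately for spike-in and
#' biological genes, so the weakly informative prior does not drag the
#' unidentified joint scale of nu and the spike-in rates) and
#' log-normal(0, 2^2) on delta_i, a
#' Gamma(1, 1) prior on theta, and a concentrated Gamma(10, 10) prior on the
#' capture-efficiency constants s_j (spike-ins enter every lysate in equal
#' amounts, so the capture constants should vary only moderately around a
#' common scale; a diffuse s prior would absorb the capture variation that
#' theta is meant to quantify and leave theta unidentified at typical cell
#' numbers). The s_j are marginalized out of the chain by quadrature, and
#' phi is rescaled every sweep so that sum(phi_j) equals the number of
#' cells. Point estimates are posterior medians; reported s_j values are
#' conditional means given nu_j and theta.
#'
#' Because spike-ins enter every lysate in equal amounts, the spike-in rows
#' carry no phi_j term; cleaning low-count genes and cells first (see
#' [clean_counts()]) matters for this model.
#'
#' @param cm A [count_matrix()] with both spike-in and biological rows,
#'   ideally cleaned.
#' @param n_iter Total MCMC sweeps (default 20000).
#' @param burn_in Sweeps discarded before recording (default 10000).
#' @param thin Keep every `thin`-th sweep after burn-in (default 10).
#' @param seed Integer seed.
#' @param s_prior_shape,s_prior_rate Gamma prior on the capture-efficiency
#'   constants s_j (default Gamma(10, 10): mean 1, CV^2 = 0.1).
#' @return A `basics_fit` with posterior medians (`mu`, `delta`, `phi`,
#'   `s`, `nu`, `theta`), retained draws in `chains`, effective-sample-size
#'   style diagnostics, and the gene/cell bookkeeping.
#' @export
fit_basics <- function(cm, n_iter = 20000, burn_in = 10000, thin = 10,
                       seed = 1, s_prior_shape = 10, s_prior_rate = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!any(cm$is_spikein) || !any(!cm$is_spikein)) {
    stop("the model needs both spike-in and biological rows", call. = FALSE)
  }
  if (burn_in >= n_iter) stop("burn_in must be below n_iter", call. = FALSE)
  bio <- cm$counts[!cm$is_spikein, , drop = FALSE]
  spike <- cm$counts[cm$is_spikein, , drop = FALSE]
  n <- ncol(bio)

  spike_col <- colSums(spike)
  if (any(spike_col == 0)) {
    stop("zero spike-in total for cell '",
         cm$cell_ids[which(spike_col == 0)[1]],
         "'; clean the matrix first", call. = FALSE)
  }
  nu0 <- spike_col / mean(spike_col)
  mu_s0 <- pmax(rowMeans(sweep(spike, 2, nu0, "/")), 1e-4)
  bio_col <- colSums(bio)
  phi0 <- bio_col / nu0
  phi0 <- phi0 / sum(phi0) * n
  mu_b0 <- pmax(rowMeans(sweep(bio, 2, phi0 * nu0, "/")), 1e-4)
  delta0 <- rep(0.5, nrow(bio))
  theta0 <- 0.2
  if (!all(is.finite(c(mu_b0, mu_s0, phi0, nu0))) ||
      any(c(mu_b0, mu_s0, phi0, nu0) <= 0)) {
    stop("non-finite log-posterior at initialization; check for empty ",
         "rows or columns", call. = FALSE)
  }

  draws <- withr::with_seed(seed, {
    basics_gibbs(bio, spike, mu_b0, mu_s0, delta0, phi0, nu0, theta0,
                 s_prior_shape, s_prior_rate,
                 mean(log(mu_b0)), mean(log(mu_s0)),
                 as.integer(n_iter), as.integer(burn_in), as.integer(thin))
  })

  med <- function(m) apply(m, 2, stats::median)
  mu <- numeric(nrow(cm$counts))
  mu[!cm$is_spikein] <- med(draws$mu_bio)
  mu[cm$is_spikein] <- med(draws$mu_spike)
  delta <- rep(NA_real_, nrow(cm$counts))
  delta[!cm$is_spikein] <- med(draws$delta)

  ess <- function(v) {
    v <- as.numeric(v)
    if (stats::sd(v) == 0) return(length(v))
    r1 <- stats::cor(v[-1], v[-length(v)])
    max(1, length(v) * (1 - r1) / (1 + r1))
  }
  structure(
    list(
      mu = mu, delta = delta,
      phi = med(draws$phi), s = med(draws$s), nu = med(draws$nu),
      theta = stats::median(draws$theta),
      chains = draws,
      diagnostics = list(
        n_kept = draws$n_kept,
        theta_ess = ess(draws$theta),
        n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed
      ),
      gene_ids = cm$gene_ids, cell_ids = cm$cell_ids,
      is_spikein = cm$is_spikein
    ),
    class = "basics_fit"
  )
}

#' @export
print.basics_fit <- function(x, ...) {
  cat("<basics_fit> ", length(x$mu), " genes (",
      sum(x$is_spikein), " spike-ins) x ", length(x$phi), " cells; ",
      "posterior median theta = ", format(x$theta, digits = 3), ", ",
      x$diagnostics$n_kept, " retained draws\n", sep = "")
  invisible(x)
}

#' Normalize counts with a fitted hierarchical Poisson-Gamma model
#'
#' Removes the estimated cell-specific multiplicative terms: biological
#' counts are divided by phi_j * nu_j, spike-in counts (which never carried
#' phi) by nu_j alone. Per-cell size factors phi_j * nu_j are recorded.
#'
#' @param fit A `basics_fit` from [fit_basics()].
#' @param cm The matching [count_matrix()].
#' @return A linear-scale [normalized_matrix()].
#' @export
normalize_basics <- function(fit, cm) {
  stopifnot(inherits(fit, "basics_fit"), inherits(cm, "count_matrix"))
  if (!identical(dim(cm$counts), c(length(fit$mu), length(fit$phi)))) {
    stop("fit and count matrix dimensions disagree", call. = FALSE)
  }
  factor_bio <- fit$phi * fit$nu
  if (any(!is.finite(factor_bio) | factor_bio <= 0) ||
      any(!is.finite(fit$nu) | fit$nu <= 0)) {
    stop("non-positive estimated size factors", call. = FALSE)
  }
  Y <- cm$counts
  Y[!cm$is_spikein, ] <- sweep(Y[!cm$is_spikein, , drop = FALSE], 2,
                               factor_bio, "/")
  Y[cm$is_spikein, ] <- sweep(Y[cm$is_spikein, , drop = FALSE], 2,
                              fit$nu, "/")
  normalized_matrix(Y, method = "basics", scale = "linear",
                    gene_ids = cm$gene_ids, cell_ids = cm$cell_ids,
                    size_factors = factor_bio, is_spikein = cm$is_spikein)
}
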