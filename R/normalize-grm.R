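#' Fit a per-cell gamma regression of log concentration on log FPKM
#'
#' Calibrates one cell against its spike-ins: the log known concentration C
#' is modelled as Gamma-distributed with shape phi and mean
#' mu(X) = sum_d beta_d X^d, a polynomial in X = log(FPKM). Candidate
#' polynomial degrees (1-4 by default) are each fit by maximum likelihood
#' (BFGS over the coefficients and log shape, started from the least-squares
#' polynomial), and the degree with the smallest mean squared spike-in
#' residual — the fit with minimal average technical noise — is selected,
#' ties resolving to the lower degree. Pairs with non-positive log
#' concentration are excluded (the gamma response requires C > 0), as are
#' degrees whose fitted mean is non-positive at any spike-in.
#'
#' @param log_fpkm_spike Log FPKM of the cell's detected spike-ins.
#' @param log_conc Matching log known concentrations.
#' @param degrees Candidate polynomial degrees.
#' @return A `grm_fit` with `degree`, `beta`, `shape`, `fit_score` (mean
#'   squared residual), `vcov` of beta, and per-degree scores.
#' @export
fit_grm_cell <- function(log_fpkm_spike, log_conc, degrees = 1:4) {
  stopifnot(length(log_fpkm_spike) == length(log_conc))
  keep <- is.finite(log_fpkm_spike) & is.finite(log_conc) & log_conc > 0
  X <- log_fpkm_spike[keep]
  C <- log_conc[keep]
  degrees <- sort(unique(as.integer(degrees)))
  degrees <- degrees[degrees >= 1]
  usable <- degrees[length(X) >= degrees + 2]
  if (length(usable) == 0) {
    stop("only ", length(X), " usable spike-ins; need at least degree + 2",
         call. = FALSE)
  }
  fits <- lapply(usable, function(d) grm_fit_degree(X, C, d))
  scores <- vapply(fits, function(f) if (is.null(f)) Inf else f$fit_score, 1.0)
  if (all(!is.finite(scores))) {
    stop("no candidate degree produced a positive fitted mean at every ",
         "spike-in", call. = FALSE)
  }
  best <- min(scores)
  pick <- which(scores <= best * (1 + 1e-9) + 1e-12)[1]
  out <- fits[[pick]]
  out$degree <- usable[pick]
  out$degree_scores <- stats::setNames(scores, usable)
  out$n_spikes <- length(X)
  class(out) <- "grm_fit"
  out
}

# Gamma MLE for one candidate degree; NULL when the degree is inadmissible.
grm_fit_degree <- function(X, C, d) {
  basis <- cbind(1, stats::poly(X, degree = d, raw = TRUE, simple = TRUE))
  if (qr(basis)$rank < ncol(basis)) return(NULL)
  beta0 <- drop(qr.coef(qr(basis), C))
  mu0 <- drop(basis %*% beta0)
  if (any(mu0 <= 0)) return(NULL)
  mse0 <- mean((C - mu0)^2)
  if (mse0 < 1e-12) {
    # exact interpolation: the gamma likelihood is maximized in the
    # degenerate shape -> Inf limit with the least-squares coefficients
    return(list(beta = unname(beta0), shape = Inf, fit_score = mse0,
                vcov = matrix(0, d + 1, d + 1), converged = TRUE))
  }
  shape0 <- min(max(mean(mu0^2) / mse0, 0.1), 1e6)
  negll <- function(par) {
    beta <- par[seq_len(d + 1)]
    phi <- exp(par[d + 2])
    mu <- drop(basis %*% beta)
    if (any(mu <= 0) || !is.finite(phi) || phi > 1e8) return(1e10)
    -sum((phi - 1) * log(C) + phi * log(phi / mu) - lgamma(phi) -
           phi * C / mu)
  }
  opt <- stats::optim(c(beta0, log(shape0)), negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12),
                      hessian = TRUE)
  beta <- opt$par[seq_len(d + 1)]
  phi <- exp(opt$par[d + 2])
  mu <- drop(basis %*% beta)
  if (any(mu <= 0)) return(NULL)
  vcov_full <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  vcov_beta <- if (is.null(vcov_full)) matrix(NA_real_, d + 1, d + 1)
               else vcov_full[seq_len(d + 1), seq_len(d + 1), drop = FALSE]
  list(beta = unname(beta), shape = phi, fit_score = mean((C - mu)^2),
       vcov = vcov_beta, converged = opt$convergence == 0)
}

#' @export
print.grm_fit <- function(x, ...) {
  cat("<grm_fit> degree=", x$degree, ", shape=", format(x$shape, digits = 4),
      ", mean squared residual=", format(x$fit_score, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Per-cell gamma-regression normalization against spike-in concentrations
#'
#' Applies [fit_grm_cell()] to every cell independently: each cell's
#' spike-ins with positive FPKM calibrate a polynomial gamma regression of
#' log known concentration on log FPKM, and every biological gene's
#' normalized value is the predicted log concentration
#' Y_i = sum_d beta_d X_i^d at its own X_i = log FPKM. Genes with zero count
#' in a cell get normalized value 0 (flagged per cell in the
#' `zero_flag` attribute). Altering one cell's counts cannot change another
#' cell's output.
#'
#' @param cm A [count_matrix()] with gene lengths and spike-in rows.
#' @param ref A [spikein_reference()] covering the spike-in rows.
#' @param degrees Candidate polynomial degrees passed to [fit_grm_cell()].
#' @return A [normalized_matrix()] of biological genes on the
#'   log-concentration scale, with per-cell `grm_fit`s in attribute `fits`
#'   and the zero-count mask in attribute `zero_flag`.
#' @export
normalize_grm <- function(cm, ref, degrees = 1:4) {
  stopifnot(inherits(cm, "count_matrix"), inherits(ref, "spikein_reference"))
  if (is.null(cm$gene_lengths)) {
    stop("gene lengths are required for FPKM-based normalization",
         call. = FALSE)
  }
  if (!any(cm$is_spikein)) stop("no spike-in rows in matrix", call. = FALSE)
  fpkm <- compute_fpkm(cm)
  spike_rows <- which(cm$is_spikein)
  conc <- ref$concentration[match(cm$gene_ids[spike_rows], ref$spikein_id)]
  known <- !is.na(conc)
  if (!any(known)) {
    stop("no spike-in rows match the reference ids", call. = FALSE)
  }
  spike_rows <- spike_rows[known]
  log_conc_all <- log(conc[known])
  bio_rows <- which(!cm$is_spikein)
  n <- ncol(cm$counts)
  vals <- matrix(0, length(bio_rows), n)
  fits <- vector("list", n)
  for (j in seq_len(n)) {
    sp_fpkm <- fpkm[spike_rows, j]
    pos <- sp_fpkm > 0
    if (!any(pos)) {
      stop("all spike-ins are zero in cell '", cm$cell_ids[j], "'",
           call. = FALSE)
    }
    fit <- fit_grm_cell(log(sp_fpkm[pos]), log_conc_all[pos],
                        degrees = degrees)
    fits[[j]] <- fit
    x_bio <- fpkm[bio_rows, j]
    nzb <- x_bio > 0
    if (any(nzb)) {
      basis <- cbind(1, stats::poly(log(x_bio[nzb]), degree = fit$degree,
                                    raw = TRUE, simple = TRUE))
      vals[nzb, j] <- drop(basis %*% fit$beta)
    }
  }
  nm <- normalized_matrix(vals, method = "grm", scale = "log",
                          gene_ids = cm$gene_ids[bio_rows],
                          cell_ids = cm$cell_ids,
                          kept_gene_index = bio_rows,
                          is_spikein = rep(FALSE, length(bio_rows)))
  attr(nm, "fits") <- fits
  attr(nm, "zero_flag") <- cm$counts[bio_rows, , drop = FALSE] == 0
  nm
}
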