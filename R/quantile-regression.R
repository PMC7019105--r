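#' Polynomial quantile regression
#'
#' Minimizes the check loss sum(rho_tau(y - poly(x))) with
#' rho_tau(u) = u * (tau - \[u < 0\]) over polynomial coefficients. The fit is
#' an iteratively reweighted least-squares approximation (asymmetric
#' 1/|residual| weights) followed by a Nelder-Mead polish of the exact check
#' loss; both stages are deterministic, so the result is reproducible for
#' identical inputs.
#'
#' @param y Numeric response.
#' @param x Numeric covariate, same length as `y`.
#' @param tau Quantile level in (0, 1).
#' @param degree Polynomial degree (raw powers of `x`).
#' @param max_iter IRLS iteration cap.
#' @param polish Refine the IRLS solution with a Nelder-Mead pass over the
#'   exact check loss (skipped automatically when the loss is already 0).
#' @param init Optional starting coefficients (warm start); default the
#'   least-squares fit.
#' @return Numeric coefficient vector (intercept first), length degree + 1.
#' @export
quantile_regression <- function(y, x, tau = 0.5, degree = 1,
                                max_iter = 100, polish = TRUE, init = NULL) {
  stopifnot(length(y) == length(x))
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)", call. = FALSE)
  if (length(y) < degree + 2) {
    stop("need at least degree + 2 observations", call. = FALSE)
  }
  X <- stats::poly(x, degree = degree, raw = TRUE, simple = TRUE)
  X <- cbind(1, X)
  if (qr(X)$rank < ncol(X)) {
    stop("collinear design: polynomial basis is rank-deficient",
         call. = FALSE)
  }
  check_loss <- function(beta) {
    r <- y - drop(X %*% beta)
    sum(r * (tau - (r < 0)))
  }
  beta <- if (is.null(init)) qr.coef(qr(X), y) else init   # OLS start
  eps <- 1e-8 * (stats::sd(y) + 1e-12)
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), eps)
    Xw <- X * w
    beta_new <- tryCatch(solve(crossprod(Xw, X), crossprod(Xw, y)),
                         error = function(e) beta)
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < 1e-10 * (1 + max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  loss <- check_loss(beta)
  if (polish && loss > 1e-12) {
    polish <- stats::optim(beta, check_loss, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-12))
    if (polish$value < loss) beta <- polish$par
  }
  unname(beta)
}

#' Batch median-regression slopes across many genes
#'
#' Vectorized IRLS for the per-gene degree-1 median regression of log
#' nonzero expression on log depth: the same estimator as
#' [quantile_regression()] at tau = 0.5, degree = 1, run simultaneously for
#' every row of a masked matrix. Used for the per-gene count-depth slopes.
#'
#' @param Y Genes x cells matrix of responses (log nonzero expression;
#'   entries where `mask` is FALSE are ignored).
#' @param x Per-cell covariate (log depth).
#' @param mask Logical genes x cells inclusion matrix.
#' @param max_iter IRLS iteration cap.
#' @return Per-gene slope vector (NA where fewer than 3 usable cells).
#' @keywords internal
batch_median_slopes <- function(Y, x, mask, max_iter = 50) {
  G <- nrow(Y)
  n <- ncol(Y)
  Xmat <- matrix(x, G, n, byrow = TRUE)
  Y0 <- ifelse(mask, Y, 0)
  usable <- rowSums(mask) >= 3
  # OLS start per gene
  sw <- rowSums(mask)
  sx <- rowSums(Xmat * mask)
  sy <- rowSums(Y0)
  sxx <- rowSums(Xmat^2 * mask)
  sxy <- rowSums(Xmat * Y0)
  det <- sw * sxx - sx^2
  slope <- ifelse(usable & det > 1e-12, (sw * sxy - sx * sy) / det, NA_real_)
  inter <- ifelse(usable & det > 1e-12, (sy - slope * sx) / sw, NA_real_)
  eps <- 1e-8
  for (it in seq_len(max_iter)) {
    R <- Y0 - (inter + slope * Xmat)
    W <- mask * 0.5 / pmax(abs(R), eps)
    sw <- rowSums(W)
    sx <- rowSums(W * Xmat)
    sy <- rowSums(W * Y0)
    sxx <- rowSums(W * Xmat^2)
    sxy <- rowSums(W * Xmat * Y0)
    det <- sw * sxx - sx^2
    ok <- usable & is.finite(det) & det > 1e-12
    new_slope <- ifelse(ok, (sw * sxy - sx * sy) / det, slope)
    new_inter <- ifelse(ok, (sy - new_slope * sx) / sw, inter)
    if (max(abs(new_slope - slope), na.rm = TRUE) < 1e-9) {
      slope <- new_slope; inter <- new_inter
      break
    }
    slope <- new_slope; inter <- new_inter
  }
  slope
}

#' Mode of a slope distribution via kernel density
#'
#' The location of the highest peak of a Gaussian kernel density estimate
#' (Silverman's rule-of-thumb bandwidth) evaluated on a 512-point grid
#' spanning the range of the slopes. Grid ties resolve to the smaller value.
#'
#' @param slopes Numeric vector of at least two finite slopes (identical
#'   values are returned directly).
#' @param bandwidth_rule Bandwidth selector; only `"silverman"` is
#'   implemented.
#' @return The modal slope.
#' @export
mode_of_slopes <- function(slopes, bandwidth_rule = "silverman") {
  slopes <- slopes[is.finite(slopes)]
  if (length(slopes) == 0) stop("no finite slopes", call. = FALSE)
  if (length(unique(slopes)) == 1) return(slopes[1])
  if (length(slopes) < 2) stop("need at least two slopes", call. = FALSE)
  bandwidth_rule <- match.arg(bandwidth_rule, "silverman")
  bw <- stats::bw.nrd0(slopes)
  d <- stats::density(slopes, bw = bw, n = 512,
                      from = min(slopes), to = max(slopes))
  d$x[which.max(d$y)]
}
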