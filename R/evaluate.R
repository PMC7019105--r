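#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e) with observed
#' agreement p_o = trace / total and expected agreement
#' p_e = sum_g row_g * col_g / total^2. More informative than raw accuracy
#' when group sizes are unequal, as is typical for cell-type data. Returns 1
#' for a diagonal matrix even when p_e = 1 (perfect forced agreement);
#' otherwise p_e = 1 is an error.
#'
#' @param cmx Square non-negative matrix, rows = true condition, columns =
#'   predicted condition.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(cmx) {
  cmx <- as.matrix(cmx)
  if (nrow(cmx) != ncol(cmx)) {
    stop("confusion matrix must be square", call. = FALSE)
  }
  total <- sum(cmx)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  p_o <- sum(diag(cmx)) / total
  p_e <- sum(rowSums(cmx) * colSums(cmx)) / total^2
  if (p_e >= 1) {
    if (p_o == 1) return(1)
    stop("expected agreement is 1 but observed agreement is not",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Repeated stratified KNN classification scored by Cohen's kappa
#'
#' The quantitative yardstick for normalization quality: over `n_repeats`
#' seeded repeats, cells are split into stratified train/test sets, each
#' test cell is classified by Euclidean k-nearest-neighbour majority vote
#' among the training cells (distance ties broken by training index, vote
#' ties by smallest class index), and the test confusion matrix is scored
#' with [cohens_kappa()]. Deterministic given the seed.
#'
#' @param values Cells x features matrix (e.g. PCA scores).
#' @param labels Condition label per cell; at least two conditions, each
#'   with at least k + 1 cells.
#' @param k Number of neighbours.
#' @param train_fraction Fraction of each condition used for training.
#' @param n_repeats Number of random splits (default 100).
#' @param seed Integer seed.
#' @return Numeric vector of `n_repeats` kappa values.
#' @export
knn_classify_repeated <- function(values, labels, k = 5,
                                  train_fraction = 0.7, n_repeats = 100,
                                  seed = 1) {
  values <- as.matrix(values)
  labels <- as.character(labels)
  stopifnot(nrow(values) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two conditions", call. = FALSE)
  sizes <- table(labels)
  if (any(sizes < k + 1)) {
    stop("condition '", names(sizes)[which(sizes < k + 1)[1]],
         "' has fewer than k + 1 cells", call. = FALSE)
  }
  y <- match(labels, classes)
  withr::with_seed(seed, {
    vapply(seq_len(n_repeats), function(rep_i) {
      train <- unlist(lapply(classes, function(cl) {
        idx <- which(labels == cl)
        sample(idx, max(1, round(train_fraction * length(idx))))
      }))
      test <- setdiff(seq_along(labels), train)
      if (length(test) == 0) stop("empty test set", call. = FALSE)
      pred <- knn_predict(values[train, , drop = FALSE], y[train],
                          values[test, , drop = FALSE], k,
                          n_classes = length(classes))
      cmx <- table(factor(y[test], levels = seq_along(classes)),
                   factor(pred, levels = seq_along(classes)))
      cohens_kappa(cmx)
    }, 1.0)
  })
}

# Euclidean KNN with deterministic tie-breaking: nearest-distance ties go to
# the lower training index, vote ties to the smallest class index.
knn_predict <- function(train, y_train, test, k, n_classes) {
  k <- min(k, nrow(train))
  d2 <- outer(rowSums(test^2), rep(1, nrow(train))) +
    outer(rep(1, nrow(test)), rowSums(train^2)) -
    2 * tcrossprod(test, train)
  apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(k)]
    votes <- tabulate(y_train[nn], nbins = n_classes)
    which.max(votes)
  })
}

#' PCA embedding of a gene-by-cell matrix
#'
#' Centered singular value decomposition with cells as observations;
#' components are ordered by decreasing singular value and each component's
#' sign is fixed so that its largest-magnitude gene loading is positive.
#'
#' @param values Genes x cells real matrix.
#' @param n_components Number of components (<= min(genes, cells)).
#' @return Cells x components score matrix with attributes `sdev` and
#'   `loadings`.
#' @export
pca_embed <- function(values, n_components = 50) {
  values <- as.matrix(values)
  n_components <- min(n_components, nrow(values), ncol(values))
  obs <- t(values)                       # cells x genes
  if (all(apply(obs, 2, stats::sd) == 0)) {
    stop("constant matrix has no principal components", call. = FALSE)
  }
  p <- stats::prcomp(obs, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(p$x))
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  load <- p$rotation[, seq_len(n_components), drop = FALSE]
  for (c_i in seq_len(n_components)) {
    top <- which.max(abs(load[, c_i]))
    if (load[top, c_i] < 0) {
      load[, c_i] <- -load[, c_i]
      scores[, c_i] <- -scores[, c_i]
    }
  }
  attr(scores, "sdev") <- p$sdev[seq_len(n_components)]
  attr(scores, "loadings") <- load
  scores
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment (delegated to
#' [stats::p.adjust()]): p-values are ranked, scaled by n / rank, and a
#' cumulative minimum from the largest rank down enforces monotonicity, with
#' results capped at 1 and returned in the original order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential-expression screen on normalized values
#'
#' Per-gene two-group test (Wilcoxon rank-sum by default, or a negative
#' binomial Wald test on counts) followed by BH adjustment; reports how many
#' genes are called at the adjusted threshold. A screening stand-in for full
#' DE pipelines: the point here is comparing normalization methods, not the
#' test itself.
#'
#' @param nm A [normalized_matrix()] (or plain matrix).
#' @param labels Condition per cell; exactly two conditions.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param test `"wilcoxon"` or `"nb_wald"`.
#' @return A list with `p` (raw p-values), `p_adjusted`, `n_significant`
#'   and `significant` (logical per gene).
#' @export
de_screen <- function(nm, labels, alpha = 0.05,
                      test = c("wilcoxon", "nb_wald")) {
  test <- match.arg(test)
  values <- if (inherits(nm, "normalized_matrix")) nm$values else
    as.matrix(nm)
  labels <- as.character(labels)
  stopifnot(ncol(values) == length(labels))
  groups <- sort(unique(labels))
  if (length(groups) != 2) {
    stop("exactly two conditions are required; run pairwise for more",
         call. = FALSE)
  }
  g1 <- labels == groups[1]
  p <- if (test == "wilcoxon") {
    apply(values, 1, function(v) {
      if (stats::sd(v) == 0) return(1)
      stats::wilcox.test(v[g1], v[!g1], exact = FALSE)$p.value
    })
  } else {
    off <- log(pmax(colSums(values), 1))
    grp <- factor(labels)
    apply(values, 1, function(v) {
      if (sum(v) == 0) return(1)
      fit <- tryCatch(
        MASS::glm.nb(round(v) ~ grp + offset(off)),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) return(1)
      stats::coef(summary(fit))[2, 4]
    })
  }
  p[is.na(p)] <- 1
  padj <- bh_adjust(p)
  list(p = p, p_adjusted = padj, n_significant = sum(padj < alpha),
       significant = padj < alpha)
}
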