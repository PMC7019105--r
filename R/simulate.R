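#' Derive a child seed from a global seed and a stage counter
#'
#' Lets one global seed fan out deterministically to independent stages so a
#' stage can be rerun on its own. Lehmer-style mixing keeps the result in the
#' 32-bit integer range R requires.
#'
#' @param seed Integer global seed.
#' @param k Integer stage counter.
#' @return An integer seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k) %% 2147483629 + 1)
}

#' Ground truth of a simulated experiment
#'
#' Bundles the generative parameters behind a simulated count matrix:
#' per-gene negative-binomial means and overdispersions (variance
#' m + phi * m^2), per-cell global scaling factors, which genes carry the
#' injected fold change, the fold change itself, group labels and (for the
#' spike-in branch) per-cell capture efficiencies.
#'
#' @param gene_mean Positive per-gene baseline means.
#' @param gene_dispersion Non-negative per-gene overdispersions.
#' @param cell_factor Positive per-cell global scaling factors.
#' @param de_flags Logical per-gene fold-change flags.
#' @param fold_change Multiplicative change (>= 1) applied to flagged genes
#'   in the second subgroup.
#' @param group_label Per-cell group labels.
#' @param capture_efficiency Optional positive per-cell capture efficiencies
#'   (spike-in branch).
#' @param seed Seed the realization was drawn under.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(gene_mean, gene_dispersion, cell_factor,
                             de_flags, fold_change, group_label,
                             capture_efficiency = NULL, seed = NA_integer_) {
  stopifnot(length(gene_mean) == length(gene_dispersion),
            length(gene_mean) == length(de_flags),
            length(cell_factor) == length(group_label))
  if (any(gene_mean <= 0)) stop("gene means must be positive", call. = FALSE)
  if (any(gene_dispersion < 0)) {
    stop("dispersions must be non-negative", call. = FALSE)
  }
  if (any(cell_factor <= 0)) {
    stop("cell factors must be positive", call. = FALSE)
  }
  if (fold_change < 1) stop("fold change must be >= 1", call. = FALSE)
  structure(
    list(gene_mean = gene_mean, gene_dispersion = gene_dispersion,
         cell_factor = cell_factor, de_flags = as.logical(de_flags),
         fold_change = fold_change, group_label = as.character(group_label),
         capture_efficiency = capture_efficiency, seed = seed),
    class = "simulation_truth"
  )
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth> ", length(x$gene_mean), " genes, ",
      length(x$cell_factor), " cells, ", sum(x$de_flags),
      " fold-changed genes (fold ", x$fold_change, ")\n", sep = "")
  invisible(x)
}

#' Estimate simulation template parameters from a count matrix
#'
#' Method-of-moments estimates used to seed the simulator from real data:
#' per-cell factors are column totals relative to their mean, per-gene means
#' are averages of factor-adjusted counts, and per-gene overdispersions come
#' from the NB variance identity var = m + phi * m^2 applied to the
#' factor-adjusted counts (clamped at zero).
#'
#' @param cm A [count_matrix()] with at least two cells.
#' @return A list with `gene_mean`, `gene_dispersion` and `cell_factor`.
#' @export
estimate_template_params <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  n <- ncol(cm$counts)
  if (n < 2) stop("at least two cells are required", call. = FALSE)
  totals <- colSums(cm$counts)
  cell_factor <- totals / mean(totals)
  adj <- sweep(cm$counts, 2, cell_factor, "/")
  gene_mean <- rowMeans(adj)
  gene_var <- apply(adj, 1, stats::var)
  gene_dispersion <- ifelse(gene_mean > 0,
                            pmax(0, (gene_var - gene_mean) / gene_mean^2), 0)
  list(gene_mean = gene_mean, gene_dispersion = gene_dispersion,
       cell_factor = cell_factor)
}

#' Default template parameters for a de-novo simulation
#'
#' When no real template matrix is available, gene means are drawn from a
#' heavy-tailed log-normal (many weakly expressed genes, a few dominant
#' ones), overdispersions from a log-normal centred near 0.5, and cell
#' factors from a log-normal with moderate spread — magnitudes typical of
#' full-length-protocol scRNA-seq counts after cleaning.
#'
#' @param n_genes Number of biological genes.
#' @param n_cells Number of cells.
#' @param mean_log,mean_sdlog Log-normal parameters for gene means.
#' @param disp_log,disp_sdlog Log-normal parameters for dispersions.
#' @param factor_sdlog Log-normal sd of the per-cell scaling factors.
#' @param seed Integer seed.
#' @return A list with `gene_mean`, `gene_dispersion` and `cell_factor`.
#' @export
default_template_params <- function(n_genes, n_cells,
                                    mean_log = 1, mean_sdlog = 1.8,
                                    disp_log = log(0.5), disp_sdlog = 0.6,
                                    factor_sdlog = 0.4, seed = 1) {
  withr::with_seed(seed, {
    list(
      gene_mean = stats::rlnorm(n_genes, mean_log, mean_sdlog),
      gene_dispersion = stats::rlnorm(n_genes, disp_log, disp_sdlog),
      cell_factor = stats::rlnorm(n_cells, 0, factor_sdlog)
    )
  })
}

#' Simulate a two-group negative-binomial count matrix
#'
#' Draws X_ij ~ NB(mean m_ij, variance m_ij + phi_i * m_ij^2) with
#' m_ij = s_j * mu_i * f^(i flagged and j in group 2): cell-specific global
#' scaling factors s_j, gene means mu_i, and a multiplicative fold change f
#' injected into `n_de` genes chosen uniformly at random for the second of
#' two equal-size groups. phi_i = 0 falls back to Poisson sampling.
#' Deterministic given `seed`.
#'
#' @param n_cells_per_group Cells in each of the two groups (>= 2).
#' @param gene_mean,gene_dispersion Per-gene NB parameters; defaults drawn by
#'   [default_template_params()].
#' @param cell_factor Per-cell factors for the 2 * n_cells_per_group cells;
#'   drawn log-normally when `NULL`.
#' @param fold_change Fold change (>= 1) applied to flagged genes in group 2.
#' @param n_de Number of fold-changed genes (capped at the gene count).
#' @param n_genes Number of genes when parameters are not supplied.
#' @param seed Integer seed.
#' @return A list with `counts` (a labelled [count_matrix()]) and `truth`
#'   (a [simulation_truth()]).
#' @export
simulate_counts <- function(n_cells_per_group = 24,
                            gene_mean = NULL, gene_dispersion = NULL,
                            cell_factor = NULL,
                            fold_change = 2, n_de = 1000,
                            n_genes = 10000, seed = 1) {
  if (fold_change < 1) stop("fold change must be >= 1", call. = FALSE)
  if (n_cells_per_group < 2) {
    stop("need at least two cells per group", call. = FALSE)
  }
  n_cells <- 2L * as.integer(n_cells_per_group)
  if (is.null(gene_mean) || is.null(gene_dispersion)) {
    tp <- default_template_params(n_genes, n_cells, seed = child_seed(seed, 101))
    if (is.null(gene_mean)) gene_mean <- tp$gene_mean
    if (is.null(gene_dispersion)) gene_dispersion <- tp$gene_dispersion
  }
  n_genes <- length(gene_mean)
  stopifnot(length(gene_dispersion) == n_genes)
  if (is.null(cell_factor)) {
    cell_factor <- withr::with_seed(child_seed(seed, 102),
                                    stats::rlnorm(n_cells, 0, 0.4))
  }
  stopifnot(length(cell_factor) == n_cells)
  n_de <- min(as.integer(n_de), n_genes)
  group <- rep(c("group1", "group2"), each = n_cells_per_group)

  withr::with_seed(child_seed(seed, 103), {
    de_idx <- sample.int(n_genes, n_de)
    de_flags <- logical(n_genes)
    de_flags[de_idx] <- TRUE
    fold <- ifelse(de_flags, fold_change, 1)
    mu <- outer(gene_mean, cell_factor)          # genes x cells
    mu[, group == "group2"] <- mu[, group == "group2"] * fold
    counts <- matrix(0, n_genes, n_cells)
    pois <- gene_dispersion == 0
    if (any(pois)) {
      counts[pois, ] <- stats::rpois(sum(pois) * n_cells, mu[pois, ])
    }
    if (any(!pois)) {
      counts[!pois, ] <- stats::rnbinom(sum(!pois) * n_cells,
                                        mu = mu[!pois, ],
                                        size = 1 / gene_dispersion[!pois])
    }
  })
  cm <- count_matrix(counts,
                     gene_ids = sprintf("gene_%05d", seq_len(n_genes)),
                     cell_ids = sprintf("cell_%04d", seq_len(n_cells)),
                     condition = group)
  truth <- simulation_truth(gene_mean, gene_dispersion, cell_factor,
                            de_flags, fold_change, group, seed = seed)
  list(counts = cm, truth = truth)
}

#' Simulate spike-in count rows
#'
#' Models the technical (spike-in) branch of the hierarchical Poisson-Gamma
#' noise model: for each cell a latent capture effect nu_j ~ Gamma(shape
#' 1/theta, mean s_j) (nu_j = s_j exactly when theta = 0), and each spike-in
#' count ~ Poisson(nu_j * mu_i) with mu_i proportional to the known
#' concentration. The default proportionality constant puts the median
#' spike-in count near 50 at s_j = 1 so the panel is informative without
#' dominating library totals.
#'
#' @param ref A [spikein_reference()].
#' @param n_cells Number of cells.
#' @param capture_efficiency Positive per-cell capture efficiency s_j
#'   (recycled if length 1).
#' @param noise_theta Non-negative technical noise theta.
#' @param seed Integer seed.
#' @param conc_scale Proportionality constant mapping concentration to the
#'   Poisson mean at nu_j = 1; default `50 / median(concentration)`.
#' @return A list with `counts` (a [count_matrix()] of spike-in rows) and
#'   `nu` (the realized capture effects).
#' @export
simulate_spikeins <- function(ref, n_cells, capture_efficiency = 1,
                              noise_theta = 0, seed = 1,
                              conc_scale = NULL) {
  stopifnot(inherits(ref, "spikein_reference"))
  if (nrow(ref) == 0) stop("empty spike-in reference", call. = FALSE)
  s <- rep_len(as.numeric(capture_efficiency), n_cells)
  if (any(s <= 0)) stop("capture efficiencies must be positive", call. = FALSE)
  if (noise_theta < 0) stop("noise_theta must be >= 0", call. = FALSE)
  if (is.null(conc_scale)) conc_scale <- 50 / stats::median(ref$concentration)
  mu <- conc_scale * ref$concentration
  withr::with_seed(seed, {
    nu <- if (noise_theta == 0) s else
      stats::rgamma(n_cells, shape = 1 / noise_theta,
                    scale = s * noise_theta)
    counts <- matrix(stats::rpois(length(mu) * n_cells, outer(mu, nu)),
                     nrow = length(mu))
  })
  cm <- count_matrix(counts, gene_ids = ref$spikein_id,
                     cell_ids = sprintf("cell_%04d", seq_len(n_cells)),
                     is_spikein = rep(TRUE, length(mu)))
  list(counts = cm, nu = nu, spike_mean = mu)
}

#' Attach simulated group labels to a count matrix
#'
#' @param cm A [count_matrix()].
#' @param truth The matching [simulation_truth()].
#' @return The `count_matrix` with its `condition` field set. Idempotent.
#' @export
attach_labels <- function(cm, truth) {
  stopifnot(inherits(cm, "count_matrix"), inherits(truth, "simulation_truth"))
  if (length(truth$group_label) != ncol(cm$counts)) {
    stop("truth has ", length(truth$group_label), " labels but matrix has ",
         ncol(cm$counts), " cells", call. = FALSE)
  }
  cm$condition <- truth$group_label
  validate_count_matrix(cm)
}

#' Simulate a full experiment: biological genes plus a spike-in panel
#'
#' Composes [simulate_counts()] and [simulate_spikeins()] into one labelled
#' matrix that mirrors the structure of a spike-in scRNA-seq study: the
#' biological depth of cell j is phi_j * nu_j (cell size times capture) while
#' the spike-in rows see only the capture effect nu_j, since spike-ins enter
#' every lysate in equal amounts regardless of cell size. Gene lengths are
#' drawn log-normally so FPKM-based methods can run.
#'
#' @param n_cells_per_group Cells per group.
#' @param n_genes Biological genes.
#' @param fold_change,n_de Fold-change injection parameters.
#' @param spike_ref A [spikein_reference()]; default the bundled synthetic
#'   ladder from [synthetic_spike_reference()].
#' @param noise_theta Spike-in technical noise theta.
#' @param phi_sdlog Log-normal sd of the cell-size component phi_j.
#' @param capture_sdlog Log-normal sd of the mean capture efficiency s_j.
#' @param seed Integer seed.
#' @return A list with `counts` (labelled [count_matrix()], spike-ins last,
#'   gene lengths attached), `truth`, and `spike_ref`.
#' @export
simulate_experiment <- function(n_cells_per_group = 24, n_genes = 10000,
                                fold_change = 2, n_de = 1000,
                                spike_ref = synthetic_spike_reference(),
                                noise_theta = 0.3,
                                phi_sdlog = 0.4, capture_sdlog = 0.2,
                                seed = 1) {
  n_cells <- 2L * as.integer(n_cells_per_group)
  comp <- withr::with_seed(child_seed(seed, 201), {
    list(phi = stats::rlnorm(n_cells, 0, phi_sdlog),
         s = stats::rlnorm(n_cells, 0, capture_sdlog))
  })
  spikes <- simulate_spikeins(spike_ref, n_cells,
                              capture_efficiency = comp$s,
                              noise_theta = noise_theta,
                              seed = child_seed(seed, 202))
  bio_factor <- comp$phi * spikes$nu
  sim <- simulate_counts(n_cells_per_group,
                         cell_factor = bio_factor,
                         fold_change = fold_change, n_de = n_de,
                         n_genes = n_genes, seed = child_seed(seed, 203))
  lengths <- withr::with_seed(child_seed(seed, 204), {
    c(round(stats::rlnorm(n_genes, log(1500), 0.5)),
      round(stats::rlnorm(nrow(spike_ref), log(1000), 0.3)))
  })
  counts <- rbind(sim$counts$counts, spikes$counts$counts)
  cm <- count_matrix(counts,
                     gene_ids = c(sim$counts$gene_ids, spike_ref$spikein_id),
                     cell_ids = sim$counts$cell_ids,
                     is_spikein = c(rep(FALSE, n_genes),
                                    rep(TRUE, nrow(spike_ref))),
                     condition = sim$counts$condition,
                     gene_lengths = pmax(lengths, 100))
  truth <- sim$truth
  truth$capture_efficiency <- spikes$nu
  truth$phi <- comp$phi
  list(counts = cm, truth = truth, spike_ref = spike_ref)
}

#' Synthetic spike-in concentration ladder
#'
#' A serial dilution ladder (ids `SPIKE-001` ...). This is a synthetic
#' stand-in panel with the qualitative shape of commercial spike-in control
#' mixes (wide dynamic range, known concentrations), not a copy of any vendor
#' table. The default 24-point 1.5-fold ladder spans roughly four orders of
#' magnitude, so under the default count scaling the dimmest spike-ins drop
#' out in some cells, as in real panels, while the panel stays around ten
#' percent of a typical library.
#'
#' @param n Number of spike-ins.
#' @param top Concentration of the most abundant spike-in.
#' @param step Dilution factor between consecutive spike-ins.
#' @return A [spikein_reference()].
#' @export
synthetic_spike_reference <- function(n = 24, top = 15000, step = 1.5) {
  spikein_reference(sprintf("SPIKE-%03d", seq_len(n)),
                    top / step^(seq_len(n) - 1),
                    unit = "attomoles/uL (synthetic)")
}
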