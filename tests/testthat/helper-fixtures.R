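# Small deterministic fixtures built in code.

# 3 genes x 2 cells with one spike-in row; the smallest matrix that
# exercises id bookkeeping and the spike-in flag.
tiny_cm <- function() {
  count_matrix(matrix(c(5, 0, 3, 7, 2, 9), nrow = 3, byrow = TRUE),
               gene_ids = c("geneA", "geneB", "ERCC-00001"),
               cell_ids = c("c1", "c2"),
               is_spikein = c(FALSE, FALSE, TRUE))
}

# Counts that are exact per-cell multiples of one base profile: every
# global-scaling method should recover the multiples exactly.
proportional_cm <- function(n_cells = 40, n_genes = 100, seed = 99) {
  withr::with_seed(seed, {
    base <- rpois(n_genes, 40) + 1
    f <- round(exp(seq(-0.6, 0.6, length.out = n_cells)) * 8) / 8
    counts <- outer(base, rep(1, n_cells)) *
      matrix(f, n_genes, n_cells, byrow = TRUE)
    count_matrix(counts * 8)  # x8 keeps everything integral
  })
}

# Pure count-depth data: X_ij = round(depth_j * mu_i), all entries nonzero,
# per-gene log count-depth slope ~= 1.
depth_effect_cm <- function(n_genes = 60, n_cells = 30, seed = 4) {
  withr::with_seed(seed, {
    mu <- runif(n_genes, 30, 300)
    depth <- exp(seq(-0.7, 0.7, length.out = n_cells))
    counts <- round(outer(mu, depth))
    count_matrix(counts)
  })
}

# Data drawn exactly from the hierarchical Poisson-Gamma model, composed
# from the package's own generators: spike-ins via simulate_spikeins()
# (nu_j ~ Gamma(1/theta, mean s_j), counts Poisson(nu_j mu_i)), biological
# rows NB with per-cell factor phi_j * nu_j. s_j is drawn from the model's
# own Gamma(10, 10) capture prior.
basics_model_data <- function(seed, theta = 0.3, n_cells = 40,
                              n_bio = 192, n_spike = 8) {
  ref <- synthetic_spike_reference(n = n_spike, top = 2000, step = 1.6)
  pars <- withr::with_seed(child_seed(seed, 1), {
    phi <- stats::rlnorm(n_cells, 0, 0.4)
    list(
      s = stats::rgamma(n_cells, 10, 10),
      phi = phi / sum(phi) * n_cells,
      mu_b = stats::rlnorm(n_bio, 2, 1.5),
      delta = stats::rlnorm(n_bio, log(0.3), 0.5)
    )
  })
  spikes <- simulate_spikeins(ref, n_cells, capture_efficiency = pars$s,
                              noise_theta = theta,
                              seed = child_seed(seed, 2))
  bio <- simulate_counts(n_cells_per_group = n_cells / 2,
                         gene_mean = pars$mu_b,
                         gene_dispersion = pars$delta,
                         cell_factor = pars$phi * spikes$nu,
                         fold_change = 1, n_de = 0,
                         seed = child_seed(seed, 3))
  cm <- count_matrix(rbind(bio$counts$counts, spikes$counts$counts),
                     gene_ids = c(bio$counts$gene_ids, ref$spikein_id),
                     cell_ids = bio$counts$cell_ids,
                     is_spikein = c(rep(FALSE, n_bio), rep(TRUE, n_spike)))
  list(cm = cm, theta = theta, phi = pars$phi, nu = spikes$nu, s = pars$s,
       mu_b = pars$mu_b, delta = pars$delta)
}

# A small matrix with gene lengths and a noiseless linear spike-in
# calibration: log(concentration) = b0 + b1 * log(FPKM) exactly in every
# cell, achieved by back-solving the concentrations from one cell and
# making all columns proportional (FPKM is depth-invariant).
grm_linear_fixture <- function(b0 = 1, b1 = 2, n_bio = 6, n_spike = 6) {
  base_spike <- c(20, 45, 90, 180, 400, 800)[seq_len(n_spike)]
  base_bio <- c(10, 30, 60, 120, 240, 480)[seq_len(n_bio)]
  counts <- cbind(c(base_bio, base_spike), 2 * c(base_bio, base_spike))
  lens <- rep(1000, n_bio + n_spike)
  cm <- count_matrix(counts,
                     gene_ids = c(sprintf("g%02d", seq_len(n_bio)),
                                  sprintf("SPIKE-%03d", seq_len(n_spike))),
                     cell_ids = c("c1", "c2"),
                     is_spikein = c(rep(FALSE, n_bio), rep(TRUE, n_spike)),
                     gene_lengths = lens)
  fpkm1 <- compute_fpkm(cm)[, 1]
  conc <- exp(b0 + b1 * log(fpkm1[cm$is_spikein]))
  ref <- spikein_reference(cm$gene_ids[cm$is_spikein], conc)
  list(cm = cm, ref = ref, b0 = b0, b1 = b1)
}
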