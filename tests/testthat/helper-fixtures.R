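# shared fixtures: small profiles, compact render configs, and independent
# brute-force QC oracles used for oracle-equivalence tests

# a deterministic profile whose indicator values are simple sequences
make_test_profile <- function(sample_id = "s1", stage = "UNKNOWN",
                              n_rounds = 20, offset = 0,
                              batch_id = "batch1") {
  vals <- sapply(seq_along(chondro_panel()), function(i) {
    offset + i * 10 + seq_len(n_rounds)
  })
  colnames(vals) <- chondro_panel()
  sample_profile(sample_id, vals, stage = stage, batch_id = batch_id)
}

# small canvas keeps rendering fast in unit tests
small_image_config <- function(...) {
  image_config(width = 420, height = 420, ...)
}

zero_noise_config <- function(...) {
  small_image_config(gaussian_sd = 0, poisson = FALSE, ...)
}

# stage-parameter set shrunk so several cells fit a small canvas
small_cells <- function(n, stage = "P2", seed = 1) {
  p <- make_stage_params(stage, overrides = list(
    cell_diameter_mean = 16, cell_diameter_sd = 1.5,
    nucleus_diameter_mean = 8, nucleus_diameter_sd = 0.8))
  sample_cell_measurements(p, n, seed = seed)
}

# ---- independent brute-force QC oracles (explicit loops, no reuse of
# package internals) ----

bf_filter_cells_min_genes <- function(expr, min_genes) {
  keep <- logical(ncol(expr))
  for (j in seq_len(ncol(expr))) {
    n_expressed <- 0
    for (i in seq_len(nrow(expr))) {
      if (expr[i, j] > 0) n_expressed <- n_expressed + 1
    }
    keep[j] <- n_expressed >= min_genes
  }
  keep
}

bf_filter_genes_min_cells <- function(expr, min_cells) {
  keep <- logical(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    n_cells <- 0
    for (j in seq_len(ncol(expr))) {
      if (expr[i, j] > 0) n_cells <- n_cells + 1
    }
    keep[i] <- n_cells >= min_cells
  }
  keep
}

bf_qualify_totals <- function(expr, k_sd) {
  totals <- numeric(ncol(expr))
  for (j in seq_len(ncol(expr))) totals[j] <- sum(expr[, j])
  mu <- sum(totals) / length(totals)
  s <- sqrt(sum((totals - mu)^2) / (length(totals) - 1))
  totals >= mu - k_sd * s & totals <= mu + k_sd * s
}

random_count_matrix <- function(n_genes = 50, n_cells = 30, lambda = 2) {
  expr <- matrix(stats::rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  dimnames(expr) <- list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("c%03d", seq_len(n_cells)))
  expr
}
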