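# Shared in-code fixtures for the test suite. Everything is generated at
# test time; no binary data on disk.

# Small normalized matrix with named genes/cells and controllable values.
toy_norm <- function(values, genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% rownames(m) %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- cells %||% colnames(m) %||% paste0("c", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standard small EMT-continuum config used across staging tests.
small_continuum <- function(seed = 11, n_cells = 1500, n_genes = 400,
                            onsets = list(TFA = list(onset = 0.4, amplitude = 2))) {
  simulate_emt_continuum(emt_sim_config(
    n_cells = n_cells, n_genes = n_genes, tf_onsets = onsets, seed = seed))
}

# Normalized matrix + stratum assignment from a continuum simulation.
staged_sim <- function(sim) {
  counts <- filter_genes_min_cells(sim$counts, 6)
  norm <- normalize_log(counts)
  list(norm = norm, assign = stratify_by_marker(norm))
}

# Adjusted Rand index (plain implementation used as a clustering oracle).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
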