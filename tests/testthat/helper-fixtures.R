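# Deterministic fixtures shared across test files.

# two-group matrix with a filler gene making both library sizes exactly 1e6,
# so the shrunken logFC of "g1" is hand-computable
logfc_fixture <- function(counts_a = c(80, 80), counts_b = c(5, 5)) {
  n <- length(counts_a) + length(counts_b)
  m <- matrix(0, nrow = 2, ncol = n,
              dimnames = list(c("g1", "filler"), paste0("s", seq_len(n))))
  m["g1", ] <- c(counts_a, counts_b)
  m["filler", ] <- 1e6 - m["g1", ]
  cell_matrix(m, rep(c("A", "B"), c(length(counts_a), length(counts_b))))
}

# small labeled matrix with explicit per-cell-type group means (every
# sample of a type carries the group mean, so group means are exact)
means_fixture <- function(means, n_per_type = 2) {
  means <- as.matrix(means)
  if (is.null(rownames(means))) rownames(means) <- paste0("g", seq_len(nrow(means)))
  types <- colnames(means)
  counts <- means[, rep(seq_along(types), each = n_per_type), drop = FALSE]
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  cell_matrix(counts, rep(types, each = n_per_type))
}

# one row of a per-dataset signature table, for consensus fixtures
sig_row <- function(dataset_id, species, gene_id, cell_type, stat,
                    measure = "enrichment", rank = 1L) {
  tibble::tibble(dataset_id = dataset_id, species = species,
                 gene_id = gene_id, cell_type = cell_type, measure = measure,
                 stat = stat, p_value = NA_real_, adj_p = NA_real_,
                 rank = as.integer(rank))
}

# brute-force fold enrichment + hypergeometric tail, independent of the
# package implementation
fe_oracle <- function(d1, d2, universe) {
  k <- length(intersect(d1, d2))
  list(
    fe = k / (length(d1) * length(d2) / length(universe)),
    p = sum(vapply(k:min(length(d1), length(d2)), function(x) {
      dhyper(x, length(d1), length(universe) - length(d1), length(d2))
    }, numeric(1)))
  )
}

# brute-force Benjamini-Hochberg
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in rev(seq_len(n))) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

# default simulation at reduced size for fast unit tests
small_sim_cfg <- function(seed = 1, n_genes = 300, cells_per_type = 15,
                          n_markers_per_type = 10, ...) {
  sim_config(n_genes = n_genes, cells_per_type = cells_per_type,
             n_markers_per_type = n_markers_per_type, seed = seed, ...)
}

expect_no_warning <- function(expr) expect_warning(expr, regexp = NA)
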