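#' Configuration for the synthetic-data generators
#'
#' Defines a negative-binomial world with planted cell-type markers: every
#' gene has a baseline mean (log-normal across genes), each cell type owns a
#' disjoint block of marker genes whose mean is multiplied by
#' `2^marker_log2_effect` in cells of that type, library sizes vary
#' log-normally, and bulk samples mix the per-type expression profiles with
#' Dirichlet-distributed proportions.
#'
#' @param n_genes Number of genes.
#' @param cell_types Cell-type labels (markers are assigned in this order).
#' @param cells_per_type Cells simulated per type.
#' @param n_markers_per_type Planted markers per cell type (disjoint blocks).
#' @param marker_log2_effect log2 expression boost of a marker in its own
#'   type (default 4, i.e. 16-fold).
#' @param baseline_mean Median negative-binomial mean of background genes.
#' @param dispersion Negative-binomial size parameter (larger = less
#'   overdispersed; variance is `mu + mu^2/size`).
#' @param libsize_cv Coefficient of variation of the log-normal library-size
#'   factors.
#' @param dropout Optional zero-inflation probability (default 0; the
#'   signature model does not assume dropout, this is for stress tests).
#' @param n_bulk_samples Number of bulk mixture samples.
#' @param dirichlet_alpha Dirichlet concentration for mixing proportions;
#'   scalar (symmetric) or one value per cell type.
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @return A `cellsig_sim_config` list.
#' @export
sim_config <- function(n_genes = 1000,
                       cell_types = brain_cell_types,
                       cells_per_type = 50,
                       n_markers_per_type = 50,
                       marker_log2_effect = 4,
                       baseline_mean = 20,
                       dispersion = 10,
                       libsize_cv = 0.3,
                       dropout = 0,
                       n_bulk_samples = 40,
                       dirichlet_alpha = 1,
                       seed = 1L) {
  stopifnot(
    n_genes >= 1, length(cell_types) >= 2, cells_per_type >= 1,
    n_markers_per_type >= 1, marker_log2_effect >= 0, baseline_mean > 0,
    dispersion > 0, libsize_cv >= 0, dropout >= 0, dropout < 1,
    n_bulk_samples >= 1, all(dirichlet_alpha > 0)
  )
  if (n_markers_per_type * length(cell_types) > n_genes) {
    abort("n_genes too small for disjoint marker blocks")
  }
  structure(
    list(
      n_genes = n_genes, cell_types = cell_types,
      cells_per_type = cells_per_type,
      n_markers_per_type = n_markers_per_type,
      marker_log2_effect = marker_log2_effect,
      baseline_mean = baseline_mean, dispersion = dispersion,
      libsize_cv = libsize_cv, dropout = dropout,
      n_bulk_samples = n_bulk_samples, dirichlet_alpha = dirichlet_alpha,
      seed = as.integer(seed)
    ),
    class = "cellsig_sim_config"
  )
}

# gene baseline means and marker assignment, deterministic given the seed
sim_gene_model <- function(cfg) {
  k <- length(cfg$cell_types)
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  base <- rlnorm(cfg$n_genes, meanlog = log(cfg$baseline_mean), sdlog = 1)
  marker_of <- rep(NA_character_, cfg$n_genes)
  idx <- seq_len(cfg$n_markers_per_type * k)
  marker_of[idx] <- rep(cfg$cell_types, each = cfg$n_markers_per_type)
  list(gene_ids = gene_ids, base = base, marker_of = marker_of)
}

# genes x cell-types matrix of expected expression
sim_profiles <- function(cfg, gm) {
  mult <- matrix(1, cfg$n_genes, length(cfg$cell_types),
                 dimnames = list(gm$gene_ids, cfg$cell_types))
  for (ct in cfg$cell_types) {
    mult[which(gm$marker_of == ct), ct] <- 2^cfg$marker_log2_effect
  }
  mult * gm$base
}

lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a single-cell-like labeled count matrix with planted markers
#'
#' Counts are negative binomial with mean
#' `baseline * 2^effect[if marker of the cell's type] * library factor`
#' and size `dispersion`. Markers are disjoint across cell types by
#' construction. Deterministic given `(cfg, seed)`.
#'
#' @param cfg A [sim_config()].
#' @param seed Overrides `cfg$seed` when given.
#' @return A list with elements `matrix` (a [cell_matrix()]) and `truth`
#'   (list with `marker_assignments` tibble, `cell_labels`, `profiles`).
#' @export
#' @examples
#' sim <- simulate_cells(sim_config(n_genes = 50, cells_per_type = 5,
#'                                  n_markers_per_type = 3, seed = 7))
#' sim$matrix
simulate_cells <- function(cfg, seed = cfg$seed) {
  with_seed_(seed, {
    gm <- sim_gene_model(cfg)
    profiles <- sim_profiles(cfg, gm)
    k <- length(cfg$cell_types)
    n_cells <- k * cfg$cells_per_type
    labels <- rep(cfg$cell_types, each = cfg$cells_per_type)
    lib <- lognormal_factors(n_cells, cfg$libsize_cv)
    mu <- profiles[, labels, drop = FALSE] * rep(lib, each = cfg$n_genes)
    counts <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = cfg$dispersion),
      nrow = cfg$n_genes
    )
    if (cfg$dropout > 0) {
      keep <- matrix(rbinom(length(counts), 1, 1 - cfg$dropout),
                     nrow = cfg$n_genes)
      counts <- counts * keep
    }
    rownames(counts) <- gm$gene_ids
    colnames(counts) <- sprintf("C%04d", seq_len(n_cells))
    covar <- tibble(total_features = unname(colSums(counts > 0)))
    m <- cell_matrix(counts, labels, covar)
    truth <- list(
      marker_assignments = tibble(gene_id = gm$gene_ids,
                                  cell_type = gm$marker_of) |>
        filter(!is.na(.data$cell_type)),
      cell_labels = labels,
      profiles = profiles
    )
    list(matrix = m, truth = truth)
  })
}

# one Dirichlet draw per row
rdirichlet_ <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = alpha, rate = 1), ncol = k, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate bulk mixtures with known cell-type proportions
#'
#' Each bulk sample's expected expression is the convex combination of the
#' per-cell-type profiles with proportions drawn from a Dirichlet; counts
#' are negative binomial around that expectation (times a library factor).
#' With `noise = FALSE` the exact convex combination is returned.
#'
#' @inheritParams simulate_cells
#' @param profiles Optional genes x cell-types matrix of expected
#'   expression; defaults to the profile matrix implied by `cfg` (same gene
#'   model as [simulate_cells()] under the same seed).
#' @param proportions Optional samples x cell-types matrix of mixing
#'   proportions (rows on the simplex); defaults to Dirichlet draws.
#' @param noise If `FALSE`, return the noiseless expectation.
#' @return A list with `bulk` (genes x samples matrix) and `truth` (list
#'   with `proportions`, a samples x cell-types matrix).
#' @export
simulate_bulk <- function(cfg, profiles = NULL, proportions = NULL,
                          noise = TRUE, seed = cfg$seed) {
  with_seed_(seed, {
    if (is.null(profiles)) profiles <- sim_profiles(cfg, sim_gene_model(cfg))
    if (any(profiles < 0)) abort("profiles must be non-negative")
    k <- ncol(profiles)
    alpha <- rep(cfg$dirichlet_alpha, length.out = k)
    if (is.null(proportions)) {
      proportions <- rdirichlet_(cfg$n_bulk_samples, alpha)
    }
    proportions <- as.matrix(proportions)
    if (ncol(proportions) != k) abort("proportions must have one column per cell type")
    stopifnot(all(abs(rowSums(proportions) - 1) < 1e-8))
    n <- nrow(proportions)
    dimnames(proportions) <- list(sprintf("B%03d", seq_len(n)), colnames(profiles))
    expected <- profiles %*% t(proportions)
    if (noise) {
      lib <- lognormal_factors(n, cfg$libsize_cv)
      mu <- expected * rep(lib, each = nrow(expected))
      bulk <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = cfg$dispersion),
                     nrow = nrow(expected), dimnames = dimnames(expected))
    } else {
      bulk <- expected
    }
    list(bulk = bulk, truth = list(proportions = proportions))
  })
}
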