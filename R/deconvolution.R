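#' Select marker genes from a consensus signature
#'
#' Takes the top `n` specificity-ranked genes per cell type and intersects
#' them with the genes available in the bulk matrix, preserving rank order.
#'
#' @param consensus A `cellsig_consensus` tibble (typically
#'   `measure = "specificity"`), or any tibble with `gene_id`, `cell_type`
#'   and `consensus_rank` (or `rank`) columns.
#' @param n Markers per cell type (default 50).
#' @param available_genes Optional character vector restricting markers to
#'   genes measured in the bulk data.
#' @return A marker tibble: `cell_type`, `gene_id`, `rank` (1 = best,
#'   re-numbered after intersection). Genes appearing in more than one cell
#'   type's list are kept in both, with a warning.
#' @export
select_markers <- function(consensus, n = 50, available_genes = NULL) {
  stopifnot(n >= 1)
  rank_col <- if ("consensus_rank" %in% names(consensus)) "consensus_rank" else "rank"
  out <- consensus
  if (!is.null(available_genes)) {
    out <- filter(out, .data$gene_id %in% available_genes)
  }
  out <- out |>
    group_by(.data$cell_type) |>
    arrange(.data[[rank_col]], .by_group = TRUE) |>
    filter(row_number() <= n) |>
    ungroup() |>
    select("cell_type", "gene_id")
  short <- out |> dplyr::count(.data$cell_type) |> filter(.data$n < !!n)
  empty <- setdiff(unique(consensus$cell_type), unique(out$cell_type))
  if (length(empty)) {
    abort(paste0("no markers available for cell type(s): ",
                 paste(empty, collapse = ", ")))
  }
  if (nrow(short)) {
    warn(paste0("fewer than ", n, " markers available for: ",
                paste(sprintf("%s (%d)", short$cell_type, short$n),
                      collapse = ", ")))
  }
  shared <- out |> dplyr::count(.data$gene_id) |> filter(.data$n > 1)
  if (nrow(shared)) {
    warn(paste0("markers assigned to multiple cell types: ",
                paste(shared$gene_id, collapse = ", ")))
  }
  out |>
    group_by(.data$cell_type) |>
    mutate(rank = row_number()) |>
    ungroup()
}

# SPV for one marker submatrix: first right singular vector, sign-corrected
spv_one <- function(x, scale_genes = TRUE) {
  if (scale_genes) {
    sds <- apply(x, 1, sd)
    if (all(sds == 0)) abort("degenerate markers: constant submatrix")
    if (any(sds == 0)) {
      warn(sprintf("%d constant marker gene(s) dropped before scaling",
                   sum(sds == 0)))
      x <- x[sds > 0, , drop = FALSE]
    }
    x <- t(scale(t(x)))
  } else if (all(apply(x, 1, sd) == 0)) {
    abort("degenerate markers: constant submatrix")
  }
  v <- svd(x, nu = 0, nv = 1)$v[, 1]
  ref <- colMeans(x)
  s <- suppressWarnings(cor(v, ref))
  flipped <- FALSE
  if (!is.na(s) && s < 0) {
    v <- -v
    flipped <- TRUE
  }
  list(spv = v, flipped = flipped, genes = rownames(x))
}

#' Estimate surrogate cell-type proportion variables from bulk expression
#'
#' For each cell type, the bulk matrix is subset to that type's marker
#' genes, each gene is (optionally) centered and unit-variance scaled
#' across samples, and the surrogate proportion variable (SPV) is the first
#' right singular vector of the marker submatrix — the CellCODE-style SVD
#' estimator. The SVD sign ambiguity is fixed so the SPV correlates
#' positively with the per-sample mean of the (scaled) marker rows. SPVs
#' are relative within a cell type across samples; they are not absolute
#' fractions and no simplex constraint is imposed.
#'
#' @param bulk Numeric genes x samples matrix, already normalized and
#'   preferably log-scale (a warning is issued when values look like raw
#'   counts).
#' @param markers Marker tibble from [select_markers()] or
#'   [read_markers()].
#' @param n_markers Top markers per cell type to use (default 50).
#' @param scale_genes Center/scale each gene across samples before the SVD
#'   (default `TRUE`).
#' @return A `cellsig_spv` object: list with `spv` (samples x cell types
#'   matrix, each column unit Euclidean norm), `markers_used` (named list),
#'   `sign_flipped` (named logical), `scale_genes`.
#' @export
estimate_proportions <- function(bulk, markers, n_markers = 50,
                                 scale_genes = TRUE) {
  stopifnot(is.matrix(bulk), !is.null(rownames(bulk)))
  if (ncol(bulk) < 3) abort("need at least 3 bulk samples")
  if (all(bulk == round(bulk)) && max(bulk) > 1e4) {
    warn("bulk values look like raw counts; normalized log-scale input is recommended")
  }
  types <- unique(markers$cell_type)
  fits <- lapply(types, function(ct) {
    g <- markers |>
      filter(.data$cell_type == ct) |>
      arrange(.data$rank) |>
      filter(row_number() <= n_markers) |>
      pull("gene_id")
    g <- g[g %in% rownames(bulk)]
    if (length(g) < 2) {
      abort(sprintf("fewer than 2 markers of '%s' present in the bulk matrix", ct))
    }
    spv_one(bulk[g, , drop = FALSE], scale_genes)
  })
  spv <- vapply(fits, `[[`, numeric(ncol(bulk)), "spv")
  dimnames(spv) <- list(colnames(bulk), types)
  structure(
    list(spv = spv,
         markers_used = setNames(lapply(fits, `[[`, "genes"), types),
         sign_flipped = setNames(vapply(fits, `[[`, logical(1), "flipped"), types),
         scale_genes = scale_genes),
    class = "cellsig_spv"
  )
}

#' @export
print.cellsig_spv <- function(x, ...) {
  cat(sprintf("<cellsig_spv> %d samples x %d cell types\n",
              nrow(x$spv), ncol(x$spv)))
  cat("markers used:",
      paste(sprintf("%s (%d)", names(x$markers_used),
                    lengths(x$markers_used)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.cellsig_spv <- function(x, ...) {
  as_tibble(as.data.frame.table(x$spv, stringsAsFactors = FALSE)) |>
    setNames(c("sample_id", "cell_type", "spv"))
}

#' @export
glance.cellsig_spv <- function(x, ...) {
  tibble(n_samples = nrow(x$spv), n_cell_types = ncol(x$spv),
         n_markers = sum(lengths(x$markers_used)),
         n_sign_flipped = sum(x$sign_flipped))
}

#' Correlation of cumulative-marker SPV estimates with a reference
#'
#' For n = 2..`max_n`, estimates the SPV from the top n markers of one cell
#' type and reports its Spearman correlation with a per-sample reference
#' (e.g. an immunohistochemistry quantification or simulated truth), along
#' with the individual per-marker correlations.
#'
#' @inheritParams estimate_proportions
#' @param reference Numeric vector, one value per bulk sample.
#' @param cell_type Which cell type's markers to use (required when
#'   `markers` covers several).
#' @param max_n Largest marker count (default: all available markers).
#' @return A `cellsig_curve` object: list with `curve` (tibble
#'   `n_markers`, `rho`), `gene_cor` (tibble `gene_id`, `rank`, `rho`) and
#'   `cell_type`. Correlations are `NA` (with one warning) when the
#'   reference is constant.
#' @export
cumulative_marker_curve <- function(bulk, markers, reference,
                                    cell_type = NULL, max_n = NULL,
                                    scale_genes = TRUE) {
  types <- unique(markers$cell_type)
  if (is.null(cell_type)) {
    if (length(types) > 1) abort("markers cover several cell types; give `cell_type`")
    cell_type <- types
  }
  mk <- markers |>
    filter(.data$cell_type == !!cell_type) |>
    arrange(.data$rank) |>
    filter(.data$gene_id %in% rownames(bulk))
  if (length(reference) != ncol(bulk)) {
    abort("`reference` must have one value per bulk sample")
  }
  const_ref <- sd(reference) == 0
  if (const_ref) warn("reference is constant; correlations are undefined (NA)")
  if (is.null(max_n)) max_n <- nrow(mk)
  if (max_n > nrow(mk)) abort("max_n exceeds the available markers")
  rho <- vapply(2:max_n, function(n) {
    est <- estimate_proportions(bulk, mk[seq_len(n), ], n_markers = n,
                                scale_genes = scale_genes)
    if (const_ref) NA_real_ else
      suppressWarnings(cor(est$spv[, 1], reference, method = "spearman"))
  }, numeric(1))
  gene_cor <- mutate(
    mk[seq_len(max_n), c("gene_id", "rank")],
    rho = vapply(.data$gene_id, function(g) {
      if (const_ref) NA_real_ else
        suppressWarnings(cor(bulk[g, ], reference, method = "spearman"))
    }, numeric(1))
  )
  structure(
    list(curve = tibble(n_markers = 2:max_n, rho = rho),
         gene_cor = gene_cor, cell_type = cell_type),
    class = "cellsig_curve"
  )
}

#' @export
tidy.cellsig_curve <- function(x, ...) x$curve

#' Residualize surrogate proportions out of a bulk matrix
#'
#' Regresses each gene's expression on all SPV columns (plus an intercept)
#' by ordinary least squares and returns the residuals with the gene's mean
#' added back — removing cell-composition effects while preserving each
#' gene's location. After adjustment every gene is uncorrelated with every
#' SPV.
#'
#' @param bulk Numeric genes x samples matrix (the matrix the SPVs were
#'   estimated on).
#' @param est A `cellsig_spv` from [estimate_proportions()].
#' @return An adjusted matrix with the dimensions of `bulk`.
#' @export
adjust_expression <- function(bulk, est) {
  spv <- est$spv
  if (nrow(spv) != ncol(bulk) ||
      !identical(rownames(spv), colnames(bulk))) {
    abort("`est` was not computed on the samples of `bulk`")
  }
  if (ncol(bulk) <= ncol(spv) + 1) abort("insufficient degrees of freedom")
  x <- cbind(1, spv)
  q <- qr(x)
  resid <- t(qr.resid(q, t(bulk)))
  out <- resid + rowMeans(bulk)
  dimnames(out) <- dimnames(bulk)
  out
}
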