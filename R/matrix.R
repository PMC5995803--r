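#' Labeled count matrix
#'
#' Bundles an integer gene-by-sample count matrix with one cell-type label
#' per sample and optional per-sample covariates (e.g. total detected
#' features). This is the input to signature derivation.
#'
#' @param counts Numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names. Counts must be non-negative.
#' @param cell_type Character vector of cell-type labels, one per sample
#'   (column). Conventionally from [brain_cell_types], but free-form labels
#'   are allowed.
#' @param covariates Optional data frame of per-sample covariates with one
#'   row per sample (numeric or categorical).
#'
#' @return An object of class `cellsig_matrix`: a list with elements
#'   `counts`, `cell_type` and `covariates`.
#' @export
#' @examples
#' counts <- matrix(rpois(12, 5), 3, 4,
#'   dimnames = list(c("AQP4", "PLP1", "CCL4"), paste0("s", 1:4)))
#' cell_matrix(counts, c("AST", "AST", "MOL", "MOL"))
cell_matrix <- function(counts, cell_type, covariates = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix (genes x samples).")
  }
  if (any(counts < 0)) abort("`counts` contains negative values.")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have row names (genes) and column names (samples).")
  }
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup)) {
    abort(paste0("duplicate gene ids: ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(colnames(counts))) abort("sample ids must be unique.")
  cell_type <- as.character(cell_type)
  if (length(cell_type) != ncol(counts)) {
    abort("`cell_type` must have one label per sample.")
  }
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    if (nrow(covariates) != ncol(counts)) {
      abort("`covariates` must have one row per sample.")
    }
  }
  structure(
    list(counts = counts, cell_type = cell_type, covariates = covariates),
    class = "cellsig_matrix"
  )
}

#' @export
print.cellsig_matrix <- function(x, ...) {
  tab <- table(x$cell_type)
  cat(sprintf(
    "<cellsig_matrix> %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)
  ))
  cat("cell types:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$covariates)) {
    cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.cellsig_matrix <- function(x) dim(x$counts)

# subset samples by index/logical, keeping labels and covariates aligned
subset_samples <- function(m, idx) {
  cell_matrix(
    m$counts[, idx, drop = FALSE],
    m$cell_type[idx],
    if (!is.null(m$covariates)) m$covariates[idx, , drop = FALSE]
  )
}

subset_genes <- function(m, idx) {
  m$counts <- m$counts[idx, , drop = FALSE]
  m
}

#' Reference cell set for a target cell type
#'
#' The reference set is every other cell type present, except that mature
#' oligodendrocytes (MOL) and oligodendrocyte precursors (OPC) are excluded
#' from each other's reference: their expression profiles are too similar
#' for the contrast to be meaningful.
#'
#' @param target Target cell type label.
#' @param cell_types Character vector of available cell types (defaults to
#'   the six major brain cell types).
#' @return Character vector of reference cell types.
#' @export
#' @examples
#' reference_set("MOL")  # excludes OPC
#' reference_set("AST")
reference_set <- function(target, cell_types = brain_cell_types) {
  cell_types <- unique(cell_types)
  if (!target %in% cell_types) {
    abort(sprintf("target cell type '%s' not among available types", target))
  }
  ref <- setdiff(cell_types, target)
  if (target == "MOL") ref <- setdiff(ref, "OPC")
  if (target == "OPC") ref <- setdiff(ref, "MOL")
  ref
}

# validate a target/reference pair against the exclusion rule
check_reference_set <- function(target, reference) {
  if (target %in% reference) abort("target cell type cannot be in its own reference set.")
  if (target == "MOL" && "OPC" %in% reference) {
    abort("OPC must be excluded from the reference set when MOL is the target.")
  }
  if (target == "OPC" && "MOL" %in% reference) {
    abort("MOL must be excluded from the reference set when OPC is the target.")
  }
  invisible(TRUE)
}

#' @export
glance.cellsig_matrix <- function(x, ...) {
  tibble(
    n_genes = nrow(x$counts),
    n_samples = ncol(x$counts),
    n_cell_types = length(unique(x$cell_type)),
    median_lib_size = stats::median(colSums(x$counts))
  )
}

#' @export
tidy.cellsig_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, stringsAsFactors = FALSE)) |>
    setNames(c("gene_id", "sample_id", "count")) |>
    left_join(
      tibble(sample_id = colnames(x$counts), cell_type = x$cell_type),
      by = "sample_id"
    )
}
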