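#' Combine per-dataset signature tables
#'
#' Stacks signature tibbles from several datasets, tagging each row with
#' the dataset id and species, and harmonizing gene symbols so human and
#' mouse tables intersect by case-folded symbol.
#'
#' @param ... Named arguments or a single list: each element a signature
#'   tibble (from [cell_signatures()] and friends).
#' @param species Character vector, one of `"human"`/`"mouse"` per dataset.
#' @param harmonize Symbol harmonization mode passed to
#'   [harmonize_symbols()] (default `"uppercase"`).
#' @return A long tibble with `dataset_id` and `species` columns prepended;
#'   input to [build_consensus()].
#' @export
dataset_signatures <- function(..., species, harmonize = "uppercase") {
  tables <- list(...)
  if (length(tables) == 1 && is.list(tables[[1]]) &&
      !inherits(tables[[1]], "data.frame")) {
    tables <- tables[[1]]
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort("every dataset table must be named (the dataset id)")
  }
  if (anyDuplicated(names(tables))) abort("dataset ids must be unique")
  species <- rep(species, length.out = length(tables))
  if (!all(species %in% c("human", "mouse"))) {
    abort("species must be 'human' or 'mouse'")
  }
  purrr::imap_dfr(tables, function(tbl, id) {
    tbl$gene_id <- as.character(
      harmonize_symbols(tbl$gene_id, mode = harmonize))
    mutate(tbl, dataset_id = id,
           species = species[[match(id, names(tables))]],
           .before = 1)
  })
}

#' Cross-dataset consensus signature
#'
#' Aggregates one cell type and measure across datasets. For enrichment and
#' specificity the aggregated statistic is the median (or mean) of the
#' per-dataset log2 fold changes over the datasets containing the gene; for
#' absolute expression it is the grand median of the per-dataset
#' within-cell-type expression ranks. A gene symbol is kept only if present
#' in strictly more than half of the in-scope datasets (those containing
#' the cell type), and — for the combined human+mouse scope — in at least
#' one human and one mouse dataset.
#'
#' @param sigs Long signature tibble from [dataset_signatures()].
#' @param measure One of `"enrichment"`, `"specificity"`, `"expression"`.
#' @param cell_type Cell type to aggregate.
#' @param scope `"combined"` (default), `"human"` or `"mouse"`.
#' @param agg `"median"` (default) or `"mean"` aggregation of log2 fold
#'   changes. Expression always aggregates ranks by the grand median.
#' @return A `cellsig_consensus` tibble: `gene_id`, `cell_type`, `measure`,
#'   `agg_stat`, `n_present`, `consensus_rank`. Ordering is by `agg_stat`
#'   (descending for fold changes, ascending for expression ranks), ties
#'   broken by (`n_present` desc, `gene_id` asc).
#' @export
build_consensus <- function(sigs, measure, cell_type,
                            scope = c("combined", "human", "mouse"),
                            agg = c("median", "mean")) {
  scope <- match.arg(scope)
  agg <- match.arg(agg)
  measure <- match.arg(measure, c("enrichment", "specificity", "expression"))
  ct <- cell_type
  rows <- filter(sigs, .data$measure == !!measure, .data$cell_type == ct)
  if (scope != "combined") rows <- filter(rows, .data$species == scope)
  if (!nrow(rows)) {
    abort(sprintf("cell type '%s' absent from all in-scope datasets", ct))
  }
  in_scope <- distinct(rows, .data$dataset_id, .data$species)
  n_ds <- nrow(in_scope)
  is_expr <- measure == "expression"
  # expression aggregates ranks by the grand median regardless of `agg`
  agg_fun <- if (agg == "median" || is_expr) stats::median else mean
  value_col <- if (is_expr) "rank" else "stat"
  per_gene <- rows |>
    group_by(.data$gene_id) |>
    summarise(
      agg_stat = agg_fun(.data[[value_col]]),
      n_present = dplyr::n_distinct(.data$dataset_id),
      n_human = dplyr::n_distinct(.data$dataset_id[.data$species == "human"]),
      n_mouse = dplyr::n_distinct(.data$dataset_id[.data$species == "mouse"]),
      .groups = "drop"
    ) |>
    filter(.data$n_present > n_ds / 2)
  # the cross-species rule can only bind when both species are in scope
  if (scope == "combined" && all(c("human", "mouse") %in% in_scope$species)) {
    per_gene <- filter(per_gene, .data$n_human >= 1, .data$n_mouse >= 1)
  }
  if (!nrow(per_gene)) {
    abort(sprintf("no genes satisfy the presence rules for '%s'", ct))
  }
  descending <- measure != "expression"
  per_gene <- per_gene |>
    arrange(
      if (descending) dplyr::desc(.data$agg_stat) else .data$agg_stat,
      dplyr::desc(.data$n_present), .data$gene_id
    ) |>
    mutate(cell_type = ct, measure = !!measure,
           consensus_rank = row_number()) |>
    select("gene_id", "cell_type", "measure", "agg_stat", "n_present",
           "consensus_rank")
  class(per_gene) <- c("cellsig_consensus", class(per_gene))
  per_gene
}

#' Top genes of a consensus signature
#'
#' @param consensus A `cellsig_consensus` tibble.
#' @param n Number of genes (default 1000). If fewer are available, all are
#'   returned with a warning.
#' @return Character vector of gene ids in consensus-rank order.
#' @export
top_genes <- function(consensus, n = 1000) {
  stopifnot(n >= 1)
  if (n > nrow(consensus)) {
    warn(sprintf("requested %d genes but only %d available", n, nrow(consensus)))
    n <- nrow(consensus)
  }
  arrange(consensus, .data$consensus_rank)$gene_id[seq_len(n)]
}
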