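#' Read and validate a pipeline run configuration
#'
#' The configuration is YAML with blocks for datasets (id, species, path,
#' optional annotation), optional `gene_lengths`, `bulk` and `markers`
#' paths, `measures`, optional `cell_types` and `reference_sets`
#' overrides, `normalization`, `consensus` and `deconvolution` parameter
#' blocks, a `seed` and an `out_dir`. Validation problems (unknown keys,
#' missing files, reference sets violating the MOL/OPC mutual-exclusion
#' rule) are aggregated and reported together.
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @return A validated `cellsig_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  allowed <- c("datasets", "gene_lengths", "bulk", "markers", "measures",
               "cell_types", "reference_sets", "normalization", "consensus",
               "deconvolution", "covariates", "seed", "out_dir")
  errors <- character()
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown config keys: ",
                               paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$out_dir)) errors <- c(errors, "out_dir is required")
  has_datasets <- !is.null(cfg$datasets) && length(cfg$datasets) >= 1
  if (!has_datasets && is.null(cfg$markers)) {
    errors <- c(errors, "need at least one dataset, or a markers file for bulk-only mode")
  }
  for (d in cfg$datasets) {
    for (k in c("id", "species", "path")) {
      if (is.null(d[[k]])) errors <- c(errors, paste0("dataset missing field: ", k))
    }
    if (!is.null(d$path) && !file.exists(d$path)) {
      errors <- c(errors, paste0("dataset file not found: ", d$path))
    }
  }
  for (k in c("gene_lengths", "bulk", "markers")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      errors <- c(errors, paste0(k, " file not found: ", cfg[[k]]))
    }
  }
  if (!is.null(cfg$reference_sets)) {
    for (tgt in names(cfg$reference_sets)) {
      ref <- cfg$reference_sets[[tgt]]
      msg <- tryCatch({ check_reference_set(tgt, ref); NULL },
                      error = function(e) conditionMessage(e))
      if (!is.null(msg)) errors <- c(errors, paste0("reference_sets: ", msg))
    }
  }
  if (length(errors)) {
    abort(paste0("invalid configuration:\n", paste0("- ", errors, collapse = "\n")))
  }
  cfg$measures <- cfg$measures %||% c("enrichment", "specificity", "expression")
  np <- cfg$normalization %||% list()
  cfg$normalization <- norm_params(np$prior_count %||% 10,
                                   np$min_mean_count %||% 5)
  cn <- cfg$consensus %||% list()
  cfg$consensus <- list(scope = cn$scope %||% "combined",
                        agg = cn$agg %||% "median")
  dc <- cfg$deconvolution %||% list()
  cfg$deconvolution <- list(n_markers = dc$n_markers %||% 50,
                            scale_genes = dc$scale_genes %||% TRUE)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "cellsig_config")
}

log_line <- function(lines, ...) c(lines, sprintf(...))

#' Derive and write signature tables for every configured dataset
#'
#' For each dataset, computes the configured measures for every cell type
#' and writes one TSV per (dataset, cell type, measure), with a `flagged`
#' volcano column on the tested measures, plus a run log echoing every
#' threshold applied (expression filter, shrinkage prior, fold-change and
#' adjusted-p cutoffs) and the per-dataset filter counts.
#'
#' @param config A `cellsig_config` (from [read_run_config()]) or a path
#'   to one.
#' @return Invisibly, a named list of per-dataset signature tibbles.
#' @export
run_signatures <- function(config) {
  cfg <- if (inherits(config, "cellsig_config")) config else read_run_config(config)
  dir.create(file.path(cfg$out_dir, "signatures"), recursive = TRUE,
             showWarnings = FALSE)
  lengths_tbl <- if (!is.null(cfg$gene_lengths)) read_gene_lengths(cfg$gene_lengths)
  log <- character()
  log <- log_line(log, "cellsig run_signatures")
  log <- log_line(log, "seed: %d", cfg$seed)
  log <- log_line(log, "min_mean_count: %g (mean raw counts in >=1 cell type)",
                  cfg$normalization$min_mean_count)
  log <- log_line(log, "prior_count: %g (shrinkage pseudocount)",
                  cfg$normalization$prior_count)
  log <- log_line(log, "volcano thresholds: adjusted p < 0.05, fold change >= 4")
  results <- list()
  for (d in cfg$datasets) {
    m <- suppressMessages(read_matrix(d$path, annotation = d$annotation))
    n_before <- nrow(m$counts)
    sig <- withCallingHandlers(
      cell_signatures(
        m, lengths = lengths_tbl, measures = cfg$measures,
        targets = cfg$cell_types, params = cfg$normalization,
        covariates = cfg$covariates
      ),
      message = function(c) invokeRestart("muffleMessage")
    )
    n_after <- length(unique(sig$gene_id))
    log <- log_line(log, "dataset %s: %d samples, %d genes, %d after filter",
                    d$id, ncol(m$counts), n_before, n_after)
    sig <- volcano_flags(sig)
    for (ct in unique(sig$cell_type)) {
      for (ms in unique(sig$measure)) {
        rows <- filter(sig, .data$cell_type == ct, .data$measure == ms)
        if (nrow(rows)) {
          write_signature(rows, file.path(
            cfg$out_dir, "signatures", sprintf("%s_%s_%s.tsv", d$id, ct, ms)))
        }
      }
    }
    results[[d$id]] <- sig
  }
  writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  invisible(results)
}

run_stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full signature-to-deconvolution pipeline
#'
#' Chains signature derivation, cross-dataset consensus, marker selection,
#' surrogate-proportion estimation on a bulk matrix, and residual
#' adjustment. Every stage's output is written under `out_dir` and
#' re-loadable; a manifest records the inputs, parameters and seed needed
#' to reproduce the run. With a `markers` file configured and no datasets,
#' the derivation stages are skipped (bulk-only mode).
#'
#' @inheritParams run_signatures
#' @return Invisibly, a list with the stage outputs that were produced
#'   (`signatures`, `consensus`, `markers`, `proportions`, `adjusted`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "cellsig_config")) config else read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  if (!is.null(cfg$markers)) {
    markers <- run_stage("markers", read_markers(cfg$markers))
  } else {
    out$signatures <- run_stage("signatures", run_signatures(cfg))
    long <- dataset_signatures(
      out$signatures,
      species = vapply(cfg$datasets, `[[`, character(1), "species")
    )
    cons <- run_stage("consensus", {
      combos <- distinct(long, .data$cell_type, .data$measure)
      purrr::pmap_dfr(combos, function(cell_type, measure) {
        build_consensus(long, measure, cell_type,
                        scope = cfg$consensus$scope, agg = cfg$consensus$agg)
      })
    })
    write_signature(cons, file.path(cfg$out_dir, "consensus.tsv"))
    out$consensus <- cons
    markers <- run_stage("markers", {
      spec <- filter(cons, .data$measure == "specificity")
      if (!nrow(spec)) spec <- filter(cons, .data$measure == "enrichment")
      select_markers(spec, n = cfg$deconvolution$n_markers)
    })
  }
  write_signature(markers, file.path(cfg$out_dir, "markers.tsv"))
  out$markers <- markers
  if (!is.null(cfg$bulk)) {
    bulk_m <- run_stage("bulk", suppressMessages(read_matrix(cfg$bulk)))
    bulk <- bulk_m$counts
    est <- run_stage("estimate_proportions", {
      suppressWarnings(estimate_proportions(
        bulk, markers, n_markers = cfg$deconvolution$n_markers,
        scale_genes = cfg$deconvolution$scale_genes))
    })
    write_signature(tidy(est), file.path(cfg$out_dir, "spv.tsv"))
    out$proportions <- est
    adj <- run_stage("adjust_expression", adjust_expression(bulk, est))
    write_signature(
      tibble::rownames_to_column(as.data.frame(adj), "gene_id"),
      file.path(cfg$out_dir, "adjusted.tsv"))
    out$adjusted <- adj
  }
  manifest <- list(
    tool = "cellsig",
    version = as.character(utils::packageVersion("cellsig")),
    seed = cfg$seed,
    inputs = list(
      datasets = lapply(cfg$datasets, function(d) d[c("id", "species", "path")]),
      gene_lengths = cfg$gene_lengths, bulk = cfg$bulk, markers = cfg$markers
    ),
    parameters = list(
      measures = cfg$measures,
      normalization = cfg$normalization[c("prior_count", "min_mean_count")],
      consensus = cfg$consensus,
      deconvolution = cfg$deconvolution
    )
  )
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(out)
}
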