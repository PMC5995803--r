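#' Read a gene-by-sample count matrix
#'
#' Reads TSV/CSV (first column `gene_id`, header row of sample ids) or
#' MatrixMarket coordinate format (`<stem>.mtx` with companion
#' `<stem>.rows.txt` and `<stem>.cols.txt` name files). Sample cell-type
#' labels are taken from a sidecar annotation TSV with mandatory columns
#' `sample_id` and `cell_type`; extra columns become covariates. By default
#' the sidecar is looked up at `<stem>.samples.tsv`.
#'
#' @param path Path to the matrix file.
#' @param format One of `"auto"`, `"tsv"`, `"csv"`, `"mtx"`. `"auto"` picks
#'   by file extension.
#' @param annotation Optional path to the sample annotation sidecar. If
#'   `NULL`, `<stem>.samples.tsv` is used when present; otherwise labels are
#'   set to `NA` with a warning.
#' @return A [cell_matrix()] object.
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        annotation = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
      abort(sprintf("cannot infer format from extension '.%s'", ext))
    )
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    rows_path <- paste0(stem, ".rows.txt")
    cols_path <- paste0(stem, ".cols.txt")
    for (p in c(rows_path, cols_path)) {
      if (!file.exists(p)) abort(sprintf("companion name file not found: %s", p))
    }
    mm <- tryCatch(Matrix::readMM(path), error = function(e) {
      abort(sprintf("malformed MatrixMarket file %s: %s", path, conditionMessage(e)))
    })
    counts <- as.matrix(mm)
    rownames(counts) <- readLines(rows_path)
    colnames(counts) <- readLines(cols_path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                 stringsAsFactors = FALSE),
      error = function(e) {
        abort(sprintf("parse error in %s: %s", path, conditionMessage(e)))
      }
    )
    if (ncol(df) < 2) abort(sprintf("parse error in %s: fewer than 2 columns", path))
    gene_ids <- as.character(df[[1]])
    vals <- df[, -1, drop = FALSE]
    bad <- which(!vapply(vals, is.numeric, logical(1)))
    if (length(bad)) {
      # locate the first offending line for the error message
      abort(sprintf(
        "parse error in %s: non-numeric values in column '%s' (e.g. data line %d)",
        path, names(vals)[bad[1]],
        which(is.na(suppressWarnings(as.numeric(vals[[bad[1]]]))))[1]
      ))
    }
    counts <- as.matrix(vals)
    rownames(counts) <- gene_ids
  }
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup)) {
    abort(paste0("duplicate gene ids in ", path, ": ", paste(dup, collapse = ", ")))
  }

  stem <- sub("\\.(tsv|txt|csv|mtx)$", "", path)
  if (is.null(annotation)) {
    cand <- paste0(stem, ".samples.tsv")
    if (file.exists(cand)) annotation <- cand
  }
  if (is.null(annotation)) {
    warn(sprintf("no sample annotation sidecar for %s; cell types set to NA", path))
    ann <- tibble(sample_id = colnames(counts), cell_type = NA_character_)
  } else {
    ann <- as_tibble(read.delim(annotation, sep = "\t", header = TRUE,
                                check.names = FALSE, stringsAsFactors = FALSE))
    if (!all(c("sample_id", "cell_type") %in% names(ann))) {
      abort(sprintf("annotation %s must have columns sample_id and cell_type", annotation))
    }
    missing <- setdiff(colnames(counts), ann$sample_id)
    if (length(missing)) {
      abort(sprintf("annotation %s lacks samples: %s", annotation,
                    paste(missing, collapse = ", ")))
    }
    ann <- ann[match(colnames(counts), ann$sample_id), ]
  }
  covars <- ann[setdiff(names(ann), c("sample_id", "cell_type"))]
  inform(sprintf("read %d genes x %d samples from %s",
                 nrow(counts), ncol(counts), path))
  cell_matrix(counts, ann$cell_type,
              if (ncol(covars)) covars else NULL)
}

#' Write a labeled count matrix
#'
#' Writes the counts in the chosen format plus the `<stem>.samples.tsv`
#' annotation sidecar (sample_id, cell_type, covariates). Integer counts
#' round-trip exactly through [read_matrix()].
#'
#' @param m A [cell_matrix()] object.
#' @param path Output path for the matrix file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  counts <- m$counts
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(stem, ".rows.txt"))
    writeLines(colnames(counts), paste0(stem, ".cols.txt"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    stem <- sub("\\.(tsv|txt|csv)$", "", path)
  }
  ann <- data.frame(sample_id = colnames(counts), cell_type = m$cell_type,
                    check.names = FALSE)
  if (!is.null(m$covariates)) ann <- cbind(ann, as.data.frame(m$covariates))
  write.table(ann, paste0(stem, ".samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a gene-length table
#'
#' TSV with columns `gene_id` and `length_bp`; lengths are used to convert
#' quantile-normalized counts to RPKM.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene_id`, `length_bp`.
#' @export
read_gene_lengths <- function(path) {
  df <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  if (!all(c("gene_id", "length_bp") %in% names(df))) {
    abort("gene length table must have columns gene_id and length_bp")
  }
  if (any(df$length_bp < 1)) abort("gene lengths must be >= 1 bp")
  if (anyDuplicated(df$gene_id)) abort("gene length table has duplicated gene_id")
  df
}

#' Harmonize gene symbols across species
#'
#' Human and mouse tables are intersected by symbol; mouse symbols are
#' title-case (e.g. `Aqp4`) where human symbols are upper-case (`AQP4`), so
#' `mode = "uppercase"` case-folds symbols to make them comparable.
#' Symbols that collide after folding are reported via a warning and in the
#' `"collisions"` attribute; they are not silently merged.
#'
#' @param gene_ids Character vector of gene symbols.
#' @param mode `"uppercase"` to case-fold, `"none"` for identity.
#' @return Character vector of mapped symbols, with attribute `collisions`
#'   (symbols that became duplicated by the mapping; empty if none).
#' @export
#' @examples
#' harmonize_symbols(c("Aqp4", "Plp1"))
harmonize_symbols <- function(gene_ids, mode = c("uppercase", "none")) {
  mode <- match.arg(mode)
  out <- if (mode == "uppercase") toupper(gene_ids) else gene_ids
  collided <- setdiff(
    unique(out[duplicated(out)]),
    unique(gene_ids[duplicated(gene_ids)])
  )
  if (length(collided)) {
    warn(paste0("symbol collisions after harmonization: ",
                paste(collided, collapse = ", ")))
  }
  attr(out, "collisions") <- collided
  out
}

#' Harmonize the gene ids of a labeled count matrix
#'
#' Applies [harmonize_symbols()] to the row names; when two rows collide
#' onto one symbol, the first occurrence is kept and the rest dropped (the
#' collision is warned about by [harmonize_symbols()]).
#'
#' @inheritParams write_matrix
#' @inheritParams harmonize_symbols
#' @return A [cell_matrix()] with harmonized, unique gene ids.
#' @export
harmonize_genes <- function(m, mode = c("uppercase", "none")) {
  mapped <- harmonize_symbols(rownames(m$counts), mode)
  keep <- !duplicated(mapped)
  m <- subset_genes(m, keep)
  rownames(m$counts) <- mapped[keep]
  m
}

#' Read or write gene sets in GMT format
#'
#' GMT is the standard tab-separated gene-set format: one set per line with
#' fields name, description, then member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    abort(sprintf("malformed GMT line %d in %s (need name, description, >=1 gene)",
                  bad[1], path))
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Optional character vector of per-set descriptions.
#' @return `write_gmt()`: `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = names(sets)) {
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a marker-list table
#'
#' Tab-separated with columns `gene` (or `gene_id`), `cell_type` and
#' optionally `rank` (1 = best marker; defaults to file order within cell
#' type).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `cell_type`, `gene_id`, `rank`.
#' @export
read_markers <- function(path) {
  df <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  if ("gene" %in% names(df) && !"gene_id" %in% names(df)) {
    df <- rename(df, gene_id = "gene")
  }
  if (!all(c("gene_id", "cell_type") %in% names(df))) {
    abort("marker table must have columns gene (or gene_id) and cell_type")
  }
  if (!"rank" %in% names(df)) {
    df <- df |> group_by(.data$cell_type) |> mutate(rank = row_number()) |> ungroup()
  }
  df |> select("cell_type", "gene_id", "rank")
}

#' Write a signature or consensus table as TSV
#'
#' @param tbl A tibble (e.g. from [cell_signatures()] or [build_consensus()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(tbl, path) {
  write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
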