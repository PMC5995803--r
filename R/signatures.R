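#' Normalization and shrinkage parameters
#'
#' `prior_count` controls the shrinkage of log2 fold changes: a pseudocount
#' proportional to each sample's relative library size is added to every
#' observation before computing group-mean CPM, pulling fold changes of
#' low-expression genes toward zero. `min_mean_count` is the expression
#' filter: a gene is kept only if some cell type's mean raw count reaches
#' it.
#'
#' @param prior_count Non-negative shrinkage pseudocount (default 10).
#' @param min_mean_count Non-negative expression filter threshold
#'   (default 5 mean raw counts in at least one cell type).
#' @return A `cellsig_norm_params` list. Log base is fixed at 2.
#' @export
norm_params <- function(prior_count = 10, min_mean_count = 5) {
  stopifnot(prior_count >= 0, min_mean_count >= 0)
  structure(list(prior_count = prior_count, min_mean_count = min_mean_count,
                 log_base = 2),
            class = "cellsig_norm_params")
}

#' Filter genes by minimum mean expression in some cell type
#'
#' Keeps a gene iff the arithmetic mean of its raw counts within at least
#' one cell type is `>= params$min_mean_count` (the threshold is
#' inclusive). Samples are unchanged.
#'
#' @param m A [cell_matrix()].
#' @param params A [norm_params()].
#' @return A filtered [cell_matrix()].
#' @export
filter_expressed <- function(m, params = norm_params()) {
  types <- unique(m$cell_type)
  if (!length(types)) abort("matrix has no cell-type labels")
  group_means <- vapply(
    types,
    function(ct) rowMeans(m$counts[, m$cell_type == ct, drop = FALSE]),
    numeric(nrow(m$counts))
  )
  keep <- apply(as.matrix(group_means), 1, max) >= params$min_mean_count
  if (!any(keep)) abort("no genes pass filter")
  inform(sprintf("filter_expressed: kept %d of %d genes (min mean count %g)",
                 sum(keep), length(keep), params$min_mean_count))
  subset_genes(m, keep)
}

# core shrunken log2FC on a raw count matrix; groups are column indices.
# Per-sample augmented count = y + prior * (lib_s / mean(lib)); effective
# library size = lib_s + 2 * prior * (lib_s / mean(lib)).
shrunken_logfc_counts <- function(counts, idx_a, idx_b, prior_count = 10,
                                  lib_size = colSums(counts)) {
  if (!length(idx_a) || !length(idx_b)) abort("both groups must be non-empty")
  if (any(lib_size[c(idx_a, idx_b)] <= 0)) {
    abort("a group contains samples with zero total counts")
  }
  rel <- lib_size / mean(lib_size)
  prior <- prior_count * rel
  aug <- sweep(counts, 2, prior, "+")
  eff_lib <- lib_size + 2 * prior
  cpm <- sweep(aug, 2, eff_lib, "/") * 1e6
  log2(rowMeans(cpm[, idx_a, drop = FALSE])) -
    log2(rowMeans(cpm[, idx_b, drop = FALSE]))
}

#' Shrunken log2 fold change between two sample groups
#'
#' Augments each observation with a pseudocount proportional to the
#' sample's relative library size (and inflates the effective library size
#' by twice that pseudocount), then takes the log2 ratio of group-mean
#' augmented CPM. Larger `prior_count` means more shrinkage toward 0; for
#' an all-zero gene with equal library sizes the result is exactly 0.
#'
#' @param m A [cell_matrix()].
#' @param group_a,group_b Sample ids or column indices of the two groups
#'   (numerator and denominator).
#' @param params A [norm_params()]; only `prior_count` is used.
#' @return A tibble with columns `gene_id`, `logfc`.
#' @export
shrunken_logfc <- function(m, group_a, group_b, params = norm_params()) {
  idx_a <- resolve_samples(m, group_a)
  idx_b <- resolve_samples(m, group_b)
  lfc <- shrunken_logfc_counts(m$counts, idx_a, idx_b, params$prior_count)
  tibble(gene_id = rownames(m$counts), logfc = unname(lfc))
}

resolve_samples <- function(m, which) {
  if (is.character(which)) {
    idx <- match(which, colnames(m$counts))
    if (anyNA(idx)) {
      abort(paste0("unknown samples: ", paste(which[is.na(idx)], collapse = ", ")))
    }
    idx
  } else {
    as.integer(which)
  }
}

# ---- negative-binomial testing ------------------------------------------

# Method-of-moments per-gene NB dispersion (phi; variance = mu + phi mu^2),
# shrunk toward a loess mean-dispersion trend across genes.
estimate_dispersion <- function(counts, group, lib_size = colSums(counts),
                                prior_weight = 0.7) {
  group <- as.factor(group)
  n <- ncol(counts)
  k <- nlevels(group)
  rel <- lib_size / mean(lib_size)
  # fitted means: group mean of library-normalized counts, rescaled per sample
  norm <- sweep(counts, 2, rel, "/")
  group_means <- vapply(levels(group), function(g) {
    rowMeans(norm[, group == g, drop = FALSE])
  }, numeric(nrow(counts)))
  mu <- as.matrix(group_means)[, as.integer(group), drop = FALSE]
  mu <- sweep(mu, 2, rel, "*")
  resid2 <- (counts - mu)^2
  # df correction for the k estimated group means
  num <- rowSums(resid2) * n / max(n - k, 1) - rowSums(mu)
  den <- rowSums(mu^2)
  phi <- pmin(pmax(num / pmax(den, 1e-8), 1e-4), 5)
  # loess trend of log dispersion against log mean CPM
  ave_cpm <- log2(rowMeans(sweep(counts, 2, lib_size, "/")) * 1e6 + 0.25)
  trend <- rep(stats::median(phi), length(phi))
  if (length(phi) >= 50) {
    fit <- tryCatch(
      loess(log(phi) ~ ave_cpm, span = 0.5, degree = 1,
            family = "symmetric"),
      error = function(e) NULL
    )
    if (!is.null(fit)) trend <- exp(predict(fit, ave_cpm))
  }
  shrunk <- exp((1 - prior_weight) * log(phi) + prior_weight * log(trend))
  pmin(pmax(shrunk, 1e-4), 5)
}

# design matrix for covariates (numeric kept, categorical expanded);
# errors when a covariate is confounded with the group indicator
build_design <- function(group_ind, covariates) {
  x <- cbind(`(Intercept)` = 1, group = group_ind)
  if (!is.null(covariates) && ncol(covariates)) {
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (anyNA(v)) {
        warn(sprintf("covariate '%s' has missing values; excluded from model", nm))
        next
      }
      cols <- if (is.numeric(v)) {
        matrix(v, ncol = 1, dimnames = list(NULL, nm))
      } else {
        mm <- model.matrix(~f, data.frame(f = factor(v)))[, -1, drop = FALSE]
        colnames(mm) <- paste0(nm, colnames(mm))
        mm
      }
      for (j in seq_len(ncol(cols))) {
        cand <- cbind(x, cols[, j])
        if (qr(cand)$rank <= qr(x)$rank) {
          abort(sprintf("covariate '%s' is confounded with the design (singular)", nm))
        }
        x <- cand
        colnames(x)[ncol(x)] <- colnames(cols)[j]
      }
    }
  }
  x
}

# per-gene NB likelihood-ratio test of the group indicator, dispersion held
# fixed at the trended estimate; covariates enter additively on log-mean scale
nb_lrt <- function(counts, group_ind, covariates = NULL,
                   lib_size = colSums(counts), dispersion) {
  x_full <- build_design(group_ind, covariates)
  x_red <- x_full[, colnames(x_full) != "group", drop = FALSE]
  off <- log(lib_size)
  n_genes <- nrow(counts)
  p <- rep(NA_real_, n_genes)
  for (g in seq_len(n_genes)) {
    y <- counts[g, ]
    if (all(y == 0)) { p[g] <- 1; next }
    fam <- MASS::negative.binomial(theta = 1 / dispersion[g], link = "log")
    full <- tryCatch(
      suppressWarnings(stats::glm.fit(x_full, y, family = fam, offset = off)),
      error = function(e) NULL
    )
    red <- tryCatch(
      suppressWarnings(stats::glm.fit(x_red, y, family = fam, offset = off)),
      error = function(e) NULL
    )
    if (is.null(full) || is.null(red)) { p[g] <- NA_real_; next }
    stat <- max(red$deviance - full$deviance, 0)
    p[g] <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  p
}

# deterministic within-measure ranking: stat desc, gene_id asc
rank_signature <- function(stat, gene_id, descending = TRUE) {
  o <- if (descending) order(-stat, gene_id) else order(stat, gene_id)
  r <- integer(length(stat))
  r[o] <- seq_along(stat)
  r
}

finish_signature <- function(tbl) {
  class(tbl) <- c("cellsig_signature", class(tbl))
  tbl
}

#' Cell-type enrichment signature
#'
#' Compares samples of the target cell type against all reference cell
#' types pooled as a single group. The statistic is the shrunken log2 fold
#' change; the p-value comes from a per-gene negative-binomial
#' likelihood-ratio test of the target-vs-reference term (dispersion fixed
#' at a trended moment estimate, covariates as additive log-scale terms),
#' with Benjamini-Hochberg adjustment across genes.
#'
#' @param m A [cell_matrix()] (typically after [filter_expressed()]).
#' @param target Target cell type.
#' @param reference Reference cell types; defaults to [reference_set()] of
#'   the types present (MOL and OPC excluded from each other's reference).
#' @param params A [norm_params()].
#' @param covariates Character vector naming covariate columns of
#'   `m$covariates` to adjust for (default: all of them).
#' @param p_method `"lrt"` for the negative-binomial test, `"none"` to skip
#'   p-values (fold changes only; much faster).
#' @return A signature tibble: `gene_id`, `cell_type`, `measure`, `stat`
#'   (log2 fold change), `p_value`, `adj_p`, `rank`.
#' @export
ct_enrichment <- function(m, target, reference = NULL,
                          params = norm_params(), covariates = NULL,
                          p_method = c("lrt", "none")) {
  p_method <- match.arg(p_method)
  types <- unique(m$cell_type)
  if (is.null(reference)) reference <- reference_set(target, types)
  check_reference_set(target, reference)
  if (sum(m$cell_type == target) < 2) {
    abort(sprintf("target '%s' needs at least 2 samples", target))
  }
  keep <- m$cell_type %in% c(target, reference)
  ms <- subset_samples(m, keep)
  idx_a <- which(ms$cell_type == target)
  idx_b <- which(ms$cell_type != target)
  lib <- colSums(ms$counts)
  stat <- shrunken_logfc_counts(ms$counts, idx_a, idx_b, params$prior_count, lib)
  if (p_method == "lrt") {
    disp <- estimate_dispersion(ms$counts, ms$cell_type, lib)
    covar <- select_covariates(ms, covariates)
    pv <- nb_lrt(ms$counts, as.integer(ms$cell_type == target), covar, lib, disp)
    adj <- p.adjust(pv, method = "BH")
  } else {
    pv <- adj <- rep(NA_real_, length(stat))
  }
  gene_id <- rownames(ms$counts)
  finish_signature(tibble(
    gene_id = gene_id, cell_type = target, measure = "enrichment",
    stat = unname(stat), p_value = pv, adj_p = adj,
    rank = rank_signature(stat, gene_id)
  ))
}

select_covariates <- function(m, covariates) {
  if (is.null(m$covariates)) return(NULL)
  if (is.null(covariates)) return(m$covariates)
  missing <- setdiff(covariates, names(m$covariates))
  if (length(missing)) {
    abort(paste0("unknown covariates: ", paste(missing, collapse = ", ")))
  }
  m$covariates[covariates]
}

#' Cell-type specificity signature
#'
#' Contrasts the target cell type against every reference cell type
#' individually and takes the minimum shrunken log2 fold change — high only
#' when the gene is elevated versus *every* other type. The p-value
#' reported for each gene is that of the pairwise contrast attaining the
#' minimum.
#'
#' @inheritParams ct_enrichment
#' @return A signature tibble as in [ct_enrichment()] with
#'   `measure = "specificity"`. The stat is by construction `<=` every
#'   pairwise log2 fold change for that gene.
#' @export
ct_specificity <- function(m, target, reference = NULL,
                           params = norm_params(), covariates = NULL,
                           p_method = c("lrt", "none")) {
  p_method <- match.arg(p_method)
  types <- unique(m$cell_type)
  if (is.null(reference)) reference <- reference_set(target, types)
  check_reference_set(target, reference)
  if (sum(m$cell_type == target) < 2) {
    abort(sprintf("target '%s' needs at least 2 samples", target))
  }
  keep <- m$cell_type %in% c(target, reference)
  ms <- subset_samples(m, keep)
  lib <- colSums(ms$counts)
  idx_t <- which(ms$cell_type == target)
  lfc <- vapply(reference, function(r) {
    shrunken_logfc_counts(ms$counts, idx_t, which(ms$cell_type == r),
                          params$prior_count, lib)
  }, numeric(nrow(ms$counts)))
  lfc <- as.matrix(lfc)
  which_min <- apply(lfc, 1, which.min)
  stat <- lfc[cbind(seq_len(nrow(lfc)), which_min)]
  if (p_method == "lrt") {
    pmat <- vapply(seq_along(reference), function(j) {
      r <- reference[j]
      sel <- ms$cell_type %in% c(target, r)
      mp <- subset_samples(ms, sel)
      libp <- colSums(mp$counts)
      disp <- estimate_dispersion(mp$counts, mp$cell_type, libp)
      nb_lrt(mp$counts, as.integer(mp$cell_type == target),
             select_covariates(mp, covariates), libp, disp)
    }, numeric(nrow(ms$counts)))
    pv <- as.matrix(pmat)[cbind(seq_len(nrow(lfc)), which_min)]
    adj <- p.adjust(pv, method = "BH")
  } else {
    pv <- adj <- rep(NA_real_, length(stat))
  }
  gene_id <- rownames(ms$counts)
  finish_signature(tibble(
    gene_id = gene_id, cell_type = target, measure = "specificity",
    stat = unname(stat), p_value = pv, adj_p = adj,
    rank = rank_signature(stat, gene_id)
  ))
}

#' Quantile-normalize the columns of a matrix
#'
#' Each column's values are mapped onto the mean of the sorted columns;
#' ties receive the mean of their target values (delegated to
#' [limma::normalizeQuantiles()]).
#'
#' @param x Numeric matrix (genes x samples).
#' @return Matrix of the same dimensions.
#' @export
quantile_normalize <- function(x) {
  if (nrow(x) < 2) return(x)  # a single value is its own quantile
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Absolute-expression signature (mean RPKM within a cell type)
#'
#' Samples are quantile-normalized on the raw-count scale, converted to
#' RPKM using gene length (kb) and per-sample library size (millions), and
#' averaged within the cell type. The stat is the mean RPKM with its
#' standard error; `rank` 1 is the highest-expressed gene within the cell
#' type.
#'
#' @inheritParams ct_enrichment
#' @param lengths A gene-length tibble (`gene_id`, `length_bp`), e.g. from
#'   [read_gene_lengths()]. Genes without a length are dropped with a
#'   warning.
#' @param target Cell type(s) to report; default all present.
#' @return A signature tibble with `measure = "expression"`, `stat` = mean
#'   RPKM, `sem`, `rank`; `p_value`/`adj_p` are `NA` (no test is involved).
#' @export
ct_expression <- function(m, lengths, target = NULL) {
  if (is.null(target)) target <- unique(m$cell_type)
  lib <- colSums(m$counts)
  if (any(lib <= 0)) abort("zero library size")
  has_len <- rownames(m$counts) %in% lengths$gene_id
  if (!all(has_len)) {
    warn(sprintf("%d genes without length dropped", sum(!has_len)))
    m <- subset_genes(m, has_len)
  }
  qn <- quantile_normalize(m$counts)
  len_kb <- lengths$length_bp[match(rownames(qn), lengths$gene_id)] / 1e3
  lib_m <- colSums(qn) / 1e6
  rpkm <- sweep(qn / len_kb, 2, lib_m, "/")
  purrr::map_dfr(target, function(ct) {
    sub <- rpkm[, m$cell_type == ct, drop = FALSE]
    mu <- rowMeans(sub)
    sem <- apply(sub, 1, sd) / sqrt(ncol(sub))
    gene_id <- rownames(rpkm)
    tibble(
      gene_id = gene_id, cell_type = ct, measure = "expression",
      stat = unname(mu), sem = unname(sem),
      p_value = NA_real_, adj_p = NA_real_,
      rank = rank_signature(mu, gene_id)
    )
  }) |> finish_signature()
}

#' Derive all signature tables for a labeled count matrix
#'
#' Convenience wrapper running [filter_expressed()] once and then the
#' requested measures for every cell type present (or `targets`).
#'
#' @inheritParams ct_enrichment
#' @inheritParams ct_expression
#' @param measures Subset of `c("enrichment", "specificity", "expression")`.
#' @param targets Cell types to profile; default all with >= 2 samples.
#' @return A single signature tibble (rows for every target x measure).
#' @export
cell_signatures <- function(m, lengths = NULL,
                            measures = c("enrichment", "specificity", "expression"),
                            targets = NULL, params = norm_params(),
                            covariates = NULL, p_method = "lrt") {
  measures <- match.arg(measures, several.ok = TRUE)
  if ("expression" %in% measures && is.null(lengths)) {
    abort("`lengths` is required for the expression measure")
  }
  mf <- filter_expressed(m, params)
  if (is.null(targets)) {
    tab <- table(mf$cell_type)
    targets <- names(tab)[tab >= 2]
  }
  out <- list()
  for (ct in targets) {
    if ("enrichment" %in% measures) {
      out[[length(out) + 1]] <-
        ct_enrichment(mf, ct, params = params, covariates = covariates,
                      p_method = p_method)
    }
    if ("specificity" %in% measures) {
      out[[length(out) + 1]] <-
        ct_specificity(mf, ct, params = params, covariates = covariates,
                       p_method = p_method)
    }
  }
  if ("expression" %in% measures) {
    out[[length(out) + 1]] <- ct_expression(mf, lengths, targets)
  }
  finish_signature(bind_rows(out))
}

#' Flag volcano-significant genes
#'
#' A gene is flagged when its BH-adjusted p-value is below `alpha`
#' (strictly) and its fold change is at least `min_fc` (inclusive, i.e.
#' `stat >= log2(min_fc)`).
#'
#' @param rows A signature tibble carrying `stat` and `adj_p`.
#' @param alpha Adjusted-p threshold (default 0.05, strict `<`).
#' @param min_fc Fold-change threshold on the natural scale (default 4).
#' @return The input with a logical `flagged` column appended.
#' @export
volcano_flags <- function(rows, alpha = 0.05, min_fc = 4) {
  mutate(rows,
         flagged = !is.na(.data$adj_p) & .data$adj_p < alpha &
           .data$stat >= log2(min_fc))
}
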