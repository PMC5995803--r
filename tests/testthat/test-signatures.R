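test_that("expression filter keeps genes at the inclusive group-mean threshold", {
  means <- cbind(AST = c(5, 4.9, 6), MIC = c(0, 4.9, 5), NEU = c(0, 4.9, 4.8))
  rownames(means) <- c("boundary", "below", "above")
  m <- means_fixture(means)
  kept <- suppressMessages(filter_expressed(m))
  expect_setequal(rownames(kept$counts), c("boundary", "above"))

  all_low <- means_fixture(cbind(AST = 1, MIC = 2))
  expect_error(suppressMessages(filter_expressed(all_low)), "no genes pass")
})

test_that("shrunken logFC matches the hand-computed augmentation exactly", {
  m <- logfc_fixture(counts_a = c(80, 80), counts_b = c(5, 5))
  lfc <- shrunken_logfc(m, c("s1", "s2"), c("s3", "s4"))
  # equal libraries 1e6, prior 10: log2((80+10)/(5+10)) = log2(6)
  expect_equal(lfc$logfc[lfc$gene_id == "g1"], log2(6), tolerance = 1e-12)
})

test_that("shrunken logFC is zero for identical groups and all-zero genes", {
  m <- logfc_fixture(counts_a = c(40, 40), counts_b = c(40, 40))
  lfc <- shrunken_logfc(m, 1:2, 3:4)
  expect_equal(lfc$logfc, c(0, 0), tolerance = 1e-12)

  counts <- matrix(c(0, 0, 0, 0, 10, 10, 10, 10), nrow = 2, byrow = TRUE,
                   dimnames = list(c("zero", "lib"), paste0("s", 1:4)))
  m0 <- cell_matrix(counts, rep(c("A", "B"), each = 2))
  expect_equal(shrunken_logfc(m0, 1:2, 3:4)$logfc[1], 0, tolerance = 1e-12)
})

test_that("increasing prior_count shrinks |logFC| monotonically toward zero", {
  sim <- simulate_cells(small_sim_cfg(seed = 21, n_genes = 500))
  m <- sim$matrix
  idx_a <- which(m$cell_type == "AST")
  idx_b <- which(m$cell_type != "AST")
  abs_lfc <- sapply(c(0, 1, 10, 100), function(p) {
    abs(shrunken_logfc(m, idx_a, idx_b, norm_params(prior_count = p))$logfc)
  })
  for (j in 2:4) expect_true(all(abs_lfc[, j] <= abs_lfc[, j - 1] + 1e-12))
})

test_that("enrichment approaches the true log2 ratio at high expression", {
  # 4x target-vs-reference at high counts: shrinkage is negligible
  m <- logfc_fixture(counts_a = c(4e4, 4e4), counts_b = c(1e4, 1e4))
  e <- ct_enrichment(m, "A", reference = "B", p_method = "none")
  expect_equal(e$stat[e$gene_id == "g1"], 2, tolerance = 0.01)
})

test_that("with two cell types specificity equals enrichment", {
  sim <- simulate_cells(small_sim_cfg(seed = 4, cell_types = c("AST", "MIC")))
  m <- suppressMessages(filter_expressed(sim$matrix))
  e <- ct_enrichment(m, "AST", p_method = "none")
  s <- ct_specificity(m, "AST", p_method = "none")
  expect_equal(s$stat, e$stat, tolerance = 1e-12)
  expect_identical(s$rank, e$rank)
})

test_that("a gene shared by two cell types is enriched but not specific", {
  means <- cbind(AST = c(100, 50, 50, 50), END = c(100, 50, 50, 50),
                 MIC = c(1, 50, 50, 50), NEU = c(1, 50, 50, 50))
  rownames(means) <- c("shared", "b1", "b2", "b3")
  m <- means_fixture(means, n_per_type = 3)
  e <- ct_enrichment(m, "AST", p_method = "none")
  s <- ct_specificity(m, "AST", p_method = "none")
  expect_gt(e$stat[e$gene_id == "shared"], 1)
  expect_lt(abs(s$stat[s$gene_id == "shared"]), 0.2)  # ~0 against END
})

test_that("specificity is bounded above by every pairwise logFC", {
  sim <- simulate_cells(small_sim_cfg(seed = 6))
  m <- suppressMessages(filter_expressed(sim$matrix))
  params <- norm_params()
  for (target in c("AST", "MOL")) {
    refs <- reference_set(target, unique(m$cell_type))
    s <- ct_specificity(m, target, p_method = "none")
    # pairwise logFCs in the same normalization context (target + reference
    # samples only; MOL/OPC exclusion changes the sample set)
    ms <- cellsig:::subset_samples(m, m$cell_type %in% c(target, refs))
    lib <- colSums(ms$counts)
    idx_t <- which(ms$cell_type == target)
    for (r in refs) {
      pair <- cellsig:::shrunken_logfc_counts(
        ms$counts, idx_t, which(ms$cell_type == r), params$prior_count, lib)
      expect_true(all(s$stat <= pair + 1e-9))
    }
  }
})

test_that("with balanced groups the enrichment stat lies between the pairwise logFCs", {
  # equal per-group sizes and equal library sizes: the pooled mean is the
  # average of group means, so enrichment is bracketed by the pairwise FCs
  set.seed(9)
  n_types <- 4
  counts <- matrix(rpois(200 * n_types * 3, 50), nrow = 200)
  counts <- rbind(counts, matrix(0, 1, ncol(counts)))
  counts[nrow(counts), ] <- 5e4 - colSums(counts)  # equalize library sizes
  rownames(counts) <- c(sprintf("g%03d", 1:200), "filler")
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  m <- cell_matrix(counts, rep(c("AST", "END", "MIC", "NEU"), each = 3))
  e <- ct_enrichment(m, "AST", p_method = "none")
  lib <- colSums(m$counts)
  idx_t <- which(m$cell_type == "AST")
  pairwise <- sapply(c("END", "MIC", "NEU"), function(r) {
    cellsig:::shrunken_logfc_counts(m$counts, idx_t,
                                    which(m$cell_type == r), 10, lib)
  })
  expect_true(all(e$stat >= apply(pairwise, 1, min) - 1e-9))
  expect_true(all(e$stat <= apply(pairwise, 1, max) + 1e-9))
})

test_that("planted markers are estimated near their true effect with significance", {
  # markers kept a small fraction of the genome so that library-composition
  # skew (strong markers inflating their own cells' library sizes) does not
  # confound the estimate being checked
  cfg <- sim_config(n_genes = 2000, cells_per_type = 50,
                    n_markers_per_type = 5, baseline_mean = 200, seed = 31)
  sim <- simulate_cells(cfg)
  m <- suppressMessages(filter_expressed(sim$matrix))
  e <- ct_enrichment(m, "AST")
  truth <- sim$truth$marker_assignments
  ast <- intersect(truth$gene_id[truth$cell_type == "AST"], e$gene_id)
  # shrinkage biases low-expression genes; judge markers whose reference
  # counts are high enough that the prior is negligible
  ref_mean <- rowMeans(m$counts[, m$cell_type != "AST", drop = FALSE])
  strong <- ast[ref_mean[ast] >= 50]
  expect_gt(length(strong), 3)
  rows <- e[match(strong, e$gene_id), ]
  expect_true(all(abs(rows$stat - 4) <= 0.3))
  expect_true(all(rows$adj_p < 0.05))
})

test_that("BH adjustment agrees with a brute-force oracle", {
  withr::with_seed(12, {
    for (i in 1:20) {
      p <- runif(sample(5:40, 1))
      expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
    }
  })
  # adjusted p is monotone non-decreasing in p rank
  p <- runif(100)
  adj <- p.adjust(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj >= p))
})

test_that("confounded covariates are rejected by name", {
  sim <- simulate_cells(small_sim_cfg(seed = 7, cell_types = c("AST", "MIC")))
  m <- sim$matrix
  m$covariates <- tibble::tibble(batch = as.integer(m$cell_type == "AST"))
  expect_error(ct_enrichment(m, "AST", covariates = "batch"), "batch")
})

test_that("RPKM, ranks and the quantile target behave as defined", {
  # single sample: count 200, length 2000 bp, library 1e6 -> RPKM 100
  counts <- matrix(c(200, 999800), ncol = 1,
                   dimnames = list(c("g1", "filler"), "s1"))
  m <- cell_matrix(counts, "AST")
  lengths <- tibble::tibble(gene_id = c("g1", "filler"),
                            length_bp = c(2000, 1000))
  ex <- ct_expression(m, lengths)
  expect_equal(ex$stat[ex$gene_id == "g1"], 100, tolerance = 1e-9)

  # two genes with RPKM 100 and 10 rank in that order
  counts2 <- matrix(c(200, 20, 999780, 200, 20, 999780), ncol = 2,
                    dimnames = list(c("hi", "lo", "filler"), c("s1", "s2")))
  m2 <- cell_matrix(counts2, c("AST", "AST"))
  lengths2 <- tibble::tibble(gene_id = c("hi", "lo", "filler"),
                             length_bp = c(2000, 2000, 1000))
  ex2 <- ct_expression(m2, lengths2)
  stats2 <- ex2$stat[match(c("hi", "lo"), ex2$gene_id)]
  expect_equal(stats2, c(100, 10), tolerance = 1e-9)
  ranks2 <- ex2$rank[match(c("hi", "lo"), ex2$gene_id)]
  expect_lt(ranks2[1], ranks2[2])

  # permuted columns share one sorted value set after quantile normalization
  x <- cbind(s1 = c(5, 1, 9, 3), s2 = c(9, 3, 5, 1))
  qn <- quantile_normalize(x)
  expect_equal(sort(qn[, 1]), sort(qn[, 2]), tolerance = 1e-12)
  expect_equal(sort(qn[, 1]), sort(rowMeans(apply(x, 2, sort))),
               tolerance = 1e-12)
})

test_that("genes without a length are dropped with a warning", {
  counts <- matrix(c(10, 20, 30, 40), 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  m <- cell_matrix(counts, c("AST", "AST"))
  lengths <- tibble::tibble(gene_id = "g1", length_bp = 1000)
  expect_warning(ex <- ct_expression(m, lengths), "without length")
  expect_identical(unique(ex$gene_id), "g1")
})

test_that("volcano flags apply an inclusive FC and strict p threshold", {
  rows <- tibble::tibble(
    gene_id = c("a", "b", "c"), cell_type = "AST", measure = "enrichment",
    stat = c(2.0, 1.99, 2.0), p_value = NA_real_,
    adj_p = c(0.049, 1e-10, 0.05), rank = 1:3
  )
  out <- volcano_flags(rows)
  expect_identical(out$flagged, c(TRUE, FALSE, FALSE))
})

test_that("shrunken logFC tracks the edgeR predFC convention", {
  skip_if_not_installed("edgeR")
  sim <- simulate_cells(small_sim_cfg(seed = 14, cell_types = c("AST", "MIC")))
  m <- sim$matrix
  group <- factor(m$cell_type, levels = c("MIC", "AST"))
  design <- model.matrix(~group)
  pfc <- edgeR::predFC(m$counts, design, prior.count = 10, dispersion = 0)
  ours <- shrunken_logfc(m, which(m$cell_type == "AST"),
                         which(m$cell_type == "MIC"))
  # same augmentation family, different mean-vs-GLM summaries: expect close
  # agreement, not identity
  expect_gt(cor(ours$logfc, pfc[, 2]), 0.99)
  expect_lt(median(abs(ours$logfc - pfc[, 2])), 0.1)
})
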