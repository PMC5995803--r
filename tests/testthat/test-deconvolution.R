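# bulk fixture: log-CPM of simulated Dirichlet mixtures plus the ranked
# true marker list
bulk_fixture <- function(seed = 1, ...) {
  cfg <- sim_config(seed = seed, ...)
  sim <- simulate_bulk(cfg)
  cells <- simulate_cells(cfg)
  markers <- cells$truth$marker_assignments |>
    dplyr::group_by(cell_type) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  bulk <- log2(sweep(sim$bulk, 2, colSums(sim$bulk), "/") * 1e6 + 1)
  list(bulk = bulk, markers = markers, truth = sim$truth$proportions)
}

test_that("select_markers intersects ranked lists with the available genes", {
  cons <- tibble::tibble(
    gene_id = paste0("g", 1:120),
    cell_type = rep(c("AST", "MIC"), each = 60),
    consensus_rank = rep(1:60, 2)
  )
  mk <- select_markers(cons, n = 50)
  expect_equal(as.integer(table(mk$cell_type)), c(50L, 50L))
  expect_identical(mk$gene_id[mk$cell_type == "AST"][1], "g1")

  avail <- c(paste0("g", seq(1, 60, 2)), paste0("g", 61:120))
  expect_warning(mk2 <- select_markers(cons, n = 50, available_genes = avail),
                 "AST \\(30\\)")
  expect_equal(sum(mk2$cell_type == "AST"), 30)
  expect_identical(mk2$rank[mk2$cell_type == "AST"], 1:30)  # order preserved

  expect_error(select_markers(cons, n = 50, available_genes = paste0("g", 61:120)),
               "AST")
})

test_that("a marker shared by two cell types is kept in both with a warning", {
  cons <- tibble::tibble(
    gene_id = c("g1", "g2", "shared", "g3", "g4", "shared"),
    cell_type = rep(c("AST", "MIC"), each = 3),
    consensus_rank = rep(1:3, 2)
  )
  expect_warning(mk <- select_markers(cons, n = 3), "shared")
  expect_equal(sum(mk$gene_id == "shared"), 2)
})

test_that("a noiseless rank-1 marker block recovers the proportions exactly", {
  withr::with_seed(8, {
    w <- runif(30, 0.5, 2)
    props <- runif(12)
    X <- outer(w, props)
    dimnames(X) <- list(paste0("g", 1:30), paste0("s", 1:12))
    mk <- tibble::tibble(cell_type = "AST", gene_id = rownames(X), rank = 1:30)
    est <- estimate_proportions(X, mk, n_markers = 30)
    expect_equal(cor(est$spv[, "AST"], props, method = "spearman"), 1)
    expect_equal(sum(est$spv[, "AST"]^2), 1, tolerance = 1e-12)  # unit norm
    # sign correction: positive correlation with mean marker expression
    expect_gte(cor(est$spv[, "AST"], colMeans(t(scale(t(X))))), 0)
  })
})

test_that("the sign correction resolves the SVD's sign ambiguity deterministically", {
  fx <- bulk_fixture(seed = 3)
  mk_ast <- dplyr::filter(fx$markers, cell_type == "AST")
  est <- estimate_proportions(fx$bulk, mk_ast)
  # each estimate satisfies its own alignment constraint ...
  Xs <- t(scale(t(fx$bulk[est$markers_used$AST, ])))
  expect_gte(cor(est$spv[, "AST"], colMeans(Xs)), 0)
  # ... so negating the data is exactly mirrored: the markers now
  # anticorrelate with abundance and the corrected SPV flips with them
  est_neg <- estimate_proportions(-fx$bulk, mk_ast)
  expect_equal(est_neg$spv[, "AST"], -est$spv[, "AST"], tolerance = 1e-9)
  expect_gte(cor(est_neg$spv[, "AST"], colMeans(-Xs)), 0)
  # and recomputing from the pre-scaled submatrix reproduces the estimate
  direct <- cellsig:::spv_one(Xs, scale_genes = FALSE)
  expect_equal(direct$spv, unname(est$spv[, "AST"]), tolerance = 1e-9)
})

test_that("the SPV equals the leading principal component from an eigen oracle", {
  fx <- bulk_fixture(seed = 5)
  est <- estimate_proportions(fx$bulk, fx$markers)
  for (ct in colnames(est$spv)) {
    g <- est$markers_used[[ct]]
    Xs <- t(scale(t(fx$bulk[g, ])))
    ev <- eigen(crossprod(Xs), symmetric = TRUE)$vectors[, 1]
    cosine <- abs(sum(ev * est$spv[, ct])) /
      sqrt(sum(ev^2) * sum(est$spv[, ct]^2))
    expect_gte(cosine, 1 - 1e-9)
  }
})

test_that("SPVs are invariant to sample and marker-gene reordering", {
  fx <- bulk_fixture(seed = 6)
  mk_ast <- dplyr::filter(fx$markers, cell_type == "AST")
  est <- estimate_proportions(fx$bulk, mk_ast)
  withr::with_seed(2, {
    perm_s <- sample(ncol(fx$bulk))
    est_s <- estimate_proportions(fx$bulk[, perm_s], mk_ast)
    expect_equal(est_s$spv[colnames(fx$bulk), "AST"], est$spv[, "AST"],
                 tolerance = 1e-9)
    est_g <- estimate_proportions(fx$bulk, mk_ast[sample(nrow(mk_ast)), ])
    expect_equal(est_g$spv[, "AST"], est$spv[, "AST"], tolerance = 1e-9)
  })
})

test_that("proportion recovery degrades as overdispersion grows", {
  mean_rho <- vapply(c(10, 1, 0.2), function(size) {
    rhos <- vapply(1:3, function(s) {
      fx <- bulk_fixture(seed = 100 + s, dispersion = size)
      est <- estimate_proportions(fx$bulk, fx$markers)
      mean(vapply(colnames(est$spv), function(ct) {
        cor(est$spv[, ct], fx$truth[, ct], method = "spearman")
      }, numeric(1)))
    }, numeric(1))
    mean(rhos)
  }, numeric(1))
  expect_gte(mean_rho[1], 0.9)
  expect_true(all(diff(mean_rho) < 0))
})

test_that("degenerate and undersized marker inputs are rejected", {
  X <- matrix(1, nrow = 4, ncol = 5,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  mk <- tibble::tibble(cell_type = "AST", gene_id = rownames(X), rank = 1:4)
  expect_error(estimate_proportions(X, mk), "degenerate markers")
  expect_error(estimate_proportions(X[, 1:2], mk), "at least 3")
  Y <- matrix(rnorm(10), 2, 5, dimnames = list(c("a", "b"), paste0("s", 1:5)))
  expect_error(
    estimate_proportions(Y, tibble::tibble(cell_type = "AST", gene_id = "a",
                                           rank = 1)),
    "fewer than 2 markers")
})

test_that("raw-count-like bulk input triggers a warning", {
  fx <- bulk_fixture(seed = 9)
  raw <- matrix(rpois(200 * 10, 50), 200, 10,
                dimnames = list(rownames(fx$bulk)[1:200], paste0("s", 1:10)))
  raw[1, 1] <- 2e4
  mk <- dplyr::filter(fx$markers, gene_id %in% rownames(raw))
  expect_warning(estimate_proportions(raw, mk), "raw counts")
})

test_that("the cumulative marker curve improves with more markers", {
  fx <- bulk_fixture(seed = 11)
  ref <- fx$truth[, "AST"]
  cv <- cumulative_marker_curve(fx$bulk, fx$markers, ref, cell_type = "AST")
  expect_equal(cv$curve$n_markers, 2:50)
  expect_gte(cv$curve$rho[cv$curve$n_markers == 50],
             cv$curve$rho[cv$curve$n_markers == 3])
  expect_equal(nrow(cv$gene_cor), 50)
  # a single informative marker correlates, but less reliably than the SPV
  expect_true(all(abs(cv$gene_cor$rho) <= 1))
})

test_that("a constant reference yields NA correlations with a warning", {
  fx <- bulk_fixture(seed = 12)
  expect_warning(
    cv <- cumulative_marker_curve(fx$bulk, fx$markers, rep(1, ncol(fx$bulk)),
                                  cell_type = "AST", max_n = 5),
    "constant")
  expect_true(all(is.na(cv$curve$rho)))
})

test_that("anticorrelated early markers dip the curve before it recovers", {
  withr::with_seed(13, {
    n_s <- 30
    props <- runif(n_s)
    z <- (props - mean(props)) / sd(props)
    X <- rbind(
      t(replicate(7, props + rnorm(n_s, sd = 1.2))),  # weak positive markers
      t(replicate(2, -5 * props + rnorm(n_s, sd = 0.1))),  # strong negatives at ranks 8-9
      t(replicate(6, props + rnorm(n_s, sd = 0.15)))  # strong positives later
    )
    dimnames(X) <- list(paste0("g", 1:15), paste0("s", 1:n_s))
    mk <- tibble::tibble(cell_type = "AST", gene_id = rownames(X), rank = 1:15)
    cv <- cumulative_marker_curve(X, mk, props, cell_type = "AST")
    rho <- cv$curve$rho
    n <- cv$curve$n_markers
    expect_lt(rho[n == 9], rho[n == 7])   # the dip
    expect_gt(rho[n == 15], rho[n == 9])  # resolved by larger n
    expect_gte(rho[n == 15], 0.9)
  })
})

test_that("adjustment leaves every gene uncorrelated with every SPV", {
  fx <- bulk_fixture(seed = 15)
  est <- estimate_proportions(fx$bulk, fx$markers)
  adj <- adjust_expression(fx$bulk, est)
  expect_identical(dim(adj), dim(fx$bulk))
  cors <- abs(cor(t(adj), est$spv))
  expect_lt(max(cors, na.rm = TRUE), 1e-8)
})

test_that("adjustment preserves orthogonal genes and flattens SPV-identical ones", {
  fx <- bulk_fixture(seed = 16)
  mk_ast <- dplyr::filter(fx$markers, cell_type == "AST")
  est <- estimate_proportions(fx$bulk, mk_ast)
  bulk <- fx$bulk
  # construct a gene already orthogonal to the SPV (residualize it first)
  g_orth <- qr.resid(qr(cbind(1, est$spv)), rnorm(ncol(bulk))) + 5
  bulk <- rbind(bulk, orth = g_orth, dupe = est$spv[, 1])
  adj <- adjust_expression(bulk, est)
  expect_equal(unname(adj["orth", ]), unname(g_orth), tolerance = 1e-9)
  expect_equal(unname(adj["dupe", ]), rep(mean(est$spv[, 1]), ncol(bulk)),
               tolerance = 1e-9)
})

test_that("adjustment requires enough residual degrees of freedom", {
  fx <- bulk_fixture(seed = 17)
  est <- estimate_proportions(fx$bulk, fx$markers)
  small <- fx$bulk[, 1:6]
  est$spv <- est$spv[1:6, ]
  expect_error(adjust_expression(small, est), "degrees of freedom")
})

test_that("spv objects expose tidy, glance and marker bookkeeping", {
  fx <- bulk_fixture(seed = 18)
  est <- estimate_proportions(fx$bulk, fx$markers)
  td <- tidy(est)
  expect_named(td, c("sample_id", "cell_type", "spv"))
  expect_equal(nrow(td), nrow(est$spv) * ncol(est$spv))
  gl <- glance(est)
  expect_equal(gl$n_cell_types, 6)
  expect_equal(gl$n_markers, sum(lengths(est$markers_used)))
})
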