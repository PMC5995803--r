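#' Fold enrichment of a pairwise gene-set overlap
#'
#' Fold enrichment is the observed intersection size divided by its
#' expectation under independent draws from the universe:
#' `FE = |d1 n d2| / (|d1| * |d2| / |U|)`. The p-value is the
#' hypergeometric upper tail `P(X >= |d1 n d2|)`.
#'
#' @param d1,d2 Character vectors (gene sets), subsets of `universe`.
#' @param universe Character vector, the gene universe (for signature
#'   comparisons: the symbols common to the compared datasets).
#' @return A one-row tibble: `n1`, `n2`, `n_universe`,
#'   `intersection_size`, `fold_enrichment`, `p_value`.
#' @export
#' @examples
#' u <- paste0("g", 1:100)
#' fold_enrichment(u[1:10], u[1:10], u)  # FE = 10
fold_enrichment <- function(d1, d2, universe) {
  d1 <- unique(d1); d2 <- unique(d2); universe <- unique(universe)
  check_subsets(list(d1, d2), universe)
  if (!length(d1) || !length(d2)) {
    warn("empty gene set; fold enrichment defined as 0")
    return(tibble(n1 = length(d1), n2 = length(d2),
                  n_universe = length(universe), intersection_size = 0L,
                  fold_enrichment = 0, p_value = 1))
  }
  k <- length(intersect(d1, d2))
  fe <- k / (length(d1) * length(d2) / length(universe))
  p <- phyper(k - 1, length(d1), length(universe) - length(d1), length(d2),
              lower.tail = FALSE)
  tibble(n1 = length(d1), n2 = length(d2), n_universe = length(universe),
         intersection_size = as.integer(k), fold_enrichment = fe, p_value = p)
}

check_subsets <- function(sets, universe) {
  for (s in sets) {
    extra <- setdiff(s, universe)
    if (length(extra)) {
      abort(paste0("set members outside the universe: ",
                   paste(head(extra, 5), collapse = ", ")))
    }
  }
  if (!length(universe)) abort("universe must be non-empty")
  invisible(TRUE)
}

# pmf of |D_1 n ... n D_k| when each D_i is a uniform random subset of its
# observed size: intersecting one more set with a current intersection of
# size m is hypergeometric, so the pmf folds one hypergeometric per set.
multiset_intersection_pmf <- function(sizes, n_universe) {
  pmf <- numeric(min(sizes) + 1)      # index x+1 = P(X = x)
  cur <- numeric(sizes[1] + 1)
  cur[sizes[1] + 1] <- 1
  for (i in seq_along(sizes)[-1]) {
    new_max <- min(sizes[seq_len(i)])
    nxt <- numeric(new_max + 1)
    for (m in which(cur > 0) - 1) {
      x <- 0:min(m, sizes[i])
      nxt[x + 1] <- nxt[x + 1] +
        cur[m + 1] * dhyper(x, m, n_universe - m, sizes[i])
    }
    cur <- nxt
  }
  cur
}

#' Multi-set intersection enrichment
#'
#' Generalizes [fold_enrichment()] to k sets:
#' `FE = |intersection| / (prod |D_i| / |U|^(k-1))`, with the p-value
#' `P(intersection >= observed)` under independent uniform draws of each
#' set's size from the universe — computed exactly by folding one
#' hypergeometric per set (used for k <= 5), or by seeded Monte Carlo with
#' the `(r + 1) / (n_perm + 1)` estimator.
#'
#' @param sets List of >= 2 character vectors, all subsets of `universe`.
#' @param universe Character vector.
#' @param method `"exact"` (default for k <= 5) or `"montecarlo"`.
#' @param n_perm Monte Carlo draws (default 10000).
#' @param seed Seed for the Monte Carlo method.
#' @return A one-row tibble: `n_sets`, `n_universe`, `intersection_size`,
#'   `fold_enrichment`, `p_value`, `method`.
#' @export
multiset_enrichment <- function(sets, universe,
                                method = NULL, n_perm = 10000, seed = 1L) {
  k <- length(sets)
  if (k < 2) abort("need at least 2 sets")
  sets <- lapply(sets, unique)
  universe <- unique(universe)
  check_subsets(sets, universe)
  if (is.null(method)) method <- if (k <= 5) "exact" else "montecarlo"
  method <- match.arg(method, c("exact", "montecarlo"))
  sizes <- lengths(sets)
  u <- length(universe)
  obs <- length(Reduce(intersect, sets))
  fe <- obs / (prod(sizes) / u^(k - 1))
  if (method == "exact") {
    pmf <- multiset_intersection_pmf(sizes, u)
    p <- sum(pmf[seq.int(obs + 1, length(pmf))])
    p <- min(max(p, 0), 1)
  } else {
    r <- with_seed_(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        tally <- integer(u)
        for (s in sizes) {
          draw <- sample.int(u, s)
          tally[draw] <- tally[draw] + 1L
        }
        if (sum(tally == k) >= obs) hits <- hits + 1L
      }
      hits
    })
    p <- (r + 1) / (n_perm + 1)
  }
  tibble(n_sets = k, n_universe = u, intersection_size = as.integer(obs),
         fold_enrichment = fe, p_value = p, method = method)
}

#' Fisher's exact gene-set enrichment of a query set
#'
#' One 2x2 Fisher's exact test per annotation set, with BH adjustment
#' across sets. The odds ratio is the conditional MLE from
#' [stats::fisher.test()], reported as `Inf` when a zero margin cell makes
#' it unbounded.
#'
#' @param query Character vector, subset of `universe`.
#' @param annotation_sets Named list of character vectors.
#' @param universe Character vector.
#' @param alternative Passed to [stats::fisher.test()] (default two-sided).
#' @return A tibble with one row per annotation set: `set`, `n_set`,
#'   `overlap`, `odds_ratio`, `p_value`, `adj_p`, ordered by `p_value`.
#' @export
fisher_enrichment <- function(query, annotation_sets, universe,
                              alternative = "two.sided") {
  query <- unique(query)
  universe <- unique(universe)
  check_subsets(c(list(query), annotation_sets), universe)
  res <- purrr::imap_dfr(annotation_sets, function(s, nm) {
    s <- unique(s)
    a <- length(intersect(query, s))
    b <- length(setdiff(query, s))
    c_ <- length(setdiff(s, query))
    d <- length(universe) - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2), alternative = alternative)
    tibble(set = nm, n_set = length(s), overlap = a,
           odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  res |>
    mutate(adj_p = p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$p_value, .data$set)
}

#' Module-overlap matrix between two coexpression networks
#'
#' All-pairs one-sided Fisher's exact tests between the modules of two
#' networks, with BH adjustment applied jointly over every pair. A pair is
#' significant when its adjusted p-value is below `alpha`. The per-column
#' summary normalizes by column: the proportion of row modules each column
#' module significantly overlaps.
#'
#' @param mods_a,mods_b Named lists of character vectors (the modules of
#'   networks A and B; A indexes rows, B columns).
#' @param universe Character vector (conventionally the union of genes in
#'   either network's input).
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @return A `cellsig_module_overlap` object: list with `adj_p` (matrix of
#'   BH-adjusted p-values), `significant` (logical matrix),
#'   `column_summary` (named proportions in `[0, 1]`), `pairs` (long
#'   tibble) and `alpha`.
#' @export
module_overlap <- function(mods_a, mods_b, universe, alpha = 0.05) {
  universe <- unique(universe)
  check_subsets(c(mods_a, mods_b), universe)
  grid <- tidyr::expand_grid(module_a = names(mods_a), module_b = names(mods_b))
  pairs <- purrr::pmap_dfr(grid, function(module_a, module_b) {
    sa <- unique(mods_a[[module_a]]); sb <- unique(mods_b[[module_b]])
    a <- length(intersect(sa, sb))
    tab <- matrix(c(a, length(setdiff(sa, sb)), length(setdiff(sb, sa)),
                    length(universe) - length(union(sa, sb))), 2)
    tibble(module_a = module_a, module_b = module_b, overlap = a,
           p_value = fisher.test(tab, alternative = "greater")$p.value)
  })
  pairs <- mutate(pairs, adj_p = p.adjust(.data$p_value, method = "BH"),
                  significant = .data$adj_p < alpha)
  adj_p <- matrix(pairs$adj_p, nrow = length(mods_a), byrow = TRUE,
                  dimnames = list(names(mods_a), names(mods_b)))
  sig <- adj_p < alpha
  structure(
    list(adj_p = adj_p, significant = sig,
         column_summary = colSums(sig) / nrow(sig),
         pairs = pairs, alpha = alpha),
    class = "cellsig_module_overlap"
  )
}

#' @export
print.cellsig_module_overlap <- function(x, ...) {
  cat(sprintf("<cellsig_module_overlap> %d x %d modules, %d significant at BH < %g\n",
              nrow(x$adj_p), ncol(x$adj_p), sum(x$significant), x$alpha))
  invisible(x)
}

#' @export
tidy.cellsig_module_overlap <- function(x, ...) x$pairs

#' @export
glance.cellsig_module_overlap <- function(x, ...) {
  tibble(n_modules_a = nrow(x$adj_p), n_modules_b = ncol(x$adj_p),
         n_significant = sum(x$significant),
         prop_significant = mean(x$significant), alpha = x$alpha)
}
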