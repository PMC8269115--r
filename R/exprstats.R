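# Expression statistics: median-of-ratios normalization, rank-based
# differential expression, multiple-testing adjustment, hypergeometric
# gene-set overrepresentation, gene-set shift tests, and the PCA +
# hierarchical-clustering embedding used for subtype discovery.

#' Median-of-ratios size-factor normalization
#'
#' Size factor of sample j is the median over genes of
#' `count_gj / geometric_mean_g`, genes with a zero count in any sample
#' excluded from the median; factors are rescaled to geometric mean 1 and
#' normalized counts are `count / factor`. Normalizing an
#' already-normalized matrix yields factors of exactly 1.
#'
#' @param counts Wide count tibble (`gene_id` + one numeric column per
#'   sample) or matrix.
#' @param pseudocount Optional pseudocount added before computing factors,
#'   for matrices without an all-nonzero gene (the counts themselves are
#'   not shifted).
#' @return A list of class `lps_norm` with `normalized` (wide tibble) and
#'   `size_factors` (tibble: sample, size_factor).
#' @export
size_factor_normalize <- function(counts, pseudocount = 0) {
  m <- expr_matrix(counts)
  if (ncol(m) < 2) stop_lps("size_factor_normalize: need at least 2 samples")
  if (any(m < 0)) stop_lps("size_factor_normalize: negative counts")
  mm <- m + pseudocount
  keep <- rowSums(mm > 0) == ncol(mm)
  if (!any(keep)) {
    stop_lps("size_factor_normalize: no gene is nonzero in every sample; ",
             "consider the `pseudocount` argument")
  }
  logs <- log(mm[keep, , drop = FALSE])
  geo <- rowMeans(logs)
  sf <- apply(exp(logs - geo), 2, median)
  sf <- sf / exp(mean(log(sf))) # geometric mean 1 => exact idempotence
  norm <- sweep(m, 2, sf, "/")
  structure(list(
    normalized = expr_tibble(norm),
    size_factors = tibble(sample = colnames(m), size_factor = unname(sf))
  ), class = "lps_norm")
}

#' @export
print.lps_norm <- function(x, ...) {
  cat("<lps_norm> ", nrow(x$normalized), " genes x ",
      nrow(x$size_factors), " samples; size factors in [",
      round(min(x$size_factors$size_factor), 3), ", ",
      round(max(x$size_factors$size_factor), 3), "]\n", sep = "")
  invisible(x)
}

#' Rank-based differential expression between two groups
#'
#' Per gene, a two-sided Wilcoxon rank-sum test on log2(normalized + 1):
#' exact null enumeration when both group sizes are at most 10 and the
#' data are untied, normal approximation with tie correction otherwise.
#' The log2 fold change is `log2((mean_B + 1) / (mean_A + 1))` on
#' normalized counts (antisymmetric under group swap). P-values are
#' BH-adjusted. The method is deliberately rank-based (method tag
#' `"wilcoxon"`), not a negative-binomial GLM.
#'
#' @param normalized Wide normalized expression tibble or matrix.
#' @param groups Tibble with `sample` and `group` columns.
#' @param group_a,group_b Group labels; fold changes are B over A.
#' @return An object of class `lps_de`; see [tidy()] / [glance()].
#' @export
differential_expression <- function(normalized, groups, group_a, group_b) {
  m <- expr_matrix(normalized)
  sa <- groups$sample[groups$group == group_a]
  sb <- groups$sample[groups$group == group_b]
  sa <- intersect(sa, colnames(m))
  sb <- intersect(sb, colnames(m))
  if (length(sa) < 3 || length(sb) < 3) {
    stop_lps("differential_expression: need at least 3 samples per group (",
             group_a, ": ", length(sa), ", ", group_b, ": ", length(sb), ")")
  }
  la <- log2p1(m[, sa, drop = FALSE])
  lb <- log2p1(m[, sb, drop = FALSE])
  exact_ok <- length(sa) <= 10 && length(sb) <= 10
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    if (sd(c(xa, xb)) == 0) {
      return(list(stat = NA_real_, p = 1))
    }
    wt <- suppressWarnings(
      wilcox.test(xb, xa, alternative = "two.sided", exact = exact_ok,
                  correct = TRUE)
    )
    list(stat = unname(wt$statistic), p = wt$p.value)
  })
  tab <- tibble(
    gene_id = rownames(m),
    log2_fc = unname(log2((rowMeans(m[, sb, drop = FALSE]) + 1) /
                            (rowMeans(m[, sa, drop = FALSE]) + 1))),
    statistic = purrr::map_dbl(res, "stat"),
    p.value = purrr::map_dbl(res, "p")
  )
  tab$p.adjusted <- p.adjust(tab$p.value, method = "BH")
  structure(list(table = tab, method = "wilcoxon",
                 group_a = group_a, group_b = group_b,
                 n_a = length(sa), n_b = length(sb)),
            class = "lps_de")
}

#' @export
print.lps_de <- function(x, ...) {
  cat("<lps_de> ", x$group_b, " vs ", x$group_a, " (", x$method, "), ",
      nrow(x$table), " genes; ", sum(x$table$p.adjusted < 0.05),
      " at adjusted p < 0.05\n", sep = "")
  invisible(x)
}

#' Multiple-testing adjustment
#'
#' Standard step-up Benjamini-Hochberg or Bonferroni (`min(1, m * p)`);
#' output is order-preserving and within `[p, 1]`.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values.
#' @export
multiple_test_adjust <- function(pvals, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop_lps("multiple_test_adjust: p-values must be in [0, 1]")
  }
  p.adjust(pvals, method = method)
}

#' Hypergeometric gene-set overrepresentation
#'
#' Upper-tail hypergeometric p per gene set for the overlap between the
#' query and the set within the universe, BH-adjusted across sets. Sets
#' with an empty intersection with the universe are skipped with a
#' warning.
#'
#' @param query Character vector of genes (must lie within `universe`).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector: the gene universe.
#' @return Tibble: set, overlap, set_size, universe_size, p.value,
#'   p.adjusted.
#' @export
hypergeometric_enrichment <- function(query, gene_sets, universe) {
  query <- unique(query)
  universe <- unique(universe)
  extra <- setdiff(query, universe)
  if (length(extra) > 0) {
    stop_lps("hypergeometric_enrichment: query genes outside the universe: ",
             paste(head(extra, 5), collapse = ", "))
  }
  rows <- purrr::imap(gene_sets, function(set, name) {
    s <- intersect(unique(set), universe)
    if (length(s) == 0) {
      warn(paste0("hypergeometric_enrichment: set '", name,
                  "' has no genes in the universe; skipped"))
      return(NULL)
    }
    k <- length(intersect(query, s))
    p <- phyper(k - 1, length(s), length(universe) - length(s),
                length(query), lower.tail = FALSE)
    tibble(set = name, overlap = k, set_size = length(s),
           universe_size = length(universe), p.value = p)
  })
  out <- bind_rows(rows)
  if (nrow(out) > 0) out$p.adjusted <- p.adjust(out$p.value, method = "BH")
  out
}

#' Gene-set expression-shift test between two groups
#'
#' Per gene set, each sample is scored by its mean log2(normalized + 1)
#' over the set's measured genes; scores are compared between groups with
#' a two-sided Wilcoxon rank-sum test and Bonferroni-adjusted across sets.
#' Fully tied scores (e.g. identical groups) give p = 1. The result for a
#' set depends only on genes inside that set.
#'
#' @param normalized Wide normalized expression tibble or matrix.
#' @param gene_sets Named list of character vectors.
#' @param groups Tibble with `sample` and `group`.
#' @param group_a,group_b Group labels.
#' @return Tibble: set, n_genes, delta (mean score B - A), p.value,
#'   p.adjusted.
#' @export
geneset_shift_test <- function(normalized, gene_sets, groups,
                               group_a, group_b) {
  m <- expr_matrix(normalized)
  sa <- intersect(groups$sample[groups$group == group_a], colnames(m))
  sb <- intersect(groups$sample[groups$group == group_b], colnames(m))
  lm2 <- log2p1(m)
  rows <- purrr::imap(gene_sets, function(set, name) {
    g <- intersect(unique(set), rownames(m))
    if (length(g) < 2) {
      stop_lps("geneset_shift_test: set '", name,
               "' has fewer than 2 measured genes")
    }
    score_a <- colMeans(lm2[g, sa, drop = FALSE])
    score_b <- colMeans(lm2[g, sb, drop = FALSE])
    p <- if (sd(c(score_a, score_b)) == 0) 1 else {
      suppressWarnings(wilcox.test(score_b, score_a,
                                   alternative = "two.sided"))$p.value
    }
    tibble(set = name, n_genes = length(g),
           delta = mean(score_b) - mean(score_a), p.value = p)
  })
  out <- bind_rows(rows)
  out$p.adjusted <- p.adjust(out$p.value, method = "bonferroni")
  out
}

#' PCA embedding and hierarchical clustering of samples
#'
#' Genes are z-scored on log2(x + 1) values (zero-variance genes dropped
#' with a warning); principal components come from the eigen-decomposition
#' of the sample covariance, sorted by variance explained, each component's
#' sign fixed so its largest-magnitude gene loading is positive. Samples
#' are then clustered (Euclidean distance, Ward linkage) and the tree cut
#' at `k`.
#'
#' @param x Wide expression tibble or matrix (counts or normalized).
#' @param genes Optional gene subset.
#' @param k Number of clusters.
#' @param linkage Agglomeration method (default `"ward.D2"`).
#' @return Object of class `lps_embed`: `scores` (sample, PCs, cluster),
#'   `var_explained`, `loadings`, `hclust`, `k`.
#' @export
embed_and_cluster <- function(x, genes = NULL, k = 2, linkage = "ward.D2") {
  m <- expr_matrix(x)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(m))
    if (length(miss) == length(genes)) {
      stop_lps("embed_and_cluster: none of the requested genes are measured")
    }
    m <- m[intersect(genes, rownames(m)), , drop = FALSE]
  }
  n <- ncol(m)
  if (k > n) stop_lps("embed_and_cluster: k = ", k, " exceeds ", n, " samples")
  lm2 <- log2p1(m)
  sds <- apply(lm2, 1, sd)
  if (any(sds == 0)) {
    warn(paste0("embed_and_cluster: dropping ", sum(sds == 0),
                " zero-variance gene(s)"))
    lm2 <- lm2[sds > 0, , drop = FALSE]
    if (nrow(lm2) == 0) stop_lps("embed_and_cluster: all genes have zero variance")
  }
  z <- t(scale(t(lm2)))           # gene-wise z-scores; samples x genes next
  zs <- t(z)
  pc <- prcomp(zs, center = FALSE, scale. = FALSE)
  # deterministic sign: largest-|loading| gene positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  hc <- hclust(dist(zs), method = linkage)
  cl <- cutree(hc, k = k)
  scores <- as_tibble(pc$x, rownames = "sample")
  scores$cluster <- unname(cl[scores$sample])
  structure(list(scores = scores, var_explained = ve,
                 loadings = pc$rotation, hclust = hc, k = k),
            class = "lps_embed")
}

#' @export
print.lps_embed <- function(x, ...) {
  cat("<lps_embed> ", nrow(x$scores), " samples, k = ", x$k,
      "; PC1/PC2 variance: ",
      paste(round(100 * x$var_explained[1:min(2, length(x$var_explained))], 1),
            collapse = "% / "), "%\n", sep = "")
  invisible(x)
}
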