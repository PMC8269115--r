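# Normalization, differential expression, multiple testing, enrichment,
# gene-set shift tests, and the embedding/clustering primitive.

test_that("size factors recover pure depth effects and ignore gene order", {
  set.seed(1)
  base <- rpois(50, 50) + 1
  two <- toy_matrix(cbind(base, base))
  sf <- size_factor_normalize(two)$size_factors$size_factor
  expect_equal(sf, c(1, 1))
  doubled <- toy_matrix(cbind(a = base, b = 2 * base))
  sf2 <- size_factor_normalize(doubled)$size_factors$size_factor
  expect_equal(sf2[2] / sf2[1], 2, tolerance = 1e-12)
  shuffled <- doubled[sample(nrow(doubled)), ]
  expect_equal(size_factor_normalize(shuffled)$size_factors$size_factor, sf2)
})

test_that("normalization is idempotent and flags all-zero-row failure", {
  set.seed(2)
  m <- toy_matrix(matrix(rpois(200, 30) + 1, ncol = 4))
  n1 <- size_factor_normalize(m)
  n2 <- size_factor_normalize(n1$normalized)
  expect_equal(n2$size_factors$size_factor, rep(1, 4), tolerance = 1e-9)
  zeroy <- toy_matrix(matrix(c(0, 5, 3, 0), nrow = 2))
  expect_error(size_factor_normalize(zeroy), "pseudocount")
  expect_s3_class(size_factor_normalize(zeroy, pseudocount = 0.5), "lps_norm")
})

test_that("the exact Wilcoxon path reproduces the enumerated p-value", {
  m <- toy_matrix(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1),
                  samples = sprintf("s%d", 1:6))
  groups <- tibble::tibble(sample = sprintf("s%d", 1:6),
                           group = rep(c("A", "B"), each = 3))
  de <- differential_expression(m, groups, "A", "B")
  expect_equal(de$table$p.value, 0.1)
  expect_gt(de$table$log2_fc, 0)
  # antisymmetry under group swap
  de_rev <- differential_expression(m, groups, "B", "A")
  expect_equal(de_rev$table$log2_fc, -de$table$log2_fc)
  expect_equal(de_rev$table$p.value, de$table$p.value)
})

test_that("Wilcoxon matches the permutation-enumeration oracle on small groups", {
  set.seed(3)
  for (sizes in list(c(3, 3), c(4, 6), c(5, 8), c(8, 8))) {
    x <- round(rnorm(sizes[1], 10), 4)
    y <- round(rnorm(sizes[2], 11), 4)
    counts <- matrix(2^c(x, y) - 1, nrow = 1)
    m <- toy_matrix(counts, samples = sprintf("s%d", seq_len(sum(sizes))))
    groups <- tibble::tibble(sample = sprintf("s%d", seq_len(sum(sizes))),
                             group = rep(c("A", "B"), sizes))
    de <- differential_expression(m, groups, "A", "B")
    expect_equal(de$table$p.value, oracle_wilcoxon(x, y), tolerance = 1e-12)
  }
})

test_that("constant genes give p = 1 and zero fold change", {
  m <- toy_matrix(matrix(5, nrow = 2, ncol = 8))
  groups <- tibble::tibble(sample = sprintf("s%02d", 1:8),
                           group = rep(c("A", "B"), each = 4))
  de <- differential_expression(m, groups, "A", "B")
  expect_equal(de$table$p.value, c(1, 1))
  expect_equal(de$table$log2_fc, c(0, 0))
})

test_that("tidy and glance summarize a DE fit", {
  set.seed(4)
  m <- toy_matrix(matrix(rpois(800, 40), ncol = 8))
  groups <- tibble::tibble(sample = sprintf("s%02d", 1:8),
                           group = rep(c("A", "B"), each = 4))
  de <- differential_expression(m, groups, "A", "B")
  td <- tidy(de)
  expect_true(all(c("gene_id", "log2_fc", "p.value", "p.adjusted") %in%
                    names(td)))
  expect_true(all(td$p.adjusted >= td$p.value))
  gl <- glance(de)
  expect_identical(gl$n_genes, 100L)
  expect_identical(gl$method, "wilcoxon")
})

test_that("multiple-testing adjustment matches closed forms and the oracle", {
  expect_equal(multiple_test_adjust(c(0.03, 0.5), "bonferroni"), c(0.06, 1))
  p0 <- rep(0.02, 7)
  expect_equal(multiple_test_adjust(p0, "BH"), p0)
  set.seed(5)
  p <- runif(200)
  bh <- multiple_test_adjust(p, "BH")
  expect_equal(bh, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(bh >= p & bh <= 1))
  expect_true(all(diff(bh[order(p)]) >= -1e-12))
  expect_error(multiple_test_adjust(c(0.2, 1.4)), "0, 1")
})

test_that("hypergeometric enrichment matches single-table closed forms", {
  universe <- sprintf("g%02d", 1:20)
  res <- hypergeometric_enrichment(universe[1:10],
                                   list(hit = universe[1:10]), universe)
  expect_equal(res$p.value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_identical(res$overlap, 10L)
  full <- hypergeometric_enrichment(universe, list(all = universe), universe)
  expect_equal(full$p.value, 1)
  # p decreases as the overlap grows at fixed margins
  ps <- vapply(4:10, function(k) {
    q <- c(universe[seq_len(k)], universe[11:20][seq_len(10 - k)])
    hypergeometric_enrichment(q, list(hit = universe[1:10]), universe)$p.value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_warning(
    hypergeometric_enrichment(universe[1:2],
                              list(empty = c("zz1", "zz2")), universe),
    "skipped"
  )
  expect_error(hypergeometric_enrichment(c("zz9"), list(a = universe[1:3]),
                                         universe), "outside")
})

test_that("gene-set shift test detects planted shifts and ignores other genes", {
  groups <- tibble::tibble(sample = sprintf("s%02d", 1:20),
                           group = rep(c("A", "B"), each = 10))
  sets <- list(sig = sprintf("g%02d", 1:5), null = sprintf("g%02d", 6:10))
  hits <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    m <- matrix(rpois(400, 50), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), groups$sample))
    m[1:5, 11:20] <- m[1:5, 11:20] * 4 # 4-fold planted shift
    res <- geneset_shift_test(toy_matrix(m, genes = rownames(m),
                                         samples = colnames(m)),
                              sets, groups, "A", "B")
    if (res$p.value[res$set == "sig"] < 0.01) hits <- hits + 1
    expect_gt(res$p.value[res$set == "null"], 0.01)
    # locality: perturbing genes outside the set leaves the result unchanged
    m2 <- m
    m2[11:20, ] <- m2[11:20, ] + 1000
    res2 <- geneset_shift_test(toy_matrix(m2, genes = rownames(m2),
                                          samples = colnames(m2)),
                               sets, groups, "A", "B")
    expect_equal(res2$p.value, res$p.value)
  }
  expect_gte(hits, 9)
  # identical groups are a guaranteed null
  m <- toy_matrix(matrix(rep(1:10, 8), nrow = 10),
                  samples = sprintf("s%02d", 1:8))
  g8 <- tibble::tibble(sample = sprintf("s%02d", 1:8),
                       group = rep(c("A", "B"), 4))
  res <- geneset_shift_test(m, list(s = sprintf("g%02d", 1:10)), g8, "A", "B")
  expect_equal(res$p.value, 1)
})

test_that("embedding separates well-separated groups and orders variance", {
  set.seed(6)
  n_g <- 40
  grp_mean <- cbind(matrix(5, n_g, 10), matrix(11, n_g, 10))
  m <- 2^(grp_mean + matrix(rnorm(n_g * 20, 0, 0.5), n_g)) - 1
  emb <- embed_and_cluster(toy_matrix(m), k = 2)
  cl <- tidy(emb)$cluster
  expect_true(length(unique(cl[1:10])) == 1 &&
                length(unique(cl[11:20])) == 1 && cl[1] != cl[20])
  expect_true(all(diff(emb$var_explained) <= 1e-12))
  expect_true(sum(emb$var_explained) <= 1 + 1e-9)
  expect_error(embed_and_cluster(toy_matrix(m), k = 25), "exceeds")
})

test_that("clustering is invariant to sample order and duplication", {
  set.seed(7)
  n_g <- 30
  m <- 2^(cbind(matrix(5, n_g, 5), matrix(9, n_g, 6)) +
            matrix(rnorm(n_g * 11, 0, 0.4), n_g)) - 1
  tm <- toy_matrix(m)
  base <- tidy(embed_and_cluster(tm, k = 2))
  perm <- c(1, sample(2:12, 11))
  reord <- tm[, perm]
  reord_cl <- tidy(embed_and_cluster(reord, k = 2))
  joined <- dplyr::inner_join(base, reord_cl, by = "sample",
                              suffix = c("_a", "_b"))
  tab <- table(joined$cluster_a, joined$cluster_b)
  expect_true(all(rowSums(tab > 0) == 1)) # one-to-one label mapping
  # duplicating every sample duplicates the labels
  dup <- m[, rep(1:11, each = 2)]
  colnames(dup) <- sprintf("s%02d", 1:22)
  dup_cl <- tidy(embed_and_cluster(toy_matrix(dup, genes = rownames(m),
                                              samples = colnames(dup)),
                                   k = 2))$cluster
  expect_equal(dup_cl[seq(1, 21, 2)], dup_cl[seq(2, 22, 2)])
  expect_warning(
    embed_and_cluster(toy_matrix(rbind(m, 7)), k = 2),
    "zero-variance"
  )
})
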