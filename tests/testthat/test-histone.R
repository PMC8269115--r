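# RD-HIST scoring, HIST+/HIST- classification, fold changes, and
# phenotype correlations.

test_that("scores reduce to closed forms on uniform expression", {
  catalog <- rd_hist_catalog()
  v <- 31
  m <- toy_matrix(matrix(v, nrow = 66, ncol = 4), genes = catalog$gene_id)
  sc <- histone_score(m, catalog)
  expect_equal(sc$overall$score, rep(log2(v + 1), 4))
  expect_equal(unique(sc$families$score), log2(v + 1))
  # doubling every catalog gene raises scores by ~1 at large counts
  sc2 <- histone_score(toy_matrix(matrix(2 * v, 66, 4),
                                  genes = catalog$gene_id), catalog)
  expect_equal(sc2$overall$score - sc$overall$score, rep(1, 4),
               tolerance = 0.05)
})

test_that("overall score is the size-weighted mean of family scores", {
  set.seed(1)
  catalog <- rd_hist_catalog()
  m <- toy_matrix(matrix(rpois(66 * 6, 40), nrow = 66),
                  genes = catalog$gene_id)
  sc <- histone_score(m, catalog)
  fam <- sc$families
  for (s in unique(fam$sample)) {
    f <- fam[fam$sample == s, ]
    expect_equal(sum(f$score * f$n_genes) / sum(f$n_genes),
                 sc$overall$score[sc$overall$sample == s], tolerance = 1e-9)
  }
})

test_that("scores ignore non-catalog genes and warn about missing ones", {
  set.seed(2)
  catalog <- rd_hist_catalog()
  base <- matrix(rpois(66 * 4, 40), nrow = 66)
  extra <- matrix(rpois(40, 1000), nrow = 10)
  m1 <- toy_matrix(base, genes = catalog$gene_id)
  m2 <- toy_matrix(rbind(base, extra),
                   genes = c(catalog$gene_id, sprintf("other%02d", 1:10)))
  expect_equal(histone_score(m1, catalog)$overall,
               histone_score(m2, catalog)$overall)
  expect_warning(histone_score(m1[-1, ], catalog), "not measured")
})

test_that("subtype recovery matches planted labels at the study group sizes", {
  for (s in 1:3) {
    sim <- simulate_cohort(quick_config(seed = 200 + s))
    nm <- size_factor_normalize(sim$cohort$counts)
    dd <- sim$cohort$sample_info$sample[sim$cohort$sample_info$group == "DD"]
    sub <- classify_hist_subtype(nm$normalized, rd_hist_catalog(), dd)
    truth <- sim$truth$subtypes
    joined <- dplyr::inner_join(tidy(sub), truth, by = "sample")
    expect_equal(mean(joined$label == joined$hist_label), 1)
    # label rule: the higher-scoring cluster is HIST+DD
    means <- joined |>
      dplyr::group_by(label) |>
      dplyr::summarise(m = mean(score), .groups = "drop")
    expect_gt(means$m[means$label == "HIST+DD"],
              means$m[means$label == "HIST-DD"])
    # deterministic relabeling: same input, same output
    sub2 <- classify_hist_subtype(nm$normalized, rd_hist_catalog(), dd)
    expect_identical(tidy(sub), tidy(sub2))
  }
  expect_error(classify_hist_subtype(toy_matrix(matrix(1, 5, 3)),
                                     rd_hist_catalog(), c("s01", "s02", "s03")),
               "at least 4")
})

test_that("classification is chance-level when the TF effect is absent", {
  acc <- vapply(1:20, function(s) {
    sim <- simulate_cohort(quick_config(seed = 300 + s, beta_tf_hist = 0))
    nm <- size_factor_normalize(sim$cohort$counts)
    dd <- sim$cohort$sample_info$sample[sim$cohort$sample_info$group == "DD"]
    sub <- classify_hist_subtype(nm$normalized, rd_hist_catalog(), dd)
    joined <- dplyr::inner_join(tidy(sub), sim$truth$subtypes, by = "sample")
    mean(joined$label == joined$hist_label)
  }, numeric(1))
  expect_gt(mean(acc), 0.35)
  expect_lt(mean(acc), 0.65)
})

test_that("classification accuracy is non-decreasing in the TF effect", {
  acc_at <- function(beta) {
    mean(vapply(1:10, function(s) {
      sim <- simulate_cohort(quick_config(seed = 500 + s, beta_tf_hist = beta))
      nm <- size_factor_normalize(sim$cohort$counts)
      dd <- sim$cohort$sample_info$sample[sim$cohort$sample_info$group == "DD"]
      sub <- classify_hist_subtype(nm$normalized, rd_hist_catalog(), dd)
      joined <- dplyr::inner_join(tidy(sub), sim$truth$subtypes, by = "sample")
      mean(joined$label == joined$hist_label)
    }, numeric(1)))
  }
  accs <- vapply(c(0.25, 0.5, 1), acc_at, numeric(1))
  expect_true(all(diff(accs) >= -0.02)) # slack for saturation at high beta
  expect_gte(accs[3], 0.95)
})

test_that("classification survives depth rescaling of the raw counts", {
  sim <- simulate_cohort(quick_config(seed = 210))
  dd <- sim$cohort$sample_info$sample[sim$cohort$sample_info$group == "DD"]
  counts <- sim$cohort$counts
  nm1 <- size_factor_normalize(counts)
  scaled <- counts
  for (j in seq_along(dd)) {
    scaled[[dd[j]]] <- scaled[[dd[j]]] * (j %% 3 + 1)
  }
  nm2 <- size_factor_normalize(scaled)
  l1 <- tidy(classify_hist_subtype(nm1$normalized, rd_hist_catalog(), dd))
  l2 <- tidy(classify_hist_subtype(nm2$normalized, rd_hist_catalog(), dd))
  expect_equal(l1$label, l2$label)
})

test_that("gene-set fold change reduces to identities and recovers the plant", {
  catalog <- rd_hist_catalog()
  m <- toy_matrix(matrix(rep(c(100, 100, 1000, 1000), each = 66), nrow = 66),
                  genes = catalog$gene_id)
  same <- geneset_fold_change(m, catalog$gene_id, c("s01", "s02"),
                              c("s01", "s02"))
  expect_equal(same$mean_fc, 1)
  tenx <- geneset_fold_change(m, catalog$gene_id, c("s01", "s02"),
                              c("s03", "s04"))
  expect_equal(tenx$mean_fc, 10, tolerance = 0.02)
  expect_identical(tenx$n_genes_used, 66L)
  expect_error(geneset_fold_change(m, character(), "s01", "s02"), "empty")
  # near-noiseless simulation: recovered mean FC within 20% of the planted
  # expectation (8 unamplified + 5 nine-fold-elevated DD samples over WD)
  cfg <- quick_config(seed = 220, sigma_expr = 0.05, amp_sdlog = 0.05,
                      tf_extra_base = 0, lib_size_sdlog = 0,
                      tf_amp_copies_histpos = 18, cn_expr_slope = 1,
                      beta_tf_hist = 1)
  sim <- simulate_cohort(cfg)
  nm <- size_factor_normalize(sim$cohort$counts, pseudocount = 0.5)
  info <- sim$cohort$sample_info
  fc <- geneset_fold_change(nm$normalized, sim$truth$catalog$gene_id,
                            info$sample[info$group == "WD"],
                            info$sample[info$group == "DD"],
                            min_detect = 0)
  planted <- (8 + 5 * (18 / 2)^1) / 13
  expect_lt(abs(fc$mean_fc - planted) / planted, 0.2)
})

test_that("phenotype correlation handles exact, null and degenerate inputs", {
  scores <- tibble::tibble(sample = sprintf("s%02d", 1:24),
                           score = seq(2, 9, length.out = 24))
  ph <- tibble::tibble(sample = scores$sample,
                       mitotic_index = 3 * scores$score + 1,
                       group = "DD")
  res <- phenotype_correlation(scores, ph, "mitotic_index")
  expect_equal(res$estimate, 1, tolerance = 1e-12)
  expect_lt(res$p.value, 1e-20)
  expect_identical(res$n, 24L)
  # normals are excluded by contract
  ph_norm <- ph
  ph_norm$group[1:10] <- "normal"
  expect_identical(phenotype_correlation(scores, ph_norm, "mitotic_index")$n,
                   14L)
  # missing values are pairwise-dropped and reported
  ph_na <- ph
  ph_na$mitotic_index[1:4] <- NA
  res_na <- phenotype_correlation(scores, ph_na, "mitotic_index")
  expect_identical(res_na$n, 20L)
  expect_identical(res_na$n_dropped, 4L)
  expect_error(phenotype_correlation(scores[1:2, ], ph[1:2, ],
                                     "mitotic_index"), "fewer than 3")
  # independent phenotype: |R| < 0.4 in at least 90% of 100 null draws
  hits <- vapply(1:100, function(s) {
    set.seed(600 + s)
    phr <- tibble::tibble(sample = scores$sample, v = rnorm(24), group = "DD")
    abs(phenotype_correlation(scores, phr, "v")$estimate) < 0.4
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the WD high-histone cross-check flags but never relabels", {
  sim <- simulate_cohort(quick_config(seed = 230))
  nm <- size_factor_normalize(sim$cohort$counts)
  info <- sim$cohort$sample_info
  dd <- info$sample[info$group == "DD"]
  wd <- info$sample[info$group == "WD"]
  sub <- classify_hist_subtype(nm$normalized, rd_hist_catalog(), dd)
  sc <- histone_score(nm$normalized, rd_hist_catalog())$overall
  before <- tidy(sub)
  flagged <- flag_wd_high_histone(sc, sub, wd)
  expect_identical(tidy(sub), before)
  expect_true(all(flagged$sample %in% wd))
  # a WD sample pushed above the HIST+ minimum is flagged
  sc_boost <- sc
  sc_boost$score[sc_boost$sample == wd[1]] <- max(sc$score) + 1
  expect_true(wd[1] %in% flag_wd_high_histone(sc_boost, sub, wd)$sample)
})
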