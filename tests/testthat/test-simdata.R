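# Synthetic cohort generator: determinism, planted-parameter fidelity,
# catalog structure, and the statistical couplings downstream stages rely on.

test_that("one seed gives a bit-identical cohort and ground truth", {
  a <- simulate_cohort(quick_config(seed = 42))
  b <- simulate_cohort(quick_config(seed = 42))
  expect_identical(a$cohort$counts, b$cohort$counts)
  expect_identical(a$cohort$depth_tumor, b$cohort$depth_tumor)
  expect_identical(a$cohort$sites, b$cohort$sites)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(quick_config(seed = 43))
  expect_false(identical(a$cohort$counts, c$cohort$counts))
})

test_that("cohort satisfies its structural invariants", {
  sim <- simulate_cohort(quick_config(seed = 5))
  co <- sim$cohort
  m <- as.matrix(co$counts[-1])
  expect_true(all(m >= 0))
  expect_setequal(co$counts$gene_id, co$annotation$gene_id)
  tumors <- co$sample_info$sample[co$sample_info$group != "normal"]
  expect_setequal(unique(co$depth_tumor$sample), tumors)
  expect_setequal(unique(co$depth_normal$sample), tumors)
  # subtype truth partitions the tumor samples
  truth <- sim$truth$subtypes
  expect_setequal(truth$sample[truth$group != "normal"], tumors)
  expect_true(all(truth$hist_label[truth$group == "DD"] %in%
                    c("HIST-DD", "HIST+DD")))
  # every truth id exists in the cohort
  expect_true(all(sim$truth$somatic_sites$sample %in% tumors))
  expect_true(all(sim$truth$catalog$gene_id %in% co$annotation$gene_id))
})

test_that("histone catalog counts are conserved across the five families", {
  sim <- simulate_cohort(quick_config(seed = 2))
  ann <- sim$cohort$annotation
  fam <- table(ann$hist_family[ann$hist_family != "none"])
  expect_identical(sum(fam), 66L)
  expect_identical(sort(names(fam)), c("H1", "H2A", "H2B", "H3", "H4"))
  expect_identical(as.integer(fam[c("H1", "H2A", "H2B", "H3", "H4")]),
                   c(6L, 16L, 18L, 15L, 11L))
  # arbitrary sizes conserve the total too
  ids <- lipodriver:::hist_gene_ids(40)
  expect_identical(nrow(ids), 40L)
  expect_identical(length(unique(ids$family)), 5L)
})

test_that("realized amplicon amplitude matches the group means over 50 tumors", {
  cfg <- quick_config(seed = 11, n_wd = 25, n_histneg_dd = 13,
                      n_histpos_dd = 12,
                      driver_amp_copies_wd = 11.8, driver_amp_copies_dd = 15.5)
  cnv <- simulate_copy_number(cfg)
  seg <- cnv$true_segments[cnv$true_segments$kind == "driver_locus", ]
  grp <- cnv$samples[match(seg$sample, cnv$samples$sample), "group", drop = TRUE]
  for (g in c("WD", "DD")) {
    x <- seg$copies[grp == g]
    target <- if (g == "WD") 11.8 else 15.5
    expect_lt(abs(mean(x) - target), 2 * sd(x) / sqrt(length(x)))
  }
  # DD stochastically dominates WD when the configured means differ
  expect_gt(mean(seg$copies[grp == "DD"]), mean(seg$copies[grp == "WD"]))
  q <- seq(0.1, 0.9, 0.2)
  expect_true(all(quantile(seg$copies[grp == "DD"], q) >
                    quantile(seg$copies[grp == "WD"], q)))
})

test_that("an all-diploid configuration plants no copy-number change", {
  cfg <- quick_config(seed = 3, driver_amp_copies_wd = 2,
                      driver_amp_copies_dd = 2, tf_amp_copies_histpos = 2,
                      tf_extra_base = 0, passenger_rate_wd = 0,
                      passenger_rate_histneg = 0, passenger_rate_histpos = 0)
  cnv <- simulate_copy_number(cfg)
  expect_true(all(cnv$true_segments$copies == 2))
  for (s in unique(cnv$depth_tumor$sample)) {
    cp <- true_copy_bins(cnv$true_segments[cnv$true_segments$sample == s, ],
                         cnv$bins)
    expect_true(all(cp == 2))
  }
})

test_that("depth simulation is reproducible and rejects shallow coverage", {
  cfg <- quick_config(seed = 8)
  a <- simulate_copy_number(cfg)
  b <- simulate_copy_number(cfg)
  expect_identical(a$depth_tumor, b$depth_tumor)
  expect_identical(a$depth_normal, b$depth_normal)
  expect_error(quick_config(depth_mean = 5), "depth_mean")
})

test_that("beta = 0 decouples the driver TF from histone expression", {
  cfg <- sim_config(seed = 21, n_wd = 30, n_histneg_dd = 35,
                    n_histpos_dd = 35, n_normal = 3,
                    n_genes = 400, n_tfs = 20, beta_tf_hist = 0)
  sim <- simulate_cohort(cfg)
  # normalized counts: depth variation would otherwise induce a shared
  # library-size component in both profiles
  nm <- size_factor_normalize(sim$cohort$counts)
  m <- as.matrix(nm$normalized[-1])
  rownames(m) <- nm$normalized$gene_id
  hist_ids <- sim$truth$catalog$gene_id
  tf <- log2(m[sim$truth$driver_tf_id, ] + 1)
  hist_mean <- colMeans(log2(m[hist_ids, ] + 1))
  expect_lt(abs(cor(tf, hist_mean)), 0.2)
})

test_that("a strong TF effect couples every family to the driver", {
  cfg <- quick_config(seed = 22, beta_tf_hist = 1, sigma_expr = 0.1)
  sim <- simulate_cohort(cfg)
  m <- as.matrix(sim$cohort$counts[-1])
  rownames(m) <- sim$cohort$counts$gene_id
  tf <- log2(m[sim$truth$driver_tf_id, ] + 1)
  for (fam in unique(sim$truth$catalog$family)) {
    g <- sim$truth$catalog$gene_id[sim$truth$catalog$family == fam]
    expect_gt(cor(tf, colMeans(log2(m[g, ] + 1))), 0.6)
  }
})

test_that("decoupled amplicon passengers show no CN-expression correlation", {
  sim <- simulate_cohort(quick_config(seed = 23, passenger_decouple = TRUE))
  co <- sim$cohort
  dd <- co$sample_info$sample[co$sample_info$group == "DD"]
  segs <- purrr::map_dfr(dd, function(s) {
    cp <- coverage_to_copy(
      co$depth_tumor[co$depth_tumor$sample == s,
                     c("chrom", "start", "end", "depth")],
      co$depth_normal[co$depth_normal$sample == s,
                      c("chrom", "start", "end", "depth")]
    )
    sg <- segment_copy_number(cp, seed = substream_seed(23, s))
    sg$sample <- s
    sg
  })
  res <- expression_cn_correlation(
    segs,
    size_factor_normalize(co$counts)$normalized,
    co$annotation,
    list(chrom = "chr12", start = 30e6, end = 42e6),
    dd
  )
  expect_lt(abs(res$estimate), 0.3)
})

test_that("increasing beta never decreases the median TF-family correlation", {
  med_r <- vapply(c(0, 0.25, 1), function(beta) {
    rs <- vapply(1:20, function(s) {
      sim <- simulate_cohort(quick_config(seed = 100 + s,
                                          beta_tf_hist = beta))
      m <- as.matrix(sim$cohort$counts[-1])
      rownames(m) <- sim$cohort$counts$gene_id
      tf <- log2(m[sim$truth$driver_tf_id, ] + 1)
      fam_r <- vapply(unique(sim$truth$catalog$family), function(fam) {
        g <- sim$truth$catalog$gene_id[sim$truth$catalog$family == fam]
        cor(tf, colMeans(log2(m[g, ] + 1)))
      }, numeric(1))
      median(fam_r)
    }, numeric(1))
    median(rs)
  }, numeric(1))
  # 0.01 slack: correlations saturate near 1 from beta ~ 0.25 on
  expect_true(all(diff(med_r) > -0.01))
  expect_lt(med_r[1], 0.4)
  expect_gt(med_r[3], 0.9)
})

test_that("somatic site counts follow the configured burden rates", {
  # rate zero emits nothing
  cfg0 <- quick_config(seed = 31, mut_rate_wd = 0, mut_rate_dd = 0)
  som0 <- simulate_somatic_reads(cfg0)
  expect_identical(nrow(som0$true_sites), 0L)
  # recovery of 14.1 / 23.5 within 2 SE at 30 tumors per group
  cfg <- quick_config(seed = 32, n_wd = 30, n_histneg_dd = 15,
                      n_histpos_dd = 15)
  som <- simulate_somatic_reads(cfg)
  counts <- table(factor(som$true_sites$sample,
                         levels = build_sample_table(cfg)$sample[1:60]))
  wd <- as.numeric(counts[1:30])
  dd <- as.numeric(counts[31:60])
  expect_lt(abs(mean(wd) - 14.1), 2 * sd(wd) / sqrt(30))
  expect_lt(abs(mean(dd) - 23.5), 2 * sd(dd) / sqrt(30))
  # determinism
  expect_identical(som$sites, simulate_somatic_reads(cfg)$sites)
})

test_that("phenotypes are monotone in histone activity and baseline in normals", {
  cfg <- quick_config(seed = 41)
  sim <- simulate_cohort(cfg)
  act <- sim$truth$activity
  ph0 <- simulate_phenotypes(cfg, act, noise_sd = 0)
  tum <- ph0$group != "normal"
  expect_equal(cor(act$activity[tum], ph0$mitotic_index[tum],
                   method = "spearman"), 1)
  expect_true(all(ph0$mitotic_index[!tum] <= 1.5))
  ph <- simulate_phenotypes(cfg, act)
  expect_true(all(ph$ki67 >= 0 & ph$ki67 <= 100))
  expect_gt(cor(act$activity[tum], ph$mitotic_index[tum]), 0.5)
})

test_that("expression simulation names the sample missing from the copy table", {
  cfg <- quick_config(seed = 51)
  cnv <- simulate_copy_number(cfg)
  cnv$true_segments <- cnv$true_segments[cnv$true_segments$sample != "DD_03", ]
  cnv$depth_tumor <- cnv$depth_tumor[cnv$depth_tumor$sample != "DD_03", ]
  expect_error(simulate_expression(cfg, cnv), "DD_03")
})

test_that("config validation enforces the documented invariants", {
  expect_error(quick_config(n_wd = 0), "n_wd")
  expect_error(quick_config(driver_amp_copies_wd = 16,
                            driver_amp_copies_dd = 12), "driver_amp")
  expect_error(quick_config(beta_tf_hist = -1), "beta_tf_hist")
  expect_error(sim_config(n_genes = 100), "n_genes")
})
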