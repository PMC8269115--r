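# Synthetic multi-omic liposarcoma cohorts with planted ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a chr12-like focal amplicon present in every tumor (higher
# amplitude in DDLPS), a driver transcription factor in its own focal
# segment that is strongly amplified only in histone-high DDLPS, a 66-gene
# replication-dependent histone cluster at normal copy number whose
# expression follows the driver TF, copy-number-decoupled passenger genes
# inside the amplicon, group-specific somatic mutation burdens, and
# proliferation phenotypes tied to histone activity.

# Fixed synthetic genome: four 60-Mb chromosomes. Coordinates 0-based
# half-open. The broad amplicon mimics the MDM2/CDK4 12q13-15 interval,
# the histone cluster mimics 6p22.2 (kept diploid), and the driver-TF
# segment sits just distal to the broad amplicon.
lps_genome <- function() {
  tibble(
    chrom = c("chr1", "chr4", "chr6", "chr12"),
    length = rep(60e6, 4)
  )
}

.regions <- list(
  driver_locus = list(chrom = "chr12", start = 30e6, end = 42e6),
  tf_segment   = list(chrom = "chr12", start = 45e6, end = 50e6),
  tf_gene      = list(chrom = "chr12", start = 46.0e6, end = 46.1e6),
  hist_cluster = list(chrom = "chr6",  start = 25e6, end = 27e6),
  # passenger events are kept out of these intervals so planted structure
  # is never overwritten
  exclude = list(
    tibble(chrom = "chr6", start = 20e6, end = 32e6),
    tibble(chrom = "chr12", start = 25e6, end = 50e6)
  )
)

.hist_family_split <- c(H1 = 6, H2A = 16, H2B = 18, H3 = 15, H4 = 11)

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the analysis is designed for:
#' 11 WDLPS, 8 histone-low DDLPS, 5 histone-high DDLPS and 3 normal tissues;
#' a broad focal amplicon in all tumors with mean amplitude 11.8 copies in
#' WDLPS and 15.5 in DDLPS; somatic burdens of 14.1 (WD) and 23.5 (DD)
#' mutations per tumor; and a 66-gene histone catalog split over the five
#' canonical families (H1:6, H2A:16, H2B:18, H3:15, H4:11).
#'
#' @param seed Integer master seed; every generator derives a named
#'   substream from it.
#' @param n_wd,n_histneg_dd,n_histpos_dd,n_normal Sample counts per group.
#' @param n_genes Total number of genes (must accommodate histone genes,
#'   TFs and amplicon passengers).
#' @param n_tfs Number of transcription factors (the first is the planted
#'   driver).
#' @param n_hist_genes Size of the histone catalog (66 by default).
#' @param driver_amp_copies_wd,driver_amp_copies_dd Mean total copies of the
#'   broad amplicon per group (lognormal extra copies around `mean - 2`).
#' @param tf_amp_copies_histpos Mean total copies of the driver-TF segment
#'   in histone-high DD tumors; must exceed `driver_amp_copies_dd` for the
#'   planted driver to carry the strongest amplification.
#' @param tf_extra_base Mean extra copies of the TF segment in WD and
#'   histone-low DD tumors (near-diploid background gains).
#' @param beta_tf_hist Log2-scale effect of driver-TF expression on histone
#'   gene expression.
#' @param sigma_expr Log2-normal expression noise SD.
#' @param cn_expr_slope Dosage exponent: log2 expression change per log2
#'   copy-number change for copy-number-coupled genes (1 = proportional
#'   dosage).
#' @param mut_rate_wd,mut_rate_dd Poisson mean somatic mutations per tumor.
#' @param depth_mean Mean sequencing depth per bin/site (rejected below 10).
#' @param passenger_decouple If `TRUE` (default), genes inside amplified
#'   intervals other than the driver TF receive no copy-number effect on
#'   expression, emulating the low CN-expression correlations seen for
#'   amplicon passengers.
#' @param bin_size Genomic bin width in bp.
#' @param passenger_rate_wd,passenger_rate_histneg,passenger_rate_histpos
#'   Poisson mean number of random passenger SCNAs per tumor, increasing
#'   with subtype severity.
#' @param passenger_extra_mean Mean extra copies of passenger gains.
#' @param amp_sdlog Lognormal sdlog for amplification amplitudes.
#' @param n_decoy_sites Error-only decoy sites per tumor in the somatic
#'   read simulator.
#' @param lib_size_sdlog Lognormal sdlog of per-sample library size factors.
#' @param expressed_frac Fraction of background genes drawn from the
#'   expressed baseline component.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_wd = 11L, n_histneg_dd = 8L, n_histpos_dd = 5L,
                       n_normal = 3L,
                       n_genes = 1200L, n_tfs = 60L, n_hist_genes = 66L,
                       driver_amp_copies_wd = 11.8,
                       driver_amp_copies_dd = 15.5,
                       tf_amp_copies_histpos = 18,
                       tf_extra_base = 0.5,
                       beta_tf_hist = 1,
                       sigma_expr = 0.3,
                       cn_expr_slope = 1,
                       mut_rate_wd = 14.1,
                       mut_rate_dd = 23.5,
                       depth_mean = 150,
                       passenger_decouple = TRUE,
                       bin_size = 1e6,
                       passenger_rate_wd = 1,
                       passenger_rate_histneg = 2.5,
                       passenger_rate_histpos = 4,
                       passenger_extra_mean = 4,
                       amp_sdlog = 0.25,
                       n_decoy_sites = 150L,
                       lib_size_sdlog = 0.15,
                       expressed_frac = 0.85) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_wd", "n_histneg_dd", "n_histpos_dd", "n_normal",
              "n_genes", "n_tfs", "n_hist_genes")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] != round(cfg[[f]])) {
      stop_lps("sim_config: `", f, "` must be a positive integer")
    }
  }
  if (cfg$driver_amp_copies_dd < cfg$driver_amp_copies_wd) {
    stop_lps("sim_config: driver_amp_copies_dd must be >= driver_amp_copies_wd")
  }
  if (cfg$beta_tf_hist < 0) stop_lps("sim_config: beta_tf_hist must be >= 0")
  if (cfg$depth_mean < 10) {
    stop_lps("sim_config: depth_mean < 10; coverage-ratio estimates would be meaningless")
  }
  n_reserved <- cfg$n_hist_genes + cfg$n_tfs + 40
  if (cfg$n_genes < n_reserved + 50) {
    stop_lps("sim_config: n_genes too small; need at least ",
             n_reserved + 50, " for histone genes, TFs and amplicon passengers")
  }
  invisible(cfg)
}

#' Deterministic sample sheet for a configuration
#'
#' Sample ids, group labels and (ground-truth) histone-high status implied
#' by the config's group sizes; the histone label is truth-side only and
#' never consumed by the analysis stages.
#'
#' @param cfg A [sim_config()].
#' @return Tibble: sample, group, hist_label.
#' @export
build_sample_table <- function(cfg) {
  wd <- sprintf("WD_%02d", seq_len(cfg$n_wd))
  dd <- sprintf("DD_%02d", seq_len(cfg$n_histneg_dd + cfg$n_histpos_dd))
  nm <- sprintf("N_%02d", seq_len(cfg$n_normal))
  tibble(
    sample = c(wd, dd, nm),
    group = c(rep("WD", cfg$n_wd),
              rep("DD", length(dd)),
              rep("normal", cfg$n_normal)),
    hist_label = c(rep(NA_character_, cfg$n_wd),
                   rep("HIST-DD", cfg$n_histneg_dd),
                   rep("HIST+DD", cfg$n_histpos_dd),
                   rep(NA_character_, cfg$n_normal))
  )
}

# histone catalog ids for an arbitrary catalog size, family proportions
# fixed to the 66-gene human cluster split (largest-remainder rounding)
hist_gene_ids <- function(n_hist_genes) {
  prop <- .hist_family_split / sum(.hist_family_split)
  raw <- prop * n_hist_genes
  k <- floor(raw)
  rem <- n_hist_genes - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  fam <- rep(names(.hist_family_split), k)
  tibble(
    gene_id = sprintf("HIST_%s_%02d", fam,
                      unlist(lapply(k, seq_len), use.names = FALSE)),
    family = fam
  )
}

# internal gene table: positions, roles and expression baselines
build_gene_table <- function(cfg) {
  genome <- lps_genome()
  hist <- hist_gene_ids(cfg$n_hist_genes)
  n_hist <- nrow(hist)
  n_locus_pass <- 40L
  n_bg <- cfg$n_genes - n_hist - cfg$n_tfs - n_locus_pass

  with_substream(cfg$seed, "genes", {
    # histone cluster: evenly spaced, diploid locus
    hist_tbl <- tibble(
      gene_id = hist$gene_id,
      chrom = .regions$hist_cluster$chrom,
      start = .regions$hist_cluster$start +
        (seq_len(n_hist) - 1) * floor((.regions$hist_cluster$end -
                                         .regions$hist_cluster$start) / n_hist),
      is_tf = FALSE,
      hist_family = hist$family,
      baseline = rnorm(n_hist, 4.5, 0.8),
      role = "histone"
    )
    hist_tbl$end <- hist_tbl$start + 5e3

    # driver TF + decoys; two decoys dropped inside the broad amplicon to
    # exercise the screen's co-expression filter on amplified non-drivers
    n_decoy <- cfg$n_tfs - 1L
    decoy_chrom <- sample(c("chr1", "chr4"), n_decoy, replace = TRUE)
    decoy_start <- floor(runif(n_decoy, 0, 60e6 - 1e4))
    if (n_decoy >= 2) {
      decoy_chrom[1:2] <- "chr12"
      decoy_start[1:2] <- floor(runif(2, .regions$driver_locus$start,
                                      .regions$driver_locus$end - 1e4))
    }
    expressed <- runif(cfg$n_tfs) < cfg$expressed_frac
    expressed[1] <- TRUE
    tf_tbl <- tibble(
      gene_id = sprintf("TF_%03d", seq_len(cfg$n_tfs)),
      chrom = c(.regions$tf_gene$chrom, decoy_chrom),
      start = c(.regions$tf_gene$start, decoy_start),
      is_tf = TRUE,
      hist_family = "none",
      baseline = ifelse(expressed, rnorm(cfg$n_tfs, 5.5, 1.8), rnorm(cfg$n_tfs, -2, 1)),
      role = c("driver_tf", rep("decoy_tf", n_decoy))
    )
    tf_tbl$baseline[1] <- 5
    tf_tbl$end <- tf_tbl$start + 1e4

    # gene-dense passengers inside the broad amplicon (MDM2/CDK4-like
    # neighbourhood); expression decoupled from CN under the default config
    pass_start <- floor(seq(.regions$driver_locus$start + 1e5,
                            .regions$driver_locus$end - 2e5,
                            length.out = n_locus_pass))
    pass_expressed <- runif(n_locus_pass) < cfg$expressed_frac
    pass_tbl <- tibble(
      gene_id = sprintf("AMP_%03d", seq_len(n_locus_pass)),
      chrom = .regions$driver_locus$chrom,
      start = pass_start,
      is_tf = FALSE,
      hist_family = "none",
      baseline = ifelse(pass_expressed, rnorm(n_locus_pass, 5.5, 1.8),
                        rnorm(n_locus_pass, -2, 1)),
      role = "amplicon_passenger"
    )
    pass_tbl$end <- pass_tbl$start + 1e4

    bg_chrom <- sample(genome$chrom, n_bg, replace = TRUE)
    bg_expressed <- runif(n_bg) < cfg$expressed_frac
    bg_tbl <- tibble(
      gene_id = sprintf("GENE_%04d", seq_len(n_bg)),
      chrom = bg_chrom,
      start = floor(runif(n_bg, 0, 60e6 - 1e4)),
      is_tf = FALSE,
      hist_family = "none",
      baseline = ifelse(bg_expressed, rnorm(n_bg, 5.5, 1.8), rnorm(n_bg, -2, 1)),
      role = "background"
    )
    bg_tbl$end <- bg_tbl$start + 1e4

    bind_rows(hist_tbl, tf_tbl, pass_tbl, bg_tbl) |>
      select("gene_id", "chrom", "start", "end", "is_tf", "hist_family",
             "baseline", "role")
  })
}

bin_grid <- function(bin_size) {
  genome <- lps_genome()
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$length[i] - 1, by = bin_size)
    tibble(chrom = genome$chrom[i], start = starts,
           end = pmin(starts + bin_size, genome$length[i]))
  })
}

# lognormal draws parameterized by their arithmetic mean
rlnorm_mean <- function(n, mean, sdlog) {
  if (mean <= 0) return(rep(0, n))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate true copy-number segments and binned tumor/normal depths
#'
#' Every tumor carries the broad focal amplicon (amplitude drawn from a
#' lognormal around the group mean); histone-high DD tumors additionally
#' amplify the driver-TF segment; random passenger SCNAs are added at a
#' rate increasing with subtype severity. Tumor depth per bin is
#' Poisson(depth_mean * copies / 2); matched normals are Poisson(depth_mean).
#'
#' @param config A [sim_config()].
#' @param samples Optional sample sheet (defaults to the config's).
#' @return A list with `samples`, `bins`, `true_segments` (one row per
#'   planted event: sample, chrom, start, end, copies, kind), `depth_tumor`
#'   and `depth_normal` (long tibbles: sample, chrom, start, end, depth).
#' @export
simulate_copy_number <- function(config, samples = NULL) {
  validate_sim_config(config)
  samples <- samples %||% build_sample_table(config)
  bins <- bin_grid(config$bin_size)
  tumors <- samples[samples$group != "normal", ]

  res <- with_substream(config$seed, "copy_number", {
    purrr::map(seq_len(nrow(tumors)), function(i) {
      smp <- tumors$sample[i]
      grp <- tumors$group[i]
      hist_lab <- tumors$hist_label[i]
      ev <- list()

      amp_mean <- if (grp == "WD") config$driver_amp_copies_wd else config$driver_amp_copies_dd
      # real 12q13-15 amplicons are internally heterogeneous: the broad
      # locus is planted as three sub-segments with independent amplitudes
      # around the same group mean
      brk <- seq(.regions$driver_locus$start, .regions$driver_locus$end,
                 length.out = 4)
      extra3 <- rlnorm_mean(3, amp_mean - 2, config$amp_sdlog)
      if (any(extra3 > 0)) {
        ev$driver <- tibble(
          sample = smp, chrom = .regions$driver_locus$chrom,
          start = brk[1:3], end = brk[2:4],
          copies = 2 + extra3, kind = "driver_locus"
        )
      }

      tf_mean_extra <- if (identical(hist_lab, "HIST+DD")) {
        config$tf_amp_copies_histpos - 2
      } else {
        config$tf_extra_base
      }
      tf_sdlog <- if (identical(hist_lab, "HIST+DD")) config$amp_sdlog else 0.5
      tf_extra <- rlnorm_mean(1, tf_mean_extra, tf_sdlog)
      if (tf_extra > 0) {
        ev$tf <- tibble(
          sample = smp, chrom = .regions$tf_segment$chrom,
          start = .regions$tf_segment$start, end = .regions$tf_segment$end,
          copies = 2 + tf_extra, kind = "tf_gene"
        )
      }

      rate <- switch(grp,
        WD = config$passenger_rate_wd,
        DD = if (identical(hist_lab, "HIST+DD")) config$passenger_rate_histpos
             else config$passenger_rate_histneg
      )
      n_pass <- rpois(1, rate)
      placed <- bind_rows(ev)
      for (k in seq_len(n_pass)) {
        for (try in 1:20) {
          chrom <- sample(lps_genome()$chrom, 1)
          len_bins <- sample(3:8, 1)
          len <- len_bins * config$bin_size
          start <- sample.int(floor((60e6 - len) / config$bin_size), 1) * config$bin_size -
            config$bin_size
          end <- start + len
          excl <- purrr::map_lgl(.regions$exclude, function(z) {
            z$chrom == chrom && overlaps(start, end, z$start, z$end)
          })
          clash <- nrow(placed) > 0 &&
            any(placed$chrom == chrom &
                  overlaps(placed$start - config$bin_size,
                           placed$end + config$bin_size, start, end))
          if (!any(excl) && !clash) {
            copies <- if (runif(1) < 0.7) {
              2 + rlnorm_mean(1, config$passenger_extra_mean, 0.35)
            } else {
              runif(1, 0.5, 1)
            }
            seg <- tibble(sample = smp, chrom = chrom, start = start,
                          end = end, copies = copies, kind = "passenger")
            placed <- bind_rows(placed, seg)
            break
          }
        }
      }
      placed
    })
  })
  true_segments <- bind_rows(res)
  if (nrow(true_segments) == 0) {
    true_segments <- tibble(sample = character(), chrom = character(),
                            start = double(), end = double(),
                            copies = double(), kind = character())
  }

  depth <- with_substream(config$seed, "depths", {
    purrr::map(seq_len(nrow(tumors)), function(i) {
      smp <- tumors$sample[i]
      cp <- true_copy_bins(true_segments[true_segments$sample == smp, ], bins)
      list(
        tumor = tibble(sample = smp, bins,
                       depth = rpois(nrow(bins), config$depth_mean * cp / 2)),
        normal = tibble(sample = smp, bins,
                        depth = rpois(nrow(bins), config$depth_mean))
      )
    })
  })

  list(
    samples = samples,
    bins = bins,
    true_segments = true_segments,
    depth_tumor = bind_rows(purrr::map(depth, "tumor")),
    depth_normal = bind_rows(purrr::map(depth, "normal"))
  )
}

#' True copy number per bin for one sample's planted events
#'
#' Bins not covered by any event are diploid; a bin takes the copy number of
#' the event covering its midpoint.
#'
#' @param segments Planted event table for a single sample.
#' @param bins Bin grid tibble (chrom, start, end).
#' @return Numeric vector of copies, one per bin row.
#' @export
true_copy_bins <- function(segments, bins) {
  cp <- rep(2, nrow(bins))
  if (nrow(segments) == 0) return(cp)
  mid <- (bins$start + bins$end) / 2
  for (j in seq_len(nrow(segments))) {
    hit <- bins$chrom == segments$chrom[j] &
      mid >= segments$start[j] & mid < segments$end[j]
    cp[hit] <- segments$copies[j]
  }
  cp
}

# copy number of the event overlapping each gene (midpoint rule), per sample
gene_copies <- function(gene_table, segments_one_sample) {
  cp <- rep(2, nrow(gene_table))
  if (nrow(segments_one_sample) == 0) return(cp)
  mid <- (gene_table$start + gene_table$end) / 2
  for (j in seq_len(nrow(segments_one_sample))) {
    hit <- gene_table$chrom == segments_one_sample$chrom[j] &
      mid >= segments_one_sample$start[j] & mid < segments_one_sample$end[j]
    cp[hit] <- segments_one_sample$copies[j]
  }
  cp
}

#' Simulate the expression count matrix
#'
#' Log2 expression of the driver TF follows its copy number through a
#' power-law dosage response
#' (`baseline + cn_expr_slope * (log2(copies) - 1) + noise`); each histone gene
#' follows the realized driver-TF expression through `beta_tf_hist`; under
#' `passenger_decouple` every other gene in an amplified interval stays at
#' its baseline (no copy-number effect). Counts are Poisson draws around
#' 2^log2-expression scaled by a lognormal per-sample library factor.
#'
#' @param config A [sim_config()].
#' @param cnv Output of [simulate_copy_number()].
#' @param gene_table Internal gene table (defaults to the config's).
#' @return A list with `counts` (wide tibble, gene_id + one column per
#'   sample), `activity` (per-sample realized driver-TF log2 expression and
#'   histone activity), and `size_factors`.
#' @export
simulate_expression <- function(config, cnv, gene_table = NULL) {
  validate_sim_config(config)
  gene_table <- gene_table %||% build_gene_table(config)
  samples <- cnv$samples %||% build_sample_table(config)
  tumors <- samples$sample[samples$group != "normal"]
  have <- unique(cnv$true_segments$sample)
  covered <- unique(c(have, cnv$depth_tumor$sample))
  missing <- setdiff(tumors, covered)
  if (length(missing) > 0) {
    stop_lps("simulate_expression: no copy-number entry for sample(s): ",
             paste(missing, collapse = ", "))
  }

  driver <- gene_table[gene_table$role == "driver_tf", ]
  tf_base <- driver$baseline[1]
  is_hist <- gene_table$hist_family != "none"

  with_substream(config$seed, "expression", {
    n_g <- nrow(gene_table)
    counts <- matrix(0L, nrow = n_g, ncol = nrow(samples),
                     dimnames = list(gene_table$gene_id, samples$sample))
    sf <- rlnorm(nrow(samples), 0, config$lib_size_sdlog)
    act <- tibble(sample = samples$sample, group = samples$group,
                  tf_log2 = NA_real_, activity = NA_real_)

    for (j in seq_len(nrow(samples))) {
      smp <- samples$sample[j]
      segs <- cnv$true_segments[cnv$true_segments$sample == smp, ]
      cp <- gene_copies(gene_table, segs)
      tf_cp <- cp[gene_table$role == "driver_tf"][1]
      tf_log2 <- tf_base + config$cn_expr_slope * (log2(tf_cp) - 1) +
        rnorm(1, 0, config$sigma_expr)
      activity <- config$beta_tf_hist * (tf_log2 - tf_base)

      mu_log2 <- gene_table$baseline +
        ifelse(is_hist, activity, 0) +
        rnorm(n_g, 0, config$sigma_expr)
      if (!config$passenger_decouple) {
        # couple every gene in an altered interval to its copy number
        mu_log2 <- mu_log2 + config$cn_expr_slope * (log2(cp) - 1)
      }
      # the driver TF row is the realized TF expression that drives the
      # histone genes (noise already included)
      mu_log2[gene_table$role == "driver_tf"] <- tf_log2
      counts[, j] <- rpois(n_g, pmin(2^mu_log2, 1e7) * sf[j])
      act$tf_log2[j] <- tf_log2
      act$activity[j] <- activity
    }

    list(
      counts = expr_tibble(counts),
      activity = act,
      size_factors = tibble(sample = samples$sample, size_factor = sf)
    )
  })
}

#' Simulate paired tumor/normal allele counts at somatic and decoy sites
#'
#' Per tumor the number of true somatic sites is Poisson with the group
#' rate; at true sites the tumor alt fraction is Beta-distributed around
#' 0.3 while the matched normal only shows sequencing error (rate 0.002);
#' decoy sites carry error-level alt reads in both samples.
#'
#' @param config A [sim_config()].
#' @param samples Optional sample sheet.
#' @return A list with `sites` (sample, chrom, pos, ref_t, alt_t, ref_n,
#'   alt_n; positions 1-based) and `true_sites` (sample, chrom, pos).
#' @export
simulate_somatic_reads <- function(config, samples = NULL) {
  validate_sim_config(config)
  samples <- samples %||% build_sample_table(config)
  tumors <- samples[samples$group != "normal", ]
  err <- 0.002

  with_substream(config$seed, "somatic", {
    out <- purrr::map(seq_len(nrow(tumors)), function(i) {
      smp <- tumors$sample[i]
      rate <- if (tumors$group[i] == "WD") config$mut_rate_wd else config$mut_rate_dd
      n_true <- rpois(1, rate)
      n_all <- n_true + config$n_decoy_sites
      chrom <- sample(lps_genome()$chrom, n_all, replace = TRUE)
      pos <- sample.int(60e6, n_all)
      is_true <- rep(c(TRUE, FALSE), c(n_true, config$n_decoy_sites))
      dp_t <- rpois(n_all, config$depth_mean)
      dp_n <- rpois(n_all, config$depth_mean)
      f <- ifelse(is_true, stats::rbeta(n_all, 6, 14), err)
      alt_t <- rbinom(n_all, dp_t, f)
      alt_n <- rbinom(n_all, dp_n, err)
      tibble(
        sample = smp, chrom = chrom, pos = pos,
        ref_t = dp_t - alt_t, alt_t = alt_t,
        ref_n = dp_n - alt_n, alt_n = alt_n,
        is_true = is_true
      )
    })
    all <- bind_rows(out)
    list(
      sites = select(all, -"is_true"),
      true_sites = select(filter(all, .data$is_true), "sample", "chrom", "pos")
    )
  })
}

#' Simulate proliferation phenotypes from true histone activity
#'
#' Mitotic index (per 10 HPF) and Ki67 (%) are noisy monotone functions of
#' the planted per-sample histone activity; normal tissues get baseline
#' values. Noise magnitudes are package defaults (documented in the methods
#' vignette), not literature values.
#'
#' @param config A [sim_config()].
#' @param activity Tibble with `sample`, `group`, `activity` (from
#'   [simulate_expression()]).
#' @param noise_sd Multiplier on the default noise SDs (0 gives noiseless
#'   monotone phenotypes).
#' @return Tibble: sample, mitotic_index, ki67, group.
#' @export
simulate_phenotypes <- function(config, activity, noise_sd = 1) {
  validate_sim_config(config)
  with_substream(config$seed, "phenotypes", {
    n <- nrow(activity)
    tumor <- activity$group != "normal"
    a <- activity$activity
    mitotic <- ifelse(tumor,
                      3 + 7 * a + rnorm(n, 0, 2.5 * noise_sd),
                      abs(rnorm(n, 0.5, 0.3 * noise_sd)))
    ki67 <- ifelse(tumor,
                   5 + 14 * a + rnorm(n, 0, 6 * noise_sd),
                   abs(rnorm(n, 2, 1 * noise_sd)))
    tibble(
      sample = activity$sample,
      mitotic_index = pmax(mitotic, 0),
      ki67 = pmin(pmax(ki67, 0), 100),
      group = activity$group
    )
  })
}

#' Simulate a complete synthetic cohort with ground truth
#'
#' Orchestrates the copy-number, expression, somatic-read and phenotype
#' generators under named substreams of one master seed. Pure: writes
#' nothing (see [write_cohort()]).
#'
#' @param config A [sim_config()].
#' @return A list with `cohort` (class `lps_cohort`: counts, annotation,
#'   sample_info, depth_tumor, depth_normal, sites, phenotypes) and `truth`
#'   (class `lps_truth`: driver TF id, planted segments, subtype labels,
#'   true somatic sites, histone catalog, per-sample activity).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  gene_table <- build_gene_table(config)
  cnv <- simulate_copy_number(config)
  expr <- simulate_expression(config, cnv, gene_table)
  som <- simulate_somatic_reads(config, cnv$samples)
  phen <- simulate_phenotypes(config, expr$activity)

  annotation <- select(gene_table, "gene_id", "chrom", "start", "end",
                       "is_tf", "hist_family")
  cohort <- structure(list(
    counts = expr$counts,
    annotation = annotation,
    sample_info = select(cnv$samples, "sample", "group"),
    depth_tumor = cnv$depth_tumor,
    depth_normal = cnv$depth_normal,
    sites = som$sites,
    phenotypes = phen,
    config = config
  ), class = "lps_cohort")

  truth <- structure(list(
    driver_tf_id = gene_table$gene_id[gene_table$role == "driver_tf"][1],
    tf_baseline = gene_table$baseline[gene_table$role == "driver_tf"][1],
    segments = cnv$true_segments,
    bins = cnv$bins,
    subtypes = cnv$samples,
    somatic_sites = som$true_sites,
    catalog = gene_table[gene_table$hist_family != "none",
                         c("gene_id", "hist_family")] |>
      rename(family = "hist_family"),
    activity = expr$activity,
    gene_table = gene_table
  ), class = "lps_truth")

  list(cohort = cohort, truth = truth)
}

#' @export
print.lps_cohort <- function(x, ...) {
  cat("<lps_cohort> ", nrow(x$counts), " genes x ", nrow(x$sample_info),
      " samples (", sum(x$sample_info$group == "WD"), " WD, ",
      sum(x$sample_info$group == "DD"), " DD, ",
      sum(x$sample_info$group == "normal"), " normal)\n", sep = "")
  invisible(x)
}

#' @export
print.lps_truth <- function(x, ...) {
  cat("<lps_truth> driver:", x$driver_tf_id, "|",
      nrow(x$segments), "planted segments |",
      nrow(x$somatic_sites), "true somatic sites\n")
  invisible(x)
}
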