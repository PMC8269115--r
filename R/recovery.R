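# Ground-truth recovery experiments: seeded end-to-end runs of the
# simulator plus the analysis stages, scored against the planted truth.
# These back the package's calibration claims and the reproduction script.

#' Focal-amplification recovery across seeded cohorts
#'
#' For each cohort: simulate, estimate per-bin copies from the paired
#' depths, segment, call focal amplifications, and score the calls against
#' the planted events. A true event counts as recovered when a passing
#' call overlaps it; a call counts as a false discovery when it overlaps
#' no planted event with extra copies above the call threshold. The
#' segment-mean error compares each recovered segment's mean against the
#' true per-bin copies it spans.
#'
#' @param n_cohorts Number of seeded cohorts.
#' @param seed Master seed; cohort i uses `seed + i`.
#' @param config_args Extra arguments forwarded to [sim_config()].
#' @param extra_copy_threshold,max_len Focal call parameters.
#' @return One-row tibble: sensitivity, fdp, rmse, n_true_events, n_calls,
#'   n_segments.
#' @export
cn_recovery_metrics <- function(n_cohorts = 20, seed = 1,
                                config_args = list(),
                                extra_copy_threshold = 2, max_len = 20e6) {
  acc <- purrr::map(seq_len(n_cohorts), function(i) {
    cfg <- do.call(sim_config, c(list(seed = seed + i), config_args))
    sim <- simulate_cohort(cfg)
    co <- sim$cohort
    tr <- sim$truth
    tumors <- co$sample_info$sample[co$sample_info$group != "normal"]
    per_sample <- purrr::map(tumors, function(s) {
      cp <- coverage_to_copy(
        co$depth_tumor[co$depth_tumor$sample == s,
                       c("chrom", "start", "end", "depth")],
        co$depth_normal[co$depth_normal$sample == s,
                        c("chrom", "start", "end", "depth")]
      )
      sg <- segment_copy_number(
        cp, seed = substream_seed(seed + i, paste0("seg_", s))
      )
      truth_s <- tr$segments[tr$segments$sample == s, ]
      cpb <- true_copy_bins(truth_s, tr$bins)
      err <- purrr::map_dbl(seq_len(nrow(sg)), function(k) {
        hit <- tr$bins$chrom == sg$chrom[k] & tr$bins$start >= sg$start[k] &
          tr$bins$end <= sg$end[k]
        sg$copies[k] - mean(cpb[hit])
      })
      calls <- call_focal_amplifications(sg, extra_copy_threshold, max_len)
      calls <- calls[calls$pass, ]
      truth_pos <- truth_s[truth_s$copies - 2 > extra_copy_threshold &
                             truth_s$end - truth_s$start <= max_len, ]
      found <- purrr::map_lgl(seq_len(nrow(truth_pos)), function(k) {
        any(calls$chrom == truth_pos$chrom[k] &
              overlaps(calls$start, calls$end,
                       truth_pos$start[k], truth_pos$end[k]))
      })
      amp_truth <- truth_s[truth_s$copies - 2 > extra_copy_threshold, ]
      false_call <- purrr::map_lgl(seq_len(nrow(calls)), function(k) {
        !any(amp_truth$chrom == calls$chrom[k] &
               overlaps(amp_truth$start, amp_truth$end,
                        calls$start[k], calls$end[k]))
      })
      list(n_true = nrow(truth_pos), n_found = sum(found),
           n_calls = nrow(calls), n_false = sum(false_call),
           sse = sum(err^2), n_seg = nrow(sg))
    })
    per_sample
  })
  flat <- unlist(acc, recursive = FALSE)
  tot <- function(f) sum(purrr::map_dbl(flat, f))
  tibble(
    sensitivity = tot("n_found") / tot("n_true"),
    fdp = tot("n_false") / max(tot("n_calls"), 1),
    rmse = sqrt(tot("sse") / tot("n_seg")),
    n_true_events = as.integer(tot("n_true")),
    n_calls = as.integer(tot("n_calls")),
    n_segments = as.integer(tot("n_seg"))
  )
}

#' HIST+/HIST- label recovery across seeded cohorts
#'
#' Simulates cohorts at the study group sizes, classifies the DD samples
#' from expression alone, and pools label accuracy against the planted
#' subtypes.
#'
#' @param n_seeds Number of cohorts.
#' @param seed Master seed.
#' @param config_args Extra arguments forwarded to [sim_config()].
#' @return One-row tibble: accuracy, n_labels, n_seeds.
#' @export
subtype_recovery_accuracy <- function(n_seeds = 20, seed = 1,
                                      config_args = list()) {
  res <- purrr::map(seq_len(n_seeds), function(i) {
    cfg <- do.call(sim_config, c(list(seed = seed + 1000 + i), config_args))
    sim <- simulate_cohort(cfg)
    nm <- size_factor_normalize(sim$cohort$counts)
    info <- sim$cohort$sample_info
    dd <- info$sample[info$group == "DD"]
    sub <- classify_hist_subtype(nm$normalized, rd_hist_catalog(), dd)
    joined <- inner_join(sub$labels, sim$truth$subtypes, by = "sample")
    joined$label == joined$hist_label
  })
  hits <- unlist(res)
  tibble(accuracy = mean(hits), n_labels = length(hits), n_seeds = n_seeds)
}

#' Driver recovery and null specificity of the TF screen
#'
#' Runs the full path (simulate, copy-number estimation, segmentation,
#' normalization, screen) on seeded cohorts and reports how often the
#' planted driver TF passes and ranks first. With `beta_tf_hist = 0` in
#' `config_args` the same function measures the null pass rate.
#'
#' @param n_seeds Number of cohorts.
#' @param seed Master seed.
#' @param config_args Extra arguments forwarded to [sim_config()].
#' @param screen_cfg A [screen_config()].
#' @return One-row tibble: rank1_rate, pass_rate, n_seeds.
#' @export
driver_recovery_rates <- function(n_seeds = 50, seed = 1,
                                  config_args = list(),
                                  screen_cfg = screen_config()) {
  res <- purrr::map(seq_len(n_seeds), function(i) {
    sd_i <- seed + 2000 + i
    cfg <- do.call(sim_config, c(list(seed = sd_i), config_args))
    sim <- simulate_cohort(cfg)
    co <- sim$cohort
    tumors <- co$sample_info$sample[co$sample_info$group != "normal"]
    segs <- purrr::map_dfr(tumors, function(s) {
      cp <- coverage_to_copy(
        co$depth_tumor[co$depth_tumor$sample == s,
                       c("chrom", "start", "end", "depth")],
        co$depth_normal[co$depth_normal$sample == s,
                        c("chrom", "start", "end", "depth")]
      )
      sg <- segment_copy_number(
        cp, seed = substream_seed(sd_i, paste0("seg_", s))
      )
      sg$sample <- s
      sg
    })
    nm <- size_factor_normalize(co$counts)
    scr <- run_screen(nm$normalized, co$annotation, segs, co$sample_info,
                      rd_hist_catalog(), screen_cfg)
    driver <- sim$truth$driver_tf_id
    cand <- scr$candidates
    top <- cand$tf[which(cand$rank == 1)]
    c(rank1 = length(top) == 1 && top == driver,
      pass = driver %in% cand$tf[cand$pass])
  })
  m <- do.call(rbind, res)
  tibble(rank1_rate = mean(m[, "rank1"]), pass_rate = mean(m[, "pass"]),
         n_seeds = n_seeds)
}

#' Type-I error of the differential-expression stage on a null matrix
#'
#' Generates genes with identical count distributions in both groups
#' (Poisson with gene-specific lognormal means) and reports the fraction
#' of raw p-values below the nominal level.
#'
#' @param n_genes Number of null genes.
#' @param n_per_group Samples per group.
#' @param seed Seed.
#' @param level Nominal level.
#' @return One-row tibble: type1, n_genes, level.
#' @export
de_null_type1 <- function(n_genes = 10000, n_per_group = 10, seed = 1,
                          level = 0.05) {
  withr::with_seed(substream_seed(seed, "de_null"), {
    n <- 2 * n_per_group
    mu <- rlnorm(n_genes, log(30), 0.8)
    m <- matrix(rpois(n_genes * n, rep(mu, n)), nrow = n_genes,
                dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n))))
    groups <- tibble(sample = colnames(m),
                     group = rep(c("A", "B"), each = n_per_group))
    de <- differential_expression(expr_tibble(m), groups, "A", "B")
    tibble(type1 = mean(de$table$p.value < level), n_genes = n_genes,
           level = level)
  })
}
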