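# Transcription-factor driver screen: expression filter -> co-expression
# with every RD-HIST family -> DD-specific focal-amplification intersection
# -> ranking, with funnel accounting at every stage.

#' Configuration of the TF driver screen
#'
#' @param cor_threshold Minimum Pearson correlation against each histone
#'   family (strict); values at or above 1 collapse the funnel.
#' @param min_expr Expression filter: minimum mean normalized count across
#'   tumor samples.
#' @param extra_copy_threshold Extra copies required for a focal
#'   amplification call (strict, default 2).
#' @param max_len Maximum focal segment length (bp).
#' @param min_dd_samples Minimum number of DD samples whose passing focal
#'   amplification overlaps the TF gene.
#' @param require_dd_gt_wd Require the mean DD extra copies at the TF gene
#'   to exceed the WD mean ("DD-specific").
#' @param scope Samples used for the co-expression stage: `"dd"` (default)
#'   or `"all"` tumors.
#' @param family_mode `"family"` correlates each TF against the five family
#'   mean profiles; `"per_gene"` requires the threshold against every
#'   individual catalog gene (strict mode).
#' @return A validated `screen_config` list.
#' @export
screen_config <- function(cor_threshold = 0.6, min_expr = 1,
                          extra_copy_threshold = 2, max_len = 20e6,
                          min_dd_samples = 1, require_dd_gt_wd = TRUE,
                          scope = c("dd", "all"),
                          family_mode = c("family", "per_gene")) {
  scope <- match.arg(scope)
  family_mode <- match.arg(family_mode)
  if (cor_threshold <= 0) stop_lps("screen_config: cor_threshold must be > 0")
  if (min_dd_samples < 1) stop_lps("screen_config: min_dd_samples must be >= 1")
  structure(list(cor_threshold = cor_threshold, min_expr = min_expr,
                 extra_copy_threshold = extra_copy_threshold,
                 max_len = max_len, min_dd_samples = min_dd_samples,
                 require_dd_gt_wd = require_dd_gt_wd, scope = scope,
                 family_mode = family_mode),
            class = "screen_config")
}

#' Per-TF, per-family co-expression with the histone catalog
#'
#' Pearson correlation between each TF's log2(normalized + 1) profile and
#' each family's mean log2 profile across the given samples. Zero-variance
#' vectors yield a flagged undefined correlation (`undefined = TRUE`,
#' estimate `NA`), never a silent 0.
#'
#' @param normalized Wide normalized expression tibble or matrix.
#' @param tfs Character vector of TF gene ids.
#' @param catalog Histone catalog tibble (`gene_id`, `family`).
#' @param samples Sample ids (at least 4).
#' @return Tibble: tf, family, estimate, undefined.
#' @export
family_correlations <- function(normalized, tfs, catalog = rd_hist_catalog(),
                                samples) {
  check_catalog(catalog)
  if (length(samples) < 4) {
    stop_lps("family_correlations: need at least 4 samples")
  }
  m <- expr_matrix(normalized)
  tfs_in <- intersect(tfs, rownames(m))
  lm2 <- log2p1(m[, samples, drop = FALSE])
  fam_split <- split(intersect(catalog$gene_id, rownames(m)),
                     catalog$family[catalog$gene_id %in% rownames(m)])
  fam_means <- purrr::map(fam_split, function(g) {
    colMeans(lm2[g, , drop = FALSE])
  })
  purrr::map_dfr(tfs_in, function(tf) {
    x <- lm2[tf, ]
    purrr::map_dfr(names(fam_means), function(fam) {
      y <- fam_means[[fam]]
      if (sd(x) == 0 || sd(y) == 0) {
        tibble(tf = tf, family = fam, estimate = NA_real_, undefined = TRUE)
      } else {
        tibble(tf = tf, family = fam, estimate = cor(x, y), undefined = FALSE)
      }
    })
  })
}

# per-gene correlation mode: min correlation against individual catalog genes
per_gene_min_correlation <- function(lm2, tf, catalog_genes) {
  x <- lm2[tf, ]
  if (sd(x) == 0) return(NA_real_)
  rs <- purrr::map_dbl(catalog_genes, function(g) {
    y <- lm2[g, ]
    if (sd(y) == 0) NA_real_ else cor(x, y)
  })
  if (all(is.na(rs))) NA_real_ else min(rs, na.rm = TRUE)
}

# mean extra copies of the interval [start, end) across a sample set
mean_extra_at_gene <- function(segments, samples, chrom, start, end) {
  vals <- purrr::map_dbl(samples, function(s) {
    cp <- segment_mean_copies(segments[segments$sample == s, ], chrom, start, end)
    if (is.na(cp)) NA_real_ else cp - 2
  })
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Run the TF driver screen
#'
#' Cascade: (1) expressed TFs (mean normalized count across tumor samples
#' at least `min_expr`); (2) co-expressed TFs (minimum per-family
#' correlation above `cor_threshold`, computed over the configured sample
#' scope); (3) amplified TFs (gene interval overlapped by a passing focal
#' amplification in at least `min_dd_samples` DD samples and, if required,
#' mean DD extra copies above the WD mean). Passers are ranked by the
#' maximum extra copies observed in DD (descending), then by minimum
#' family correlation (descending), then by gene id.
#'
#' @param normalized Wide normalized expression tibble or matrix.
#' @param annotation Gene annotation with `gene_id`, `chrom`, `start`,
#'   `end`, `is_tf`.
#' @param segments Per-sample segment tibble (`sample`, `chrom`, `start`,
#'   `end`, `copies`, `n_bins`).
#' @param sample_info Tibble with `sample` and `group` (WD/DD/normal).
#' @param catalog Histone catalog tibble.
#' @param config A [screen_config()].
#' @return Object of class `lps_screen`: `candidates`, `family_r`,
#'   `funnel`, `config`.
#' @export
run_screen <- function(normalized, annotation, segments, sample_info,
                       catalog = rd_hist_catalog(),
                       config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  check_catalog(catalog)
  m <- expr_matrix(normalized)
  cat_missing <- setdiff(catalog$gene_id, annotation$gene_id)
  if (length(cat_missing) > 0) {
    stop_lps("run_screen: catalog ids absent from the annotation: ",
             paste(head(cat_missing, 5), collapse = ", "),
             if (length(cat_missing) > 5) ", ..." else "")
  }
  tf_tbl <- annotation[annotation$is_tf & annotation$gene_id %in% rownames(m), ]
  dd <- sample_info$sample[sample_info$group == "DD"]
  wd <- sample_info$sample[sample_info$group == "WD"]
  tumors <- c(wd, dd)
  cor_samples <- if (config$scope == "dd") dd else tumors

  # stage 1: expressed
  mean_expr <- rowMeans(m[tf_tbl$gene_id, tumors, drop = FALSE])
  expressed <- mean_expr >= config$min_expr

  # stage 2: co-expression with every family
  fam_r <- family_correlations(m, tf_tbl$gene_id, catalog, cor_samples)
  if (config$family_mode == "family") {
    min_r <- fam_r |>
      group_by(.data$tf) |>
      summarise(min_r = ifelse(any(.data$undefined), NA_real_,
                               min(.data$estimate)),
                .groups = "drop")
  } else {
    lm2 <- log2p1(m[, cor_samples, drop = FALSE])
    cg <- intersect(catalog$gene_id, rownames(m))
    min_r <- tibble(
      tf = tf_tbl$gene_id,
      min_r = purrr::map_dbl(tf_tbl$gene_id, per_gene_min_correlation,
                             lm2 = lm2, catalog_genes = cg)
    )
  }
  cand <- tf_tbl |>
    select("gene_id", "chrom", "start", "end") |>
    rename(tf = "gene_id") |>
    mutate(mean_expr = unname(mean_expr), expressed = unname(expressed)) |>
    left_join(min_r, by = "tf") |>
    mutate(coexpressed = .data$expressed & !is.na(.data$min_r) &
             .data$min_r > config$cor_threshold)

  # stage 3: DD-specific focal amplification at the TF gene
  calls <- call_focal_amplifications(segments, config$extra_copy_threshold,
                                     config$max_len)
  passing <- calls[calls$pass, ]
  amp <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    g <- cand[i, ]
    hits_dd <- purrr::map_lgl(dd, function(s) {
      ps <- passing[passing$sample == s, ]
      any(ps$chrom == g$chrom & overlaps(ps$start, ps$end, g$start, g$end))
    })
    max_extra_dd <- {
      ex <- purrr::map_dbl(dd, function(s) {
        ps <- passing[passing$sample == s, ]
        hit <- ps$chrom == g$chrom & overlaps(ps$start, ps$end, g$start, g$end)
        if (any(hit)) max(ps$extra[hit]) else NA_real_
      })
      if (all(is.na(ex))) NA_real_ else max(ex, na.rm = TRUE)
    }
    dd_mean_extra <- mean_extra_at_gene(segments, dd, g$chrom, g$start, g$end)
    wd_mean_extra <- mean_extra_at_gene(segments, wd, g$chrom, g$start, g$end)
    dd_specific <- !config$require_dd_gt_wd ||
      (!is.na(dd_mean_extra) && !is.na(wd_mean_extra) &&
         dd_mean_extra > wd_mean_extra)
    tibble(tf = g$tf, n_dd_amplified = sum(hits_dd),
           max_extra_dd = max_extra_dd,
           dd_mean_extra = dd_mean_extra, wd_mean_extra = wd_mean_extra,
           amplified = sum(hits_dd) >= config$min_dd_samples && dd_specific)
  })
  cand <- left_join(cand, amp, by = "tf") |>
    mutate(pass = .data$coexpressed & .data$amplified)

  passers <- cand[cand$pass, ]
  if (nrow(passers) > 0) {
    ord <- order(-passers$max_extra_dd, -passers$min_r, passers$tf)
    passers$rank <- NA_integer_
    passers$rank[ord] <- seq_len(nrow(passers))
    cand <- left_join(cand, passers[, c("tf", "rank")], by = "tf")
  } else {
    cand$rank <- NA_integer_
  }

  funnel <- tibble(
    stage = c("tfs", "expressed", "coexpressed", "amplified_pass"),
    n = c(nrow(cand), sum(cand$expressed), sum(cand$coexpressed),
          sum(cand$pass))
  )
  funnel$of_total <- funnel_percent(funnel$n, funnel$n[1])

  structure(list(candidates = arrange(cand, is.na(.data$rank), .data$rank),
                 family_r = fam_r, funnel = funnel, config = config),
            class = "lps_screen")
}

#' Funnel percentage
#'
#' Percentage of `k` out of `n`, rounded to one decimal as reported in
#' funnel summaries (e.g. 68 of 1988 gives 3.4).
#'
#' @param k Stage count(s).
#' @param n Total.
#' @return Numeric percentage(s), one decimal.
#' @export
funnel_percent <- function(k, n) {
  stopifnot(n > 0)
  round(100 * k / n, 1)
}

#' Format a funnel stage as "count (pct%)"
#'
#' @param k Stage count.
#' @param n Total.
#' @return Character, e.g. `"68 (3.4%)"`.
#' @export
format_funnel_count <- function(k, n) {
  sprintf("%d (%s%%)", k, format(funnel_percent(k, n), trim = TRUE))
}

#' @export
print.lps_screen <- function(x, ...) {
  cat("<lps_screen> funnel:\n")
  f <- x$funnel
  for (i in seq_len(nrow(f))) {
    cat("  ", format(f$stage[i], width = 15),
        format_funnel_count(f$n[i], f$n[1]), "\n")
  }
  top <- x$candidates[!is.na(x$candidates$rank) & x$candidates$rank == 1, ]
  if (nrow(top) > 0) cat("  top candidate:", top$tf[1], "\n")
  invisible(x)
}

#' Copy-number / expression correlation for one candidate gene
#'
#' Per-sample copy estimate at the gene (mean of overlapping segments)
#' against log2(normalized + 1) expression, Pearson with two-sided p. A
#' constant copy-number or expression vector is flagged undefined rather
#' than raising an error.
#'
#' @param normalized Wide normalized expression tibble or matrix.
#' @param segments Per-sample segment tibble.
#' @param gene_id Candidate gene id.
#' @param annotation Gene annotation (`gene_id`, `chrom`, `start`, `end`).
#' @param samples Sample ids (at least 3 with both values).
#' @return One-row tibble: gene_id, estimate, p.value, n, undefined.
#' @export
candidate_cn_expression <- function(normalized, segments, gene_id,
                                    annotation, samples) {
  g <- annotation[annotation$gene_id == gene_id, ]
  if (nrow(g) != 1) stop_lps("candidate_cn_expression: unknown gene ", gene_id)
  m <- expr_matrix(normalized)
  samples <- intersect(samples, colnames(m))
  cp <- purrr::map_dbl(samples, function(s) {
    segment_mean_copies(segments[segments$sample == s, ],
                        g$chrom, g$start, g$end)
  })
  expr <- log2p1(m[gene_id, samples])
  ok <- !is.na(cp)
  if (sum(ok) < 3) {
    stop_lps("candidate_cn_expression: fewer than 3 samples with both values")
  }
  if (sd(cp[ok]) == 0 || sd(expr[ok]) == 0) {
    return(tibble(gene_id = gene_id, estimate = NA_real_, p.value = NA_real_,
                  n = sum(ok), undefined = TRUE))
  }
  ct <- cor.test(cp[ok], expr[ok], method = "pearson")
  tibble(gene_id = gene_id, estimate = unname(ct$estimate),
         p.value = ct$p.value, n = sum(ok), undefined = FALSE)
}
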