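# broom-style tidiers for fitted/result objects.

#' Tidy a differential-expression result
#'
#' @param x An `lps_de` object.
#' @param ... Unused.
#' @return Per-gene tibble: gene_id, log2_fc, statistic, p.value,
#'   p.adjusted.
#' @export
tidy.lps_de <- function(x, ...) x$table

#' @rdname tidy.lps_de
#' @return For `glance()`: one-row tibble with gene counts at common
#'   adjusted-p cutoffs and the method tag.
#' @export
glance.lps_de <- function(x, ...) {
  tibble(
    n_genes = nrow(x$table),
    n_sig_05 = sum(x$table$p.adjusted < 0.05),
    n_sig_01 = sum(x$table$p.adjusted < 0.01),
    n_sig_001 = sum(x$table$p.adjusted < 0.001),
    method = x$method,
    group_a = x$group_a, group_b = x$group_b,
    n_a = x$n_a, n_b = x$n_b
  )
}

#' Tidy an embedding/clustering result
#'
#' @param x An `lps_embed` object.
#' @param ... Unused.
#' @return Tibble of per-sample principal-component coordinates and
#'   cluster labels.
#' @export
tidy.lps_embed <- function(x, ...) x$scores

#' @rdname tidy.lps_embed
#' @export
glance.lps_embed <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    k = x$k,
    pc1_var = x$var_explained[1],
    pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_
  )
}

#' Tidy a histone-score result
#'
#' @param x An `lps_hist_score` object.
#' @param ... Unused.
#' @return Long tibble of per-sample, per-family scores plus the overall
#'   score as family `"overall"`.
#' @export
tidy.lps_hist_score <- function(x, ...) {
  bind_rows(
    mutate(x$overall, family = "overall",
           n_genes = sum(x$families$n_genes[!duplicated(x$families$family)])) |>
      select("sample", "family", "n_genes", "score"),
    x$families
  )
}

#' Tidy a HIST subtype classification
#'
#' @param x An `lps_subtype` object.
#' @param ... Unused.
#' @return Per-sample tibble: sample, cluster, score, label.
#' @export
tidy.lps_subtype <- function(x, ...) x$labels

#' @rdname tidy.lps_subtype
#' @export
glance.lps_subtype <- function(x, ...) {
  tibble(
    n_samples = nrow(x$labels),
    n_histpos = sum(x$labels$label == "HIST+DD"),
    n_histneg = sum(x$labels$label == "HIST-DD"),
    score_gap = diff(range(x$cluster_means$mean_score)),
    singleton = x$singleton
  )
}

#' Tidy a TF screen result
#'
#' @param x An `lps_screen` object.
#' @param ... Unused.
#' @return Candidate tibble with filter flags and ranks.
#' @export
tidy.lps_screen <- function(x, ...) x$candidates

#' @rdname tidy.lps_screen
#' @return For `glance()`: the funnel as one row.
#' @export
glance.lps_screen <- function(x, ...) {
  f <- x$funnel
  tibble(
    n_tfs = f$n[f$stage == "tfs"],
    n_expressed = f$n[f$stage == "expressed"],
    n_coexpressed = f$n[f$stage == "coexpressed"],
    n_pass = f$n[f$stage == "amplified_pass"],
    pct_expressed = funnel_percent(f$n[f$stage == "expressed"], f$n[1]),
    pct_coexpressed = funnel_percent(f$n[f$stage == "coexpressed"], f$n[1])
  )
}
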