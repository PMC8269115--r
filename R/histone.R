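# RD-HIST signature scoring, HIST+/HIST- subtype classification of DDLPS,
# gene-set fold changes, and score-phenotype correlations.

#' The default replication-dependent histone catalog
#'
#' Sixty-six placeholder gene ids grouped into the five canonical histone
#' families (H1: 6, H2A: 16, H2B: 18, H3: 15, H4: 11), matching the ids
#' used by the synthetic cohort generator. Users analysing real data supply
#' their own catalog via [read_gmt()].
#'
#' @param path Optional GMT file; defaults to the catalog shipped with the
#'   package.
#' @return Tibble: gene_id, family.
#' @export
rd_hist_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rd_hist.gmt",
                                package = "lipodriver", mustWork = TRUE)
  gmt <- read_gmt(path)
  fams <- c("H1", "H2A", "H2B", "H3", "H4")
  gmt |>
    filter(.data$set %in% fams) |>
    rename(family = "set") |>
    select("gene_id", "family")
}

check_catalog <- function(catalog) {
  stopifnot(all(c("gene_id", "family") %in% names(catalog)))
  if (anyDuplicated(catalog$gene_id)) {
    stop_lps("catalog: families must be disjoint (duplicated gene ids)")
  }
  invisible(catalog)
}

#' Score RD-HIST expression per sample
#'
#' The overall score of a sample is its mean log2(normalized + 1) over the
#' measured catalog genes; per-family scores are the same mean within each
#' family. The overall score equals the size-weighted mean of the family
#' scores. Unmeasured catalog genes are reported with a warning.
#'
#' @param normalized Wide normalized expression tibble or matrix.
#' @param catalog Tibble with `gene_id` and `family` (default
#'   [rd_hist_catalog()]).
#' @return Object of class `lps_hist_score`: `overall` (sample, score),
#'   `families` (sample, family, n_genes, score), `missing_genes`.
#' @export
histone_score <- function(normalized, catalog = rd_hist_catalog()) {
  check_catalog(catalog)
  m <- expr_matrix(normalized)
  measured <- catalog[catalog$gene_id %in% rownames(m), ]
  missing <- setdiff(catalog$gene_id, rownames(m))
  if (nrow(measured) == 0) {
    stop_lps("histone_score: no catalog gene is measured")
  }
  if (length(missing) > 0) {
    warn(paste0("histone_score: ", length(missing),
                " catalog gene(s) not measured: ",
                paste(head(missing, 5), collapse = ", "),
                if (length(missing) > 5) ", ..." else ""))
  }
  lm2 <- log2p1(m[measured$gene_id, , drop = FALSE])
  overall <- tibble(sample = colnames(m), score = unname(colMeans(lm2)))
  families <- purrr::map_dfr(split(measured$gene_id, measured$family),
                             function(g) {
                               tibble(sample = colnames(m),
                                      n_genes = length(g),
                                      score = unname(colMeans(lm2[g, , drop = FALSE])))
                             }, .id = "family") |>
    select("sample", "family", "n_genes", "score")
  structure(list(overall = overall, families = families,
                 missing_genes = missing),
            class = "lps_hist_score")
}

#' @export
print.lps_hist_score <- function(x, ...) {
  cat("<lps_hist_score> ", nrow(x$overall), " samples, ",
      length(unique(x$families$family)), " families; overall score range [",
      round(min(x$overall$score), 2), ", ",
      round(max(x$overall$score), 2), "]\n", sep = "")
  invisible(x)
}

#' Classify DD tumors into HIST+ and HIST- subgroups
#'
#' Restricts the matrix to the catalog genes and the DD samples, embeds and
#' Ward-clusters them at k = 2 ([embed_and_cluster()]), and labels the
#' cluster with the higher mean overall histone score `HIST+DD`, the other
#' `HIST-DD`. The label rule makes the classification deterministic given
#' the input; singleton clusters are allowed but flagged.
#'
#' @param normalized Wide normalized expression tibble or matrix.
#' @param catalog Histone catalog tibble.
#' @param dd_samples Character vector of DD sample ids (at least 4).
#' @return Object of class `lps_subtype`: `labels` (sample, cluster, score,
#'   label), `cluster_means`, `embedding`, `singleton`.
#' @export
classify_hist_subtype <- function(normalized, catalog = rd_hist_catalog(),
                                  dd_samples) {
  check_catalog(catalog)
  if (length(dd_samples) < 4) {
    stop_lps("classify_hist_subtype: need at least 4 DD samples (got ",
             length(dd_samples), "); clustering is unstable below that")
  }
  m <- expr_matrix(normalized)
  miss <- setdiff(dd_samples, colnames(m))
  if (length(miss) > 0) {
    stop_lps("classify_hist_subtype: samples not in the matrix: ",
             paste(miss, collapse = ", "))
  }
  sub <- m[, dd_samples, drop = FALSE]
  emb <- embed_and_cluster(sub, genes = catalog$gene_id, k = 2)
  sc <- histone_score(sub, catalog)
  labels <- left_join(emb$scores[, c("sample", "cluster")], sc$overall,
                      by = "sample")
  cluster_means <- labels |>
    group_by(.data$cluster) |>
    summarise(mean_score = mean(.data$score), n = dplyr::n(),
              .groups = "drop")
  pos_cluster <- cluster_means$cluster[which.max(cluster_means$mean_score)]
  labels$label <- ifelse(labels$cluster == pos_cluster, "HIST+DD", "HIST-DD")
  structure(list(labels = labels, cluster_means = cluster_means,
                 embedding = emb,
                 singleton = any(cluster_means$n == 1)),
            class = "lps_subtype")
}

#' @export
print.lps_subtype <- function(x, ...) {
  n_pos <- sum(x$labels$label == "HIST+DD")
  cat("<lps_subtype> ", nrow(x$labels), " DD samples: ", n_pos, " HIST+DD, ",
      nrow(x$labels) - n_pos, " HIST-DD",
      if (x$singleton) " (singleton cluster)" else "", "\n", sep = "")
  invisible(x)
}

#' Average fold change of a gene set between two sample groups
#'
#' Per gene, `FC = (mean_B + 1) / (mean_A + 1)` on normalized counts; the
#' summary is the mean FC over set genes that survive a detection filter
#' (mean normalized count across the used samples at least `min_detect`).
#' The surviving subset size is reported so a filtered catalog (e.g. 53 of
#' 66 genes) is always explicit.
#'
#' @param normalized Wide normalized expression tibble or matrix.
#' @param genes Character vector: the gene set (non-empty).
#' @param samples_a,samples_b Sample ids of the two groups (non-empty).
#' @param min_detect Detection threshold on the mean normalized count
#'   (set to 0 to disable).
#' @return List: `mean_fc`, `n_genes_used`, `n_genes_total`, `per_gene`
#'   tibble (gene_id, mean_a, mean_b, fc, detected).
#' @export
geneset_fold_change <- function(normalized, genes, samples_a, samples_b,
                                min_detect = 1) {
  if (length(genes) == 0) stop_lps("geneset_fold_change: empty gene set")
  if (length(samples_a) == 0 || length(samples_b) == 0) {
    stop_lps("geneset_fold_change: both groups need at least one sample")
  }
  m <- expr_matrix(normalized)
  g <- intersect(unique(genes), rownames(m))
  if (length(g) == 0) stop_lps("geneset_fold_change: no set gene is measured")
  ma <- rowMeans(m[g, samples_a, drop = FALSE])
  mb <- rowMeans(m[g, samples_b, drop = FALSE])
  overall_mean <- rowMeans(m[g, c(samples_a, samples_b), drop = FALSE])
  per_gene <- tibble(gene_id = g, mean_a = unname(ma), mean_b = unname(mb),
                     fc = unname((mb + 1) / (ma + 1)),
                     detected = unname(overall_mean >= min_detect))
  used <- per_gene[per_gene$detected, ]
  if (nrow(used) == 0) {
    stop_lps("geneset_fold_change: no set gene passes the detection filter")
  }
  list(mean_fc = mean(used$fc), n_genes_used = nrow(used),
       n_genes_total = length(g), per_gene = per_gene)
}

#' Correlate a per-sample score with a phenotype
#'
#' Pearson correlation with a two-sided t-based p-value between the score
#' and one phenotype column; normal-tissue samples are excluded by
#' contract, and pairs with missing values are dropped and reported. At
#' least 3 complete pairs are required.
#'
#' @param scores Tibble with `sample` and `score`.
#' @param phenotypes Tibble with `sample`, the phenotype column, and
#'   optionally `group` (rows with group `"normal"` are excluded).
#' @param variable Name of the phenotype column.
#' @return One-row tibble: variable, estimate, p.value, n, n_dropped.
#' @export
phenotype_correlation <- function(scores, phenotypes, variable) {
  stopifnot(all(c("sample", "score") %in% names(scores)),
            "sample" %in% names(phenotypes))
  if (!variable %in% names(phenotypes)) {
    stop_lps("phenotype_correlation: no column `", variable, "` in phenotypes")
  }
  if ("group" %in% names(phenotypes)) {
    phenotypes <- phenotypes[phenotypes$group != "normal", ]
  }
  d <- inner_join(scores, phenotypes[, c("sample", variable)], by = "sample")
  y <- d[[variable]]
  ok <- complete.cases(d$score, y)
  n_dropped <- sum(!ok)
  if (sum(ok) < 3) {
    stop_lps("phenotype_correlation: fewer than 3 complete pairs (",
             sum(ok), ")")
  }
  ct <- cor.test(d$score[ok], y[ok], method = "pearson")
  tibble(variable = variable, estimate = unname(ct$estimate),
         p.value = ct$p.value, n = sum(ok), n_dropped = n_dropped)
}

#' Flag WD samples scoring above the HIST+ range
#'
#' Cross-check echoing the question of histone-high sub-clones within
#' WDLPS: reports any WD sample whose overall histone score exceeds the
#' minimum score among HIST+DD samples. Labels are never changed.
#'
#' @param scores Overall score tibble (`sample`, `score`) covering WD and
#'   DD samples.
#' @param subtype A [classify_hist_subtype()] result.
#' @param wd_samples Character vector of WD sample ids.
#' @return Tibble of flagged WD samples (possibly empty): sample, score,
#'   histpos_min.
#' @export
flag_wd_high_histone <- function(scores, subtype, wd_samples) {
  pos <- subtype$labels[subtype$labels$label == "HIST+DD", ]
  if (nrow(pos) == 0) {
    return(tibble(sample = character(), score = double(),
                  histpos_min = double()))
  }
  thr <- min(pos$score)
  wd <- scores[scores$sample %in% wd_samples & scores$score > thr, ]
  tibble(sample = wd$sample, score = wd$score, histpos_min = thr)
}
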