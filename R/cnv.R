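# Somatic copy number from paired tumor/normal binned coverage:
# ratio-based per-bin estimates, recursive change-point segmentation with a
# permutation stopping rule, focal amplification calls, SCNA burden, and
# copy-number / expression correlation.

#' Per-bin copy-number estimates from paired tumor/normal coverage
#'
#' Copies are anchored at diploid autosomes by median normalization:
#' `copy_i = 2 * (t_i / median_t) / (n_i / median_n)`, medians taken over
#' autosomal bins with nonzero normal depth. Bins with zero normal depth are
#' masked (`NA` copies), never zeroed. Estimates are invariant to rescaling
#' all tumor (or all normal) depths by a constant.
#'
#' @param tumor,normal Coverage tibbles (`chrom`, `start`, `end`, `depth`)
#'   on identical bin grids, sorted by (chrom, start), non-overlapping.
#' @return The bin grid with `copies` and `masked` columns.
#' @export
coverage_to_copy <- function(tumor, normal) {
  need <- c("chrom", "start", "end", "depth")
  stopifnot(all(need %in% names(tumor)), all(need %in% names(normal)))
  if (nrow(tumor) != nrow(normal)) {
    stop_lps("coverage_to_copy: tumor has ", nrow(tumor), " bins, normal has ",
             nrow(normal))
  }
  mismatch <- which(tumor$chrom != normal$chrom | tumor$start != normal$start |
                      tumor$end != normal$end)
  if (length(mismatch) > 0) {
    i <- mismatch[1]
    stop_lps("coverage_to_copy: bin grids differ; first discordant bin at row ",
             i, " (tumor ", tumor$chrom[i], ":", tumor$start[i], "-",
             tumor$end[i], " vs normal ", normal$chrom[i], ":",
             normal$start[i], "-", normal$end[i], ")")
  }
  if (any(tumor$depth < 0) || any(normal$depth < 0)) {
    stop_lps("coverage_to_copy: negative depths")
  }
  autosome <- !(tumor$chrom %in% c("chrX", "chrY", "X", "Y"))
  usable <- autosome & normal$depth > 0
  med_n <- median(normal$depth[usable])
  med_t <- median(tumor$depth[usable])
  if (!isTRUE(med_n > 0)) stop_lps("coverage_to_copy: normal median depth is 0")
  if (!isTRUE(med_t > 0)) stop_lps("coverage_to_copy: tumor median depth is 0")
  masked <- normal$depth == 0
  copies <- ifelse(masked, NA_real_,
                   2 * (tumor$depth / med_t) / (normal$depth / med_n))
  tibble(chrom = tumor$chrom, start = tumor$start, end = tumor$end,
         copies = copies, masked = masked)
}

# recursive change-point carving of one chromosome's unmasked bins
segment_one_chrom <- function(vals, starts, ends, alpha, n_perm, min_bins) {
  emit <- function(i, j) {
    tibble(start = starts[i], end = ends[j],
           copies = mean(vals[i:j]), n_bins = j - i + 1L)
  }
  recurse <- function(i, j) {
    m_ij <- j - i + 1L
    if (m_ij < 2L * min_bins) return(emit(i, j))
    res <- segment_scan_test(vals[i:j], min_bins, n_perm)
    if (is.na(res$seg_start) || res$p_value >= alpha) return(emit(i, j))
    a <- i + res$seg_start - 1L   # arc bounds in absolute bin indices
    b <- i + res$seg_end - 1L
    parts <- list()
    if (a > i) parts <- c(parts, list(recurse(i, a - 1L)))
    parts <- c(parts, list(recurse(a, b)))
    if (b < j) parts <- c(parts, list(recurse(b + 1L, j)))
    bind_rows(parts)
  }
  recurse(1L, length(vals))
}

#' Segment per-bin copy-number estimates
#'
#' Recursive change-point carving per chromosome in the circular-binary-
#' segmentation style: at each step the contiguous bin arc contrasting most
#' with the rest of the current window (scaled mean-shift statistic
#' `|mean_in - mean_out| * sqrt(n_in n_out / n)`, leftmost on ties) is
#' accepted when a permutation test (shuffling the window's bins,
#' reference = max arc statistic of each shuffle) gives p below `alpha`;
#' the arc and its flanks are then carved recursively. Arcs and nonempty
#' flanks always keep at least `min_bins` bins. Masked bins are excluded
#' from segment means; segment means conserve the per-chromosome bin mean
#' when weighted by `n_bins`.
#'
#' @param copy_bins Output of [coverage_to_copy()] (needs `chrom`, `start`,
#'   `end`, `copies`; optional `masked`).
#' @param alpha Permutation significance threshold to accept a split.
#' @param n_perm Number of shuffles.
#' @param min_bins Minimum bins per emitted flank.
#' @param seed Optional seed for the permutation RNG (fix it for
#'   byte-reproducible pipelines).
#' @return Segments tibble: chrom, start, end, copies, n_bins.
#' @export
segment_copy_number <- function(copy_bins, alpha = 0.01, n_perm = 1000,
                                min_bins = 3, seed = NULL) {
  stopifnot(all(c("chrom", "start", "end", "copies") %in% names(copy_bins)))
  run <- function() {
    purrr::map_dfr(unique(copy_bins$chrom), function(ch) {
      sub <- copy_bins[copy_bins$chrom == ch & !is.na(copy_bins$copies), ]
      if (nrow(sub) == 0) {
        warn(paste0("segment_copy_number: chromosome ", ch,
                    " has no unmasked bins; skipped"))
        return(NULL)
      }
      sub <- arrange(sub, .data$start)
      segs <- segment_one_chrom(sub$copies, sub$start, sub$end,
                                alpha, n_perm, as.integer(min_bins))
      mutate(segs, chrom = ch, .before = 1)
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Call focal amplifications from segments
#'
#' A segment passes when its extra copies (`copies - 2`) exceed
#' `extra_copy_threshold` and its length does not exceed `max_len`
#' ("focal"). Raising the threshold never adds calls.
#'
#' @param segments Segment tibble from [segment_copy_number()].
#' @param extra_copy_threshold Extra copies required (strict), default 2
#'   (">two-copy amplifications").
#' @param max_len Maximum focal segment length in bp (default 20 Mb).
#' @return Segments with `extra`, `length` and `pass` columns.
#' @export
call_focal_amplifications <- function(segments, extra_copy_threshold = 2,
                                      max_len = 20e6) {
  stopifnot(all(c("chrom", "start", "end", "copies") %in% names(segments)))
  mutate(segments,
         extra = .data$copies - 2,
         length = .data$end - .data$start,
         pass = .data$extra > extra_copy_threshold & .data$length <= max_len)
}

#' Genome-wide SCNA burden
#'
#' Counts segments deviating from diploid by at least `min_dev` copies and
#' supported by at least `min_bins` bins. Invariant under segment
#' reordering.
#'
#' @param segments Segment tibble with `copies` and `n_bins`.
#' @param min_dev Minimum |copies - 2|.
#' @param min_bins Minimum supporting bins.
#' @return Non-negative integer count.
#' @export
scna_burden <- function(segments, min_dev = 1, min_bins = 3) {
  stopifnot(all(c("copies", "n_bins") %in% names(segments)))
  sum(abs(segments$copies - 2) >= min_dev & segments$n_bins >= min_bins)
}

#' Copy-number / expression correlation across genes in an interval
#'
#' For each gene annotated inside the interval, the mean copy number of its
#' overlapping segments (averaged over the sample group) is correlated with
#' its mean log2 normalized expression over the same samples (Pearson, with
#' a two-sided t-based p-value).
#'
#' @param segments Per-sample segment tibble (must carry a `sample` column).
#' @param normalized Wide normalized expression tibble (`gene_id` +
#'   samples).
#' @param annotation Gene annotation (`gene_id`, `chrom`, `start`, `end`).
#' @param interval List or one-row data frame with `chrom`, `start`, `end`.
#' @param samples Character vector of samples defining the group.
#' @return One-row tibble: estimate, p.value, n_genes.
#' @export
expression_cn_correlation <- function(segments, normalized, annotation,
                                      interval, samples) {
  stopifnot("sample" %in% names(segments))
  interval <- as.list(interval)
  genes <- annotation[annotation$chrom == interval$chrom &
                        overlaps(annotation$start, annotation$end,
                                 interval$start, interval$end), ]
  genes <- genes[genes$gene_id %in% normalized$gene_id, ]
  if (nrow(genes) < 3) {
    stop_lps("expression_cn_correlation: fewer than 3 genes with both copy ",
             "number and expression in the interval (found ", nrow(genes), ")")
  }
  m <- expr_matrix(normalized)[genes$gene_id, samples, drop = FALSE]
  mean_expr <- rowMeans(log2p1(m))
  mean_cp <- purrr::map_dbl(seq_len(nrow(genes)), function(i) {
    per_sample <- purrr::map_dbl(samples, function(s) {
      segment_mean_copies(segments[segments$sample == s, ],
                          genes$chrom[i], genes$start[i], genes$end[i])
    })
    mean(per_sample, na.rm = TRUE)
  })
  if (sd(mean_expr) == 0) {
    stop_lps("expression_cn_correlation: expression is constant across genes ",
             "(zero variance)")
  }
  if (sd(mean_cp) == 0) {
    stop_lps("expression_cn_correlation: copy number is constant across genes ",
             "(zero variance)")
  }
  ct <- cor.test(mean_cp, mean_expr, method = "pearson")
  tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
         n_genes = nrow(genes))
}
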