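# Shared fixtures built in code.

# small but structurally complete config for fast cohort simulation
quick_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 400, n_tfs = 20, ...)
}

# segment all tumors of a cohort; returns the long per-sample segment table
segment_cohort <- function(cohort, seed, n_perm = 1000) {
  tumors <- cohort$sample_info$sample[cohort$sample_info$group != "normal"]
  purrr::map_dfr(tumors, function(s) {
    cp <- coverage_to_copy(
      cohort$depth_tumor[cohort$depth_tumor$sample == s,
                         c("chrom", "start", "end", "depth")],
      cohort$depth_normal[cohort$depth_normal$sample == s,
                          c("chrom", "start", "end", "depth")]
    )
    sg <- segment_copy_number(cp, n_perm = n_perm,
                              seed = substream_seed(seed, paste0("seg_", s)))
    sg$sample <- s
    sg
  })
}

# deterministic wide expression tibble
toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  tibble::as_tibble(m, rownames = "gene_id")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flat_copy_bins <- function(n = 60, copies = 2, noise = 0, chrom = "chr1") {
  tibble::tibble(
    chrom = chrom,
    start = seq(0, by = 1e6, length.out = n),
    end = seq(1e6, by = 1e6, length.out = n),
    copies = copies + if (noise > 0) rnorm(n, 0, noise) else 0
  )
}
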