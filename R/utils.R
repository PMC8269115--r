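# Shared helpers: seed substreams, expression-table accessors, interval overlap.

#' Derive a named substream seed from a master seed
#'
#' Each stochastic generator in the package draws from its own substream so
#' that adding or reordering generators never perturbs the draws of another.
#' The substream seed is a deterministic function of the master seed and the
#' stream name, kept below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param name Character stream name, e.g. `"copy_number"`.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1000003
  as.integer((abs(seed) * 7919 + h * 271 + 17) %% (2^31 - 1))
}

# run code under a substream seed, restoring global RNG state afterwards
with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

# ---- expression-table helpers -------------------------------------------

# A "wide" expression table is a tibble with a gene_id column and one numeric
# column per sample. These helpers convert to/from a plain numeric matrix.
expr_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(is.data.frame(x), "gene_id" %in% names(x))
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  rownames(m) <- x$gene_id
  storage.mode(m) <- "double"
  m
}

expr_tibble <- function(m) {
  out <- as_tibble(m, rownames = "gene_id")
  out
}

sample_ids <- function(x) {
  if (is.matrix(x)) colnames(x) else setdiff(names(x), "gene_id")
}

log2p1 <- function(x) log2(x + 1)

# ---- interval helpers (0-based half-open throughout) --------------------

overlaps <- function(start1, end1, start2, end2) {
  start1 < end2 & start2 < end1
}

# mean copy number of the segments overlapping [start, end) on chrom,
# for one sample's segment table
segment_mean_copies <- function(segments, chrom, start, end) {
  hit <- segments$chrom == chrom &
    overlaps(segments$start, segments$end, start, end)
  if (!any(hit)) return(NA_real_)
  mean(segments$copies[hit])
}

`%||%` <- rlang::`%||%`

stop_lps <- function(msg, ...) abort(paste0(msg, ...), class = "lipodriver_error")
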