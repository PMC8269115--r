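# Somatic SNV candidate ranking from paired tumor/normal allele counts:
# two-tailed Fisher's exact test per site, read-support filters, ranking,
# and per-tumor / per-group mutation burden.

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Classical two-tailed definition: the sum of hypergeometric probabilities
#' of all tables with the observed margins whose probability does not
#' exceed that of the observed table (absolute slack 1e-12 for float
#' comparisons). Invariant to swapping rows with columns. By convention a
#' table with any zero margin returns p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows (a, b) and (c, d).
#'   Vectorized over sites.
#' @return P-values in `[0, 1]`.
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  stopifnot(length(a) == length(b), length(b) == length(c),
            length(c) == length(d))
  cells <- cbind(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_lps("fisher_two_tailed: counts must be non-negative integers")
  }
  vapply(seq_along(a), function(i) {
    r1 <- a[i] + b[i]; r2 <- c[i] + d[i]
    c1 <- a[i] + c[i]; c2 <- b[i] + d[i]
    if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
    x <- seq(max(0, c1 - r2), min(r1, c1))
    pr <- dhyper(x, r1, r2, c1)
    p_obs <- dhyper(a[i], r1, r2, c1)
    min(1, sum(pr[pr <= p_obs + 1e-12]))
  }, numeric(1))
}

#' Call and rank somatic SNV candidates
#'
#' Each site is tested with [fisher_two_tailed()] on the (ref, alt) x
#' (tumor, normal) table; candidates pass when p is below `alpha`, the
#' tumor alt support reaches `min_alt_t`, and the matched normal shows at
#' most `max_alt_n` alt reads. Sites are ranked by (p ascending, chrom,
#' pos) so ranks are a deterministic total order; BH-adjusted q-values are
#' reported alongside the raw ranking p.
#'
#' @param sites Tibble with `chrom`, `pos` (1-based), `ref_t`, `alt_t`,
#'   `ref_n`, `alt_n` (and any extra columns, preserved).
#' @param alpha Raw p-value threshold for the pass flag.
#' @param min_alt_t Minimum tumor alt reads.
#' @param max_alt_n Maximum normal alt reads.
#' @return Input with `p.value`, `q.value`, `rank`, `pass`, ordered by
#'   rank; empty input yields an empty result.
#' @export
call_somatic_candidates <- function(sites, alpha = 0.01, min_alt_t = 4,
                                    max_alt_n = 1) {
  need <- c("chrom", "pos", "ref_t", "alt_t", "ref_n", "alt_n")
  stopifnot(all(need %in% names(sites)))
  if (nrow(sites) == 0) {
    return(mutate(sites, p.value = double(), q.value = double(),
                  rank = integer(), pass = logical()))
  }
  out <- mutate(sites,
                p.value = fisher_two_tailed(.data$ref_t, .data$ref_n,
                                            .data$alt_t, .data$alt_n),
                q.value = p.adjust(.data$p.value, method = "BH"))
  ord <- order(out$p.value, out$chrom, out$pos)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  out$pass <- out$p.value < alpha &
    out$alt_t >= min_alt_t &
    out$alt_n <= max_alt_n
  out
}

#' Mutation burden of one sample
#'
#' Number of passing somatic calls; invariant under input reordering.
#'
#' @param calls Output of [call_somatic_candidates()] for one sample.
#' @return Non-negative integer.
#' @export
mutation_burden <- function(calls) {
  stopifnot("pass" %in% names(calls))
  sum(calls$pass)
}

#' Per-group mean mutation burden
#'
#' @param burdens Tibble with `sample` and `burden`.
#' @param labels Tibble with `sample` and `group`.
#' @return Tibble: group, mean_burden, n.
#' @export
group_burden <- function(burdens, labels) {
  stopifnot(all(c("sample", "burden") %in% names(burdens)),
            all(c("sample", "group") %in% names(labels)))
  inner_join(burdens, labels, by = "sample") |>
    group_by(.data$group) |>
    summarise(mean_burden = mean(.data$burden), n = dplyr::n(),
              .groups = "drop")
}
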