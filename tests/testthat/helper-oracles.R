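# Independent oracles. These deliberately avoid the package's code paths:
# the Fisher oracle enumerates tables with lchoose arithmetic, the Wilcoxon
# oracle enumerates group assignments, the BH oracle is the textbook
# step-up loop, and the screen oracle recomputes every filter with plain
# loops.

# two-tailed Fisher p by direct enumeration over all tables with the
# observed margins, probabilities from log-binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  pr <- exp(logp)
  p_obs <- pr[support == a]
  min(1, sum(pr[pr <= p_obs + 1e-12]))
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_wilcoxon <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  idx <- utils::combn(length(pooled), n1)
  rk <- rank(pooled)
  stats <- apply(idx, 2, function(i) sum(rk[i]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(r_obs - mu) - 1e-9)
}

# textbook step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# brute-force recomputation of the screen cascade with plain loops
oracle_screen <- function(norm_mat, annotation, segments, sample_info,
                          catalog, cfg) {
  dd <- sample_info$sample[sample_info$group == "DD"]
  wd <- sample_info$sample[sample_info$group == "WD"]
  tumors <- c(wd, dd)
  scope <- if (cfg$scope == "dd") dd else tumors
  lm2 <- log2(norm_mat + 1)
  fams <- unique(catalog$family)
  tf_ids <- annotation$gene_id[annotation$is_tf &
                                 annotation$gene_id %in% rownames(norm_mat)]
  res <- list()
  for (tf in tf_ids) {
    row <- annotation[annotation$gene_id == tf, ]
    expressed <- mean(norm_mat[tf, tumors]) >= cfg$min_expr
    rs <- c()
    for (fam in fams) {
      g <- catalog$gene_id[catalog$family == fam]
      g <- intersect(g, rownames(norm_mat))
      fm <- colMeans(lm2[g, scope, drop = FALSE])
      rs <- c(rs, if (sd(lm2[tf, scope]) == 0 || sd(fm) == 0) NA
              else cor(lm2[tf, scope], fm))
    }
    min_r <- if (any(is.na(rs))) NA else min(rs)
    coex <- expressed && !is.na(min_r) && min_r > cfg$cor_threshold
    n_hit <- 0
    max_extra <- NA_real_
    for (s in dd) {
      seg <- segments[segments$sample == s, ]
      hit_extra <- c()
      for (i in seq_len(nrow(seg))) {
        focal <- (seg$copies[i] - 2) > cfg$extra_copy_threshold &&
          (seg$end[i] - seg$start[i]) <= cfg$max_len
        ovl <- seg$chrom[i] == row$chrom && seg$start[i] < row$end &&
          row$start < seg$end[i]
        if (focal && ovl) hit_extra <- c(hit_extra, seg$copies[i] - 2)
      }
      if (length(hit_extra) > 0) {
        n_hit <- n_hit + 1
        max_extra <- max(max_extra, max(hit_extra), na.rm = TRUE)
      }
    }
    mean_extra <- function(group) {
      v <- c()
      for (s in group) {
        seg <- segments[segments$sample == s, ]
        ovl <- seg$chrom == row$chrom & seg$start < row$end &
          row$start < seg$end
        v <- c(v, if (any(ovl)) mean(seg$copies[ovl]) - 2 else NA)
      }
      mean(v, na.rm = TRUE)
    }
    dd_specific <- !cfg$require_dd_gt_wd || isTRUE(mean_extra(dd) > mean_extra(wd))
    amplified <- n_hit >= cfg$min_dd_samples && dd_specific
    res[[tf]] <- list(tf = tf, expressed = expressed, min_r = min_r,
                      coexpressed = coex, amplified = amplified,
                      pass = coex && amplified, max_extra_dd = max_extra)
  }
  res
}
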