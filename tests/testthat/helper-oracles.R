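# Independent oracles, implemented by different routes than the package.

# Weir-Cockerham components via the two-level ANOVA mean squares on allele
# indicators (population / individual / allele), rather than the closed-form
# frequency expressions the package uses.
wc_anova_oracle <- function(counts1, counts2) {
  # expand genotype counts into per-individual allele pairs
  expand <- function(counts) {
    g <- rep(c(0L, 1L, 2L), counts)
    lapply(g, function(x) switch(x + 1L, c(0, 0), c(0, 1), c(1, 1)))
  }
  pops <- list(expand(counts1), expand(counts2))
  r <- 2
  n_i <- vapply(pops, length, 0L)
  n_tot <- sum(n_i)
  nbar <- n_tot / r
  nc <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  p_i <- vapply(pops, function(pop) mean(unlist(pop)), 0)
  pbar <- sum(n_i * p_i) / n_tot
  ss_ap <- sum(2 * n_i * (p_i - pbar)^2)
  ss_ai <- sum(vapply(seq_len(r), function(k)
    sum(vapply(pops[[k]], function(al) 2 * (mean(al) - p_i[k])^2, 0)), 0))
  ss_wi <- sum(vapply(unlist(pops, recursive = FALSE), function(al)
    sum((al - mean(al))^2), 0))
  ms_ap <- ss_ap / (r - 1)
  ms_ai <- ss_ai / sum(n_i - 1)
  ms_wi <- ss_wi / n_tot
  c(a = (ms_ap - ms_ai) / (2 * nc),
    b = (ms_ai - ms_wi) / 2,
    c = ms_wi)
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws.
hyper_enum_oracle <- function(k, K, n, N) {
  genes <- seq_len(N)
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Interval merging by pairwise closure (union-find), not a sorted sweep.
merge_oracle <- function(regions, max_gap) {
  n <- nrow(regions)
  if (n == 0L) return(regions[, c("chrom", "start", "end")])
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (regions$chrom[i] == regions$chrom[j] &&
        regions$start[j] <= regions$end[i] + max_gap &&
        regions$end[j] + max_gap >= regions$start[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  out <- do.call(rbind, lapply(unique(root), function(rt) {
    m <- regions[root == rt, , drop = FALSE]
    data.frame(chrom = m$chrom[1L], start = min(m$start), end = max(m$end))
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Top-fraction flagging by per-value rank counting (no sorting-based cut).
top_frac_oracle <- function(values, fraction) {
  defined <- which(!is.na(values))
  m <- ceiling(fraction * length(defined))
  n_greater <- vapply(defined, function(i)
    sum(values[defined] > values[i]), 0L)
  sort(defined[n_greater < m])
}

# r^2 by explicit formula on complete pairs.
r2_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  num <- mean(x * y) - mean(x) * mean(y)
  den <- sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
  (num / den)^2
}
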