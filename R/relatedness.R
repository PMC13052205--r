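#' Method-of-moments IBD relatedness for one sample pair
#'
#' PLINK-style estimator: identity-by-state counts (IBS0/1/2) over sites
#' where both samples are called and the allele frequency is informative
#' (0 < p < 1) are equated to their frequency-dependent expectations under
#' IBD states 0/1/2 and solved sequentially for P(IBD=0), P(IBD=1),
#' P(IBD=2). Negative solutions are clamped to zero and the triple
#' renormalized; PI_HAT = P2 + P1/2.
#'
#' Frequencies default to the pooled panel of all samples in the matrix.
#' Pooling strongly diverged populations inflates apparent within-
#' population relatedness; pass per-population frequencies to avoid this.
#'
#' @param gm genotype_matrix of LD-pruned variant sites.
#' @param pair character vector of two sample IDs.
#' @param allele_freqs optional per-site alt-allele frequencies; default
#'   estimated from all samples in \code{gm}.
#' @return one-row data.frame: \code{sample1}, \code{sample2}, \code{N0},
#'   \code{N1}, \code{N2}, \code{n_informative}, \code{P0}, \code{P1},
#'   \code{P2}, \code{pi_hat}, \code{pi_hat_raw} (before clamping),
#'   \code{dissimilarity}, \code{low_confidence} (fewer than 50
#'   informative sites).
#' @export
estimate_pi_hat <- function(gm, pair, allele_freqs = NULL) {
  stopifnot(length(pair) == 2L, all(pair %in% gm$samples))
  if (is.null(allele_freqs)) {
    ac <- allele_counts(gm)
    allele_freqs <- ifelse(ac$n > 0L, ac$alt / ac$n, NA_real_)
  }
  g1 <- gm$calls[, pair[1L]]
  g2 <- gm$calls[, pair[2L]]
  p <- allele_freqs
  use <- gm$sites$is_variant & !is.na(g1) & !is.na(g2) &
    !is.na(p) & p > 0 & p < 1
  g1 <- g1[use]; g2 <- g2[use]; p <- p[use]
  q <- 1 - p
  diff <- abs(g1 - g2)
  N0 <- sum(diff == 2L); N1 <- sum(diff == 1L); N2 <- sum(diff == 0L)
  n <- length(p)

  # expected IBS counts conditional on IBD state, summed over sites
  S0_ibd0 <- sum(2 * p^2 * q^2)
  S1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  S2_ibd0 <- n - S0_ibd0 - S1_ibd0
  S1_ibd1 <- sum(2 * p * q)
  S2_ibd1 <- n - S1_ibd1

  P0 <- if (S0_ibd0 > 0) N0 / S0_ibd0 else 0
  P1 <- if (S1_ibd1 > 0) (N1 - P0 * S1_ibd0) / S1_ibd1 else 0
  P2 <- if (n > 0) (N2 - P0 * S2_ibd0 - P1 * S2_ibd1) / n else 0
  pi_hat_raw <- P2 + P1 / 2
  # sequential bounds: more opposite homozygotes than the panmictic
  # expectation (P0 > 1) means no detectable IBD sharing, as between
  # strongly diverged populations; then clamp negatives and renormalize
  if (P0 > 1) {
    cl <- c(1, 0, 0)
  } else {
    cl <- pmax(c(P0, P1, P2), 0)
    if (sum(cl) > 0) cl <- cl / sum(cl) else cl <- c(1, 0, 0)
  }
  pi_hat <- cl[3L] + cl[2L] / 2
  data.frame(sample1 = pair[1L], sample2 = pair[2L],
             N0 = N0, N1 = N1, N2 = N2, n_informative = n,
             P0 = cl[1L], P1 = cl[2L], P2 = cl[3L],
             pi_hat = pi_hat, pi_hat_raw = pi_hat_raw,
             dissimilarity = 1 - pi_hat,
             low_confidence = n < 50L)
}

#' All-pairs relatedness and dissimilarity matrix
#'
#' @param gm genotype_matrix of LD-pruned variant sites (>= 2 samples).
#' @param popmap optional popmap; with \code{freqs = "per_population"} the
#'   moment equations use the pair's own population frequencies when both
#'   members share a population, else pooled.
#' @param freqs \code{"pooled"} (default, one panel-wide frequency per
#'   site) or \code{"per_population"}.
#' @return list with \code{pairs} (data.frame of all unordered pairs) and
#'   \code{dissimilarity} (symmetric matrix, 1 - PI_HAT, zero diagonal).
#' @export
relatedness_matrix <- function(gm, popmap = NULL,
                               freqs = c("pooled", "per_population")) {
  freqs <- match.arg(freqs)
  smp <- gm$samples
  if (length(smp) < 2L) stop("need >= 2 samples")
  ac <- allele_counts(gm)
  pooled <- ifelse(ac$n > 0L, ac$alt / ac$n, NA_real_)
  pop_freq <- NULL
  if (freqs == "per_population") {
    if (is.null(popmap)) stop("per_population frequencies need a popmap")
    pop_freq <- lapply(split(popmap$sample, popmap$population), function(m) {
      a <- allele_counts(gm, intersect(m, smp))
      ifelse(a$n > 0L, a$alt / a$n, NA_real_)
    })
  }
  pop_of <- if (!is.null(popmap))
    stats::setNames(popmap$population, popmap$sample) else NULL
  rows <- list()
  for (i in seq_len(length(smp) - 1L)) {
    for (j in seq(i + 1L, length(smp))) {
      f <- pooled
      if (freqs == "per_population" &&
          identical(pop_of[[smp[i]]], pop_of[[smp[j]]]))
        f <- pop_freq[[pop_of[[smp[i]]]]]
      rows[[length(rows) + 1L]] <-
        estimate_pi_hat(gm, c(smp[i], smp[j]), allele_freqs = f)
    }
  }
  pairs <- do.call(rbind, rows)
  d <- matrix(0, length(smp), length(smp), dimnames = list(smp, smp))
  for (k in seq_len(nrow(pairs))) {
    d[pairs$sample1[k], pairs$sample2[k]] <- pairs$dissimilarity[k]
    d[pairs$sample2[k], pairs$sample1[k]] <- pairs$dissimilarity[k]
  }
  list(pairs = pairs, dissimilarity = d)
}

#' Pairwise dosage r-squared within a distance cutoff
#'
#' Squared Pearson correlation of genotype dosages over pairwise-complete
#' samples, for same-chromosome site pairs at distance in (0, max_dist].
#' Sites failing the MAF cutoff or with zero dosage variance are skipped.
#'
#' @param gm genotype_matrix.
#' @param max_dist maximum pair distance in bp (default 1 Mb).
#' @param min_maf minimum MAF for a site to enter (default 0.10).
#' @param max_sites_per_chrom dense panels are thinned to this many evenly
#'   spaced sites per chromosome before pairing (deterministic; default
#'   2000). Binned decay means are insensitive to this thinning; set to
#'   \code{Inf} to disable.
#' @return data.frame with \code{chrom}, \code{pos1}, \code{pos2},
#'   \code{dist}, \code{r2}.
#' @export
pairwise_r2 <- function(gm, max_dist = 1e6, min_maf = 0.10,
                        max_sites_per_chrom = 2000L) {
  maf <- compute_maf(gm)
  keep <- which(gm$sites$is_variant & !is.na(maf) & maf >= min_maf)
  out <- list()
  for (ch in unique(gm$sites$chrom[keep])) {
    idx <- keep[gm$sites$chrom[keep] == ch]
    idx <- idx[order(gm$sites$pos[idx])]
    if (length(idx) > max_sites_per_chrom)
      idx <- idx[unique(round(seq(1L, length(idx),
                                  length.out = max_sites_per_chrom)))]
    if (length(idx) < 2L) next
    pos <- gm$sites$pos[idx]
    r2m <- suppressWarnings(
      stats::cor(t(gm$calls[idx, , drop = FALSE]),
                 use = "pairwise.complete.obs"))^2
    pr <- which(upper.tri(r2m), arr.ind = TRUE)
    dist <- pos[pr[, 2L]] - pos[pr[, 1L]]
    ok <- dist > 0 & dist <= max_dist & !is.na(r2m[pr])
    if (!any(ok)) next
    out[[ch]] <- data.frame(chrom = ch,
                            pos1 = pos[pr[ok, 1L]], pos2 = pos[pr[ok, 2L]],
                            dist = dist[ok], r2 = r2m[pr][ok])
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), pos1 = integer(),
                      pos2 = integer(), dist = integer(), r2 = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average r-squared in physical distance bins
#'
#' Right-closed bins: a pair at distance d lands in bin ceiling(d / bin),
#' so the bins partition (0, max_dist]. Empty bins are reported with
#' \code{n = 0}.
#'
#' @param pairs data.frame from \code{\link{pairwise_r2}}.
#' @param bin bin width in bp (default 10 kb).
#' @param max_dist extent of the binning (default 1 Mb).
#' @return data.frame with \code{bin_start}, \code{bin_end}, \code{n},
#'   \code{mean_r2}.
#' @export
ld_decay_bins <- function(pairs, bin = 10000L, max_dist = 1e6) {
  n_bins <- ceiling(max_dist / bin)
  bin_of <- ceiling(pairs$dist / bin)
  in_range <- bin_of >= 1 & bin_of <= n_bins
  b <- bin_of[in_range]
  r2 <- pairs$r2[in_range]
  n <- tabulate(b, nbins = n_bins)
  sums <- rep(0, n_bins)
  if (length(b) > 0L) {
    agg <- rowsum(r2, b)
    sums[as.integer(rownames(agg))] <- agg[, 1L]
  }
  data.frame(bin_start = (seq_len(n_bins) - 1L) * bin,
             bin_end = seq_len(n_bins) * bin,
             n = n,
             mean_r2 = ifelse(n > 0, sums / n, NA_real_))
}

#' LD decay profile for one population
#'
#' With fewer than 4 samples the r-squared estimates are dominated by
#' sampling noise (with n = 2 nearly every pair is at r^2 ~ 1 regardless
#' of true LD), so the profile is refused unless \code{force = TRUE}.
#'
#' @param gm genotype_matrix.
#' @param samples sample IDs of the population to profile.
#' @param bin,max_dist,min_maf see \code{\link{pairwise_r2}} and
#'   \code{\link{ld_decay_bins}}.
#' @param force emit the profile even for < 4 samples.
#' @return data.frame of bins, as \code{\link{ld_decay_bins}}.
#' @export
ld_decay <- function(gm, samples = gm$samples, bin = 10000L,
                     max_dist = 1e6, min_maf = 0.10, force = FALSE) {
  if (length(samples) < 4L && !force)
    stop("refusing an LD decay profile for ", length(samples),
         " samples: r^2 is uninformative at this size (use force = TRUE)")
  sub <- genotype_matrix(gm$sites, samples,
                         gm$calls[, samples, drop = FALSE])
  ld_decay_bins(pairwise_r2(sub, max_dist = max_dist, min_maf = min_maf),
                bin = bin, max_dist = max_dist)
}
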