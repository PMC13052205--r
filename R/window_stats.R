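#' Sliding windows over chromosomes
#'
#' Windows start at 0, step, 2*step, ... while start < chromosome length;
#' the last window is truncated at the chromosome end. Coordinates are
#' 0-based half-open.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp (default 50 kb).
#' @param step step between window starts in bp (default 10 kb).
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{index} (1-based, over the whole genome, in order).
#' @export
make_windows <- function(chrom_lengths, size = 50000L, step = 10000L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (step > size) stop("step > size would leave uncovered gaps")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = step)
    data.frame(chrom = ch, start = starts, end = pmin(starts + size, len))
  })
  out <- do.call(rbind, out)
  out$index <- seq_len(nrow(out))
  out
}

#' Per-site nucleotide diversity
#'
#' Mean pairwise difference among the \code{n} called alleles at a site:
#' pi = c*(n-c) / (n*(n-1)/2) for alt-allele count \code{c}. Sites with
#' fewer than 2 called alleles get \code{NA} (they are skipped from both
#' numerator and denominator in window summaries).
#'
#' @param c alt-allele count(s).
#' @param n called allele count(s).
#' @return per-site pi, vectorized.
#' @export
site_pi <- function(c, n) {
  ifelse(n >= 2, (c * (n - c)) / (n * (n - 1) / 2), NA_real_)
}

#' Per-site absolute divergence between two populations
#'
#' Mean difference over cross-population allele pairs:
#' d = (c1*(n2-c2) + c2*(n1-c1)) / (n1*n2). Sites where either population
#' has no called allele get \code{NA}.
#'
#' @param c1,c2 alt-allele counts in populations 1 and 2.
#' @param n1,n2 called allele counts in populations 1 and 2.
#' @return per-site Dxy, vectorized.
#' @export
site_dxy <- function(c1, n1, c2, n2) {
  ifelse(n1 >= 1 & n2 >= 1,
         (c1 * (n2 - c2) + c2 * (n1 - c1)) / (n1 * n2), NA_real_)
}

#' Weir-Cockerham variance components for one biallelic site
#'
#' Two-level (population / individual / allele) components for diploid
#' data: \code{a} among populations, \code{b} among individuals within
#' populations, \code{c} within individuals. Components may be negative;
#' the site-level estimator is a/(a+b+c) and windowed Fst is the ratio of
#' sums of these components over sites.
#'
#' @param counts1,counts2 length-3 integer vectors (hom-ref, het, hom-alt
#'   genotype counts) for the two populations.
#' @return named numeric vector \code{c(a =, b =, c =)}.
#' @export
wc_site_components <- function(counts1, counts2) {
  stopifnot(length(counts1) == 3L, length(counts2) == 3L)
  n1 <- sum(counts1); n2 <- sum(counts2)
  if (n1 < 1 || n2 < 1) stop("each population needs >= 1 called genotype")
  p1 <- (counts1[2L] + 2 * counts1[3L]) / (2 * n1)
  p2 <- (counts2[2L] + 2 * counts2[3L]) / (2 * n2)
  h1 <- counts1[2L] / n1
  h2 <- counts2[2L] / n2
  v <- .wc_components_vec(n1, p1, h1, n2, p2, h2)
  c(a = v$a, b = v$b, c = v$c)
}

# Vectorized Weir-Cockerham (1984) two-population diploid components.
# n_i: called diploid genotypes; p_i: alt allele frequency; h_i: observed
# heterozygote frequency. Requires mean sample size > 1.
.wc_components_vec <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  ok <- nbar > 1 & nc > 0
  a <- ifelse(ok,
              (nbar / nc) *
                (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) /
                   (nbar - 1)),
              NA_real_)
  b <- ifelse(ok,
              (nbar / (nbar - 1)) *
                (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                   (2 * nbar - 1) / (4 * nbar) * hbar),
              NA_real_)
  cc <- ifelse(ok, hbar / 2, NA_real_)
  list(a = a, b = b, c = cc)
}

# Per-population per-site genotype tallies for a sample subset.
# Returns list(n = called genotypes, c = alt allele count, het = het count).
.pop_site_tallies <- function(gm, samples) {
  g <- gm$calls[, samples, drop = FALSE]
  list(n = rowSums(!is.na(g)),
       c = rowSums(g, na.rm = TRUE),
       het = rowSums(g == 1L, na.rm = TRUE))
}

#' Sliding-window pi, Dxy and Fst for two populations
#'
#' Window pi and Dxy are ratios of summed per-site numerators to summed
#' per-site pair-count denominators over callable sites: invariant sites
#' contribute zero numerator but full denominator, and sites where a
#' population is entirely missing are skipped from both, so the estimates
#' are unbiased under random missingness. With \code{denominator =
#' "window_length"} (for variant-only input) the summed numerators are
#' divided by the window length instead, and the output is labelled
#' accordingly. Window Fst is the ratio of summed Weir-Cockerham
#' components, Sum(a) / Sum(a+b+c), over variant sites; negative values
#' are retained.
#'
#' @param gm filtered genotype_matrix (all-sites input recommended).
#' @param popmap data.frame from \code{\link{read_popmap}}; exactly two
#'   populations.
#' @param windows data.frame from \code{\link{make_windows}}.
#' @param min_variant_sites windows with fewer variant sites than this get
#'   \code{NA} Fst (default 1).
#' @param denominator \code{"callable"} (default) or \code{"window_length"}.
#' @return data.frame with one row per window: \code{chrom}, \code{start},
#'   \code{end}, \code{index}, \code{n_sites} (variant sites used),
#'   \code{n_callable_pop1}, \code{n_callable_pop2}, \code{pi_pop1},
#'   \code{pi_pop2}, \code{dxy}, \code{fst}; attribute \code{populations}
#'   gives the label order and \code{denominator} the mode used.
#' @export
summarize_windows <- function(gm, popmap, windows, min_variant_sites = 1L,
                              denominator = c("callable", "window_length")) {
  denominator <- match.arg(denominator)
  pops <- .check_two_pops(gm, popmap)
  t1 <- .pop_site_tallies(gm, pops$members[[1L]])
  t2 <- .pop_site_tallies(gm, pops$members[[2L]])
  a1 <- 2 * t1$n; a2 <- 2 * t2$n            # called alleles
  is_var <- gm$sites$is_variant

  # per-site numerators / denominators (0 where the site is skipped)
  pi1_num <- ifelse(a1 >= 2, t1$c * (a1 - t1$c), 0)
  pi1_den <- ifelse(a1 >= 2, a1 * (a1 - 1) / 2, 0)
  pi2_num <- ifelse(a2 >= 2, t2$c * (a2 - t2$c), 0)
  pi2_den <- ifelse(a2 >= 2, a2 * (a2 - 1) / 2, 0)
  both <- a1 >= 1 & a2 >= 1
  dxy_num <- ifelse(both, t1$c * (a2 - t2$c) + t2$c * (a1 - t1$c), 0)
  dxy_den <- ifelse(both, a1 * a2, 0)

  usable <- is_var & t1$n >= 1 & t2$n >= 1
  p1 <- ifelse(t1$n > 0, t1$c / a1, 0)
  p2 <- ifelse(t2$n > 0, t2$c / a2, 0)
  h1 <- ifelse(t1$n > 0, t1$het / t1$n, 0)
  h2 <- ifelse(t2$n > 0, t2$het / t2$n, 0)
  wc <- .wc_components_vec(t1$n, p1, h1, t2$n, p2, h2)
  wc_ok <- usable & !is.na(wc$a)
  fst_a <- ifelse(wc_ok, wc$a, 0)
  fst_abc <- ifelse(wc_ok, wc$a + wc$b + wc$c, 0)

  callable1 <- as.numeric(t1$n >= 1)
  callable2 <- as.numeric(t2$n >= 1)
  n_var <- as.numeric(is_var)

  cols <- cbind(pi1_num, pi1_den, pi2_num, pi2_den, dxy_num, dxy_den,
                fst_a, fst_abc, callable1, callable2, n_var)
  sums <- .window_sums(gm$sites$chrom, gm$sites$pos, windows, cols)

  pi_den1 <- if (denominator == "callable") sums[, "pi1_den"] else
    windows$end - windows$start
  pi_den2 <- if (denominator == "callable") sums[, "pi2_den"] else
    windows$end - windows$start
  dxy_den_w <- if (denominator == "callable") sums[, "dxy_den"] else
    windows$end - windows$start

  out <- data.frame(
    chrom = windows$chrom, start = windows$start, end = windows$end,
    index = windows$index,
    n_sites = as.integer(sums[, "n_var"]),
    n_callable_pop1 = as.integer(sums[, "callable1"]),
    n_callable_pop2 = as.integer(sums[, "callable2"]),
    pi_pop1 = ifelse(pi_den1 > 0, sums[, "pi1_num"] / pi_den1, NA_real_),
    pi_pop2 = ifelse(pi_den2 > 0, sums[, "pi2_num"] / pi_den2, NA_real_),
    dxy = ifelse(dxy_den_w > 0, sums[, "dxy_num"] / dxy_den_w, NA_real_),
    fst = ifelse(sums[, "fst_abc"] != 0,
                 sums[, "fst_a"] / sums[, "fst_abc"], NA_real_))
  out$fst[out$n_sites < min_variant_sites] <- NA_real_
  attr(out, "populations") <- pops$pops
  attr(out, "denominator") <- denominator
  out
}

# Sum per-site columns over (possibly overlapping) windows via cumulative
# sums on position-sorted sites; windows are 0-based half-open, sites carry
# 1-based pos. Site in window iff start <= pos-1 < end.
.window_sums <- function(chrom, pos, windows, cols) {
  res <- matrix(0, nrow = nrow(windows), ncol = ncol(cols),
                dimnames = list(NULL, colnames(cols)))
  for (ch in unique(windows$chrom)) {
    wsel <- which(windows$chrom == ch)
    ssel <- which(chrom == ch)
    if (length(ssel) == 0L) next
    o <- ssel[order(pos[ssel])]
    pos0 <- pos[o] - 1L
    cum <- apply(cols[o, , drop = FALSE], 2L, cumsum)
    if (is.null(dim(cum)))                       # single site on this chrom
      cum <- matrix(cum, nrow = 1L, dimnames = list(NULL, colnames(cols)))
    cum <- rbind(0, cum)
    lo <- findInterval(windows$start[wsel] - 0.5, pos0)   # sites with pos0 < start
    hi <- findInterval(windows$end[wsel] - 0.5, pos0)     # sites with pos0 < end
    res[wsel, ] <- cum[hi + 1L, , drop = FALSE] - cum[lo + 1L, , drop = FALSE]
  }
  res
}

#' Genome-wide ratio-of-sums Weir-Cockerham Fst
#'
#' Sum(a) / Sum(a+b+c) over all usable variant sites (both populations
#' with at least one called genotype and mean sample size > 1).
#'
#' @param gm genotype_matrix.
#' @param popmap two-population popmap.
#' @return a single Fst estimate (may be negative; NA if no usable site).
#' @export
global_fst <- function(gm, popmap) {
  pops <- .check_two_pops(gm, popmap)
  t1 <- .pop_site_tallies(gm, pops$members[[1L]])
  t2 <- .pop_site_tallies(gm, pops$members[[2L]])
  usable <- gm$sites$is_variant & t1$n >= 1 & t2$n >= 1
  p1 <- ifelse(t1$n > 0, t1$c / (2 * t1$n), 0)
  p2 <- ifelse(t2$n > 0, t2$c / (2 * t2$n), 0)
  h1 <- ifelse(t1$n > 0, t1$het / t1$n, 0)
  h2 <- ifelse(t2$n > 0, t2$het / t2$n, 0)
  wc <- .wc_components_vec(t1$n, p1, h1, t2$n, p2, h2)
  ok <- usable & !is.na(wc$a)
  den <- sum(wc$a[ok] + wc$b[ok] + wc$c[ok])
  if (!any(ok) || den == 0) return(NA_real_)
  sum(wc$a[ok]) / den
}

#' Per-individual heterozygosity
#'
#' Heterozygous calls over non-missing calls, per sample, across all sites
#' present in the matrix (with all-sites input this is a per-callable-site
#' rate; with variant-only input it is a per-variant-site rate).
#'
#' @param gm genotype_matrix.
#' @return data.frame with \code{sample}, \code{n_het}, \code{n_called},
#'   \code{het_rate} (\code{NA} for samples with no called site).
#' @export
individual_heterozygosity <- function(gm) {
  if (n_sites(gm) == 0L) stop("empty genotype matrix")
  n_het <- colSums(gm$calls == 1L, na.rm = TRUE)
  n_called <- colSums(!is.na(gm$calls))
  data.frame(sample = gm$samples, n_het = as.integer(n_het),
             n_called = as.integer(n_called),
             het_rate = ifelse(n_called > 0, n_het / n_called, NA_real_),
             row.names = NULL)
}
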