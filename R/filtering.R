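#' Hard-filter configuration
#'
#' The variant caller's thresholds are study-specific, so every rule is
#' configurable; the defaults (QUAL >= 30, depth within 1/3x to 2x of the
#' dataset mean, missingness <= 0.10, MAF >= 0.05) are this package's
#' choices and match the pruning-stage thresholds where those are fixed.
#' Setting a field to \code{NULL}/\code{NA} disables that rule.
#'
#' @param min_qual minimum site QUAL.
#' @param depth_bounds length-2 multipliers (low, high) of the mean
#'   total depth across sites with a depth value.
#' @param min_maf minimum minor-allele frequency, in [0, 0.5].
#' @param max_missing_fraction maximum fraction of missing genotypes per
#'   site, in [0, 1].
#' @param exclude_chroms chromosomes removed outright (e.g. the X).
#' @return list of class \code{filter_config}.
#' @export
filter_config <- function(min_qual = 30, depth_bounds = c(1 / 3, 2),
                          min_maf = 0.05, max_missing_fraction = 0.10,
                          exclude_chroms = character()) {
  if (!is.null(min_maf) && !is.na(min_maf) &&
      (min_maf < 0 || min_maf > 0.5))
    stop("min_maf must lie in [0, 0.5]")
  if (!is.null(max_missing_fraction) && !is.na(max_missing_fraction) &&
      (max_missing_fraction < 0 || max_missing_fraction > 1))
    stop("max_missing_fraction must lie in [0, 1]")
  if (!is.null(depth_bounds) && length(depth_bounds) != 2L)
    stop("depth_bounds must be two multipliers (low, high)")
  structure(list(min_qual = min_qual, depth_bounds = depth_bounds,
                 min_maf = min_maf,
                 max_missing_fraction = max_missing_fraction,
                 exclude_chroms = exclude_chroms),
            class = "filter_config")
}

#' Per-site minor allele frequency
#'
#' MAF = min(p, 1 - p) with p the alt-allele frequency among called
#' alleles. Sites with no called alleles get \code{NA}.
#'
#' @param gm genotype_matrix
#' @param samples samples to pool (default all).
#' @return numeric vector over sites, in [0, 0.5] or \code{NA}.
#' @export
compute_maf <- function(gm, samples = gm$samples) {
  ac <- allele_counts(gm, samples)
  p <- ifelse(ac$n > 0L, ac$alt / ac$n, NA_real_)
  pmin(p, 1 - p)
}

#' Per-site fraction of missing genotypes
#' @param gm genotype_matrix
#' @return numeric vector over sites, in [0, 1].
#' @export
site_missingness <- function(gm) {
  rowMeans(is.na(gm$calls))
}

#' Apply hard site filters
#'
#' Rules are applied in a fixed order — chromosome exclusion, QUAL, depth,
#' missingness, MAF — and each dropped site is attributed to the first rule
#' it fails. Invariant sites have no MAF and are exempt from the MAF rule.
#'
#' @param gm genotype_matrix from \code{\link{read_vcf}}.
#' @param config a \code{\link{filter_config}}.
#' @return list with \code{matrix} (the filtered genotype_matrix) and
#'   \code{drops}, a named integer vector of per-rule drop counts.
#' @export
apply_site_filters <- function(gm, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  n <- n_sites(gm)
  fail_rule <- rep(NA_character_, n)
  flag <- function(bad, rule) {
    bad[is.na(bad)] <- FALSE
    fail_rule[bad & is.na(fail_rule)] <<- rule
  }
  if (length(config$exclude_chroms) > 0L)
    flag(gm$sites$chrom %in% config$exclude_chroms, "chrom")
  if (!is.null(config$min_qual) && !is.na(config$min_qual))
    flag(gm$sites$qual < config$min_qual, "qual")
  if (!is.null(config$depth_bounds) && !anyNA(config$depth_bounds)) {
    dp <- gm$sites$total_depth
    mean_dp <- mean(dp, na.rm = TRUE)
    if (!is.nan(mean_dp))
      flag(dp < config$depth_bounds[1L] * mean_dp |
             dp > config$depth_bounds[2L] * mean_dp, "depth")
  }
  if (!is.null(config$max_missing_fraction) &&
      !is.na(config$max_missing_fraction))
    flag(site_missingness(gm) > config$max_missing_fraction, "missing")
  if (!is.null(config$min_maf) && !is.na(config$min_maf)) {
    maf <- compute_maf(gm)
    flag(gm$sites$is_variant & (is.na(maf) | maf < config$min_maf), "maf")
  }
  keep <- is.na(fail_rule)
  drops <- c(chrom = sum(fail_rule == "chrom", na.rm = TRUE),
             qual = sum(fail_rule == "qual", na.rm = TRUE),
             depth = sum(fail_rule == "depth", na.rm = TRUE),
             missing = sum(fail_rule == "missing", na.rm = TRUE),
             maf = sum(fail_rule == "maf", na.rm = TRUE))
  list(matrix = subset_sites(gm, keep), drops = drops)
}

#' LD pruning configuration
#'
#' Defaults mirror the PLINK idiom \code{--indep-pairwise 50 10 0.2}:
#' 50-SNP windows, 10-SNP step, r-squared threshold 0.2.
#'
#' @param window_size_snps SNPs per scan window.
#' @param step_snps SNPs to advance between windows.
#' @param r2_threshold prune one of any pair with dosage r^2 above this.
#' @return list of class \code{prune_config}.
#' @export
prune_config <- function(window_size_snps = 50L, step_snps = 10L,
                         r2_threshold = 0.2) {
  if (step_snps > window_size_snps) stop("step must not exceed window size")
  if (r2_threshold <= 0 || r2_threshold >= 1)
    stop("r2_threshold must lie in (0, 1)")
  structure(list(window_size_snps = as.integer(window_size_snps),
                 step_snps = as.integer(step_snps),
                 r2_threshold = r2_threshold),
            class = "prune_config")
}

#' Greedy pairwise-r^2 LD pruning
#'
#' Scans each chromosome in windows of \code{window_size_snps} variant
#' sites; within a window, every pair of still-kept sites with squared
#' Pearson dosage correlation above the threshold has its later-positioned
#' member removed; the window then advances by \code{step_snps}. The result
#' is deterministic, and no surviving pair within any window exceeds the
#' threshold.
#'
#' @param gm genotype_matrix with sites sorted by (chrom, pos); only
#'   variant sites are considered (invariant sites are always kept).
#' @param config a \code{\link{prune_config}}.
#' @return integer vector of kept site indices (into \code{gm$sites}),
#'   including all invariant sites.
#' @export
ld_prune <- function(gm, config = prune_config()) {
  s <- gm$sites
  ord <- order(s$chrom, s$pos)
  if (any(ord != seq_along(ord)))
    stop("sites must be sorted by (chrom, pos) before pruning")
  var_idx <- which(s$is_variant)
  keep <- rep(TRUE, length(var_idx))
  for (ch in unique(s$chrom[var_idx])) {
    local <- which(s$chrom[var_idx] == ch)
    m <- length(local)
    if (m < 2L) next
    start <- 1L
    repeat {
      stop_at <- min(start + config$window_size_snps - 1L, m)
      win <- local[start:stop_at]
      alive <- win[keep[win]]
      if (length(alive) >= 2L) {
        g <- gm$calls[var_idx[alive], , drop = FALSE]
        r2 <- suppressWarnings(stats::cor(t(g),
                                          use = "pairwise.complete.obs"))^2
        live <- rep(TRUE, length(alive))
        for (i in seq_along(alive)) {
          if (!live[i]) next
          hit <- which(r2[i, ] > config$r2_threshold)
          hit <- hit[hit > i & live[hit] & !is.na(r2[i, hit])]
          live[hit] <- FALSE
        }
        keep[alive[!live]] <- FALSE
      }
      if (stop_at >= m) break
      start <- start + config$step_snps
    }
  }
  sort(c(which(!s$is_variant), var_idx[keep]))
}
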