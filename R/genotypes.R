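#' Construct a genotype matrix
#'
#' The central container of the package: per-sample, per-site diploid
#' genotype dosages with explicit missingness. Sites carry VCF-style 1-based
#' positions; every interval type in the package (windows, regions, genes)
#' is 0-based half-open, so a site at position \code{pos} falls in window
#' \code{[start, end)} iff \code{start <= pos - 1 < end}.
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt} (\code{NA} for invariant all-sites records),
#'   \code{qual}, \code{total_depth} (optional, may be \code{NA}) and
#'   \code{is_variant}.
#' @param samples character vector of unique sample IDs.
#' @param calls integer matrix (sites x samples) of alt-allele dosages:
#'   0 = hom-ref, 1 = het, 2 = hom-alt, \code{NA} = missing.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(sites, samples, calls) {
  stopifnot(is.data.frame(sites), is.character(samples))
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  required <- c("chrom", "pos", "ref", "alt", "qual", "is_variant")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0L)
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"total_depth" %in% names(sites)) sites$total_depth <- NA_real_
  if (nrow(sites) != nrow(calls))
    stop("calls has ", nrow(calls), " rows but sites has ", nrow(sites))
  if (length(samples) != ncol(calls))
    stop("calls has ", ncol(calls), " columns but ", length(samples),
         " samples were given")
  if (anyDuplicated(samples)) stop("sample IDs must be unique")
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  bad <- !is.na(calls) & (calls < 0L | calls > 2L)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  # invariant records carry no alt allele and only hom-ref (or missing) calls
  inv <- !sites$is_variant
  if (any(inv)) {
    inv_calls <- calls[inv, , drop = FALSE]
    if (any(!is.na(inv_calls) & inv_calls != 0L))
      stop("invariant sites must have only hom-ref or missing calls")
  }
  dimnames(calls) <- list(NULL, samples)
  rownames(sites) <- NULL
  structure(list(sites = sites, samples = samples, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d sites (%d variant) x %d samples, %.1f%% missing\n",
    n_sites(x), sum(x$sites$is_variant), length(x$samples),
    100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param x genotype_matrix
#' @return integer count of sites (rows).
#' @export
n_sites <- function(x) nrow(x$sites)

#' Subset a genotype matrix by site index
#' @param x genotype_matrix
#' @param i integer or logical index over sites.
#' @return genotype_matrix restricted to the selected sites.
#' @export
subset_sites <- function(x, i) {
  genotype_matrix(x$sites[i, , drop = FALSE], x$samples,
                  x$calls[i, , drop = FALSE])
}

#' Per-site alt-allele and called-allele counts for a set of samples
#'
#' @param x genotype_matrix
#' @param samples sample IDs to pool (default: all).
#' @return data.frame with \code{alt} (alt-allele count) and \code{n}
#'   (called alleles, i.e. 2 x called genotypes) per site.
#' @export
allele_counts <- function(x, samples = x$samples) {
  g <- x$calls[, samples, drop = FALSE]
  data.frame(alt = rowSums(g, na.rm = TRUE),
             n = 2L * rowSums(!is.na(g)))
}

#' Read a sample-to-population map
#'
#' Two-column whitespace-delimited text: sample ID, population label.
#' Duplicate sample rows are rejected.
#'
#' @param path path to the popmap file.
#' @return data.frame with columns \code{sample} and \code{population}.
#' @export
read_popmap <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("popmap is empty: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) != 2L))
    stop("popmap rows must have exactly two fields (sample, population)")
  pm <- data.frame(sample = vapply(fields, `[`, "", 1L),
                   population = vapply(fields, `[`, "", 2L))
  dup <- duplicated(pm$sample)
  if (any(dup)) stop("sample(s) listed more than once in popmap: ",
                     paste(unique(pm$sample[dup]), collapse = ", "))
  pm <- pm[order(pm$sample), , drop = FALSE]
  rownames(pm) <- NULL
  pm
}

# Validate a popmap against a genotype matrix for two-population analyses.
# Returns list(pops = sorted population labels, members = list of sample IDs).
.check_two_pops <- function(gm, popmap) {
  missing <- setdiff(gm$samples, popmap$sample)
  if (length(missing) > 0L)
    stop("samples absent from popmap: ", paste(missing, collapse = ", "))
  popmap <- popmap[popmap$sample %in% gm$samples, , drop = FALSE]
  pops <- sort(unique(popmap$population))
  if (length(pops) != 2L)
    stop("exactly 2 populations required, got ", length(pops))
  members <- lapply(pops, function(p) popmap$sample[popmap$population == p])
  if (any(lengths(members) == 0L)) stop("each population must be non-empty")
  list(pops = pops, members = members)
}
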