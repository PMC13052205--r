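#' Flag the empirical top fraction of window values
#'
#' Rank-based: the ceiling(fraction * W) highest defined values are
#' flagged, where W counts defined (non-NA) values; ties at the realized
#' threshold are all included. Undefined windows are excluded before
#' ranking and never flagged.
#'
#' @param values numeric vector (one value per window; NA = undefined).
#' @param fraction top fraction to flag, in (0, 1); default 0.01.
#' @return list with \code{flagged} (integer indices into \code{values}),
#'   \code{threshold} (the realized cut value) and \code{n_defined}.
#' @export
empirical_top_fraction <- function(values, fraction = 0.01) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  defined <- which(!is.na(values))
  if (length(defined) == 0L) stop("no defined values to rank")
  m <- ceiling(fraction * length(defined))
  v <- values[defined]
  threshold <- sort(v, decreasing = TRUE)[m]
  flagged <- defined[v >= threshold]
  if (length(flagged) == length(defined))
    warning("all defined values are at or above the top-fraction threshold")
  list(flagged = sort(flagged), threshold = threshold,
       n_defined = length(defined))
}

# windows data.frame -> GRanges (0-based half-open -> IRanges 1-based closed)
.to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

#' Merge flagged outlier windows into contiguous regions
#'
#' Overlapping windows and windows separated by at most \code{max_gap} bp
#' are merged. The output regions are disjoint, pairwise separated by more
#' than \code{max_gap}, and cover the union of the inputs.
#'
#' @param windows data.frame of the flagged windows (\code{chrom},
#'   \code{start}, \code{end}, optionally \code{index}).
#' @param values optional statistic value per flagged window, used for
#'   the per-region max/mean summaries.
#' @param max_gap merge windows up to this many bp apart (default 10 kb);
#'   the rule is inclusive (a gap of exactly \code{max_gap} merges).
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{n_windows}, \code{member_indices} (comma-separated window
#'   indices), \code{max_value}, \code{mean_value}.
#' @export
merge_outlier_windows <- function(windows, values = NULL, max_gap = 10000L) {
  if (nrow(windows) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      member_indices = character(),
                      max_value = numeric(), mean_value = numeric()))
  ord <- order(windows$chrom, windows$start)
  windows <- windows[ord, , drop = FALSE]
  if (!is.null(values)) values <- values[ord]
  idx <- if ("index" %in% names(windows)) windows$index else seq_len(nrow(windows))
  gr <- .to_granges(windows)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_windows = lengths(revmap),
    member_indices = vapply(revmap, function(i)
      paste(idx[i], collapse = ","), ""),
    max_value = vapply(revmap, function(i)
      if (is.null(values)) NA_real_ else max(values[i]), 0),
    mean_value = vapply(revmap, function(i)
      if (is.null(values)) NA_real_ else mean(values[i]), 0))
}

#' Core islands: intersection of Fst and Dxy outlier windows
#'
#' A window is core iff it is flagged in the top fraction of both Fst and
#' Dxy; core windows are then merged under the same gap rule. By
#' construction the merged core cover is contained in both single-statistic
#' merged outlier covers; this is asserted on every run.
#'
#' @param fst_flags,dxy_flags integer window indices (into \code{windows})
#'   flagged for Fst and Dxy respectively, e.g. from
#'   \code{\link{empirical_top_fraction}}.
#' @param windows the full window data.frame both flag sets refer to.
#' @param max_gap merge gap in bp (inclusive), default 10 kb.
#' @return data.frame of merged core islands (as
#'   \code{\link{merge_outlier_windows}}) with attribute
#'   \code{n_core_windows} (count before merging).
#' @export
core_islands <- function(fst_flags, dxy_flags, windows, max_gap = 10000L) {
  if (length(fst_flags) > 0 && max(fst_flags) > nrow(windows))
    stop("fst_flags refer to windows outside the window list")
  if (length(dxy_flags) > 0 && max(dxy_flags) > nrow(windows))
    stop("dxy_flags refer to windows outside the window list")
  core <- sort(intersect(fst_flags, dxy_flags))
  merged <- merge_outlier_windows(windows[core, , drop = FALSE],
                                  max_gap = max_gap)
  # containment invariant: core cover is inside both outlier covers
  for (flags in list(fst_flags, dxy_flags)) {
    outer <- merge_outlier_windows(windows[sort(flags), , drop = FALSE],
                                   max_gap = max_gap)
    if (nrow(merged) > 0L) {
      hits <- GenomicRanges::findOverlaps(.to_granges(merged),
                                          .to_granges(outer), type = "within")
      if (length(unique(S4Vectors::queryHits(hits))) < nrow(merged))
        stop("internal error: core islands not contained in outlier regions")
    }
  }
  attr(merged, "n_core_windows") <- length(core)
  merged
}

#' Genes overlapping outlier regions
#'
#' A gene is assigned to a region iff their half-open intervals overlap by
#' at least 1 bp.
#'
#' @param regions data.frame with \code{chrom}, \code{start}, \code{end}.
#' @param genes data.frame from \code{\link{read_gff3_genes}}.
#' @return list with \code{per_region} (list of gene_id character vectors,
#'   one per region row) and \code{union} (deduplicated gene_ids).
#' @export
genes_in_regions <- function(regions, genes) {
  if (nrow(regions) == 0L || nrow(genes) == 0L)
    return(list(per_region = rep(list(character()), nrow(regions)),
                union = character()))
  hits <- GenomicRanges::findOverlaps(.to_granges(regions),
                                      .to_granges(genes))
  per_region <- rep(list(character()), nrow(regions))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  for (r in unique(q)) per_region[[r]] <- genes$gene_id[s[q == r]]
  list(per_region = per_region,
       union = sort(unique(genes$gene_id[s])))
}
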