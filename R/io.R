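#' Read a (possibly all-sites) VCF into a genotype matrix
#'
#' Keeps biallelic SNP records and invariant records (no alt allele);
#' multiallelic and indel records are dropped and their counts reported in
#' the \code{"dropped"} attribute and via a message. Genotype phase is
#' ignored; half-missing genotypes (one missing allele) are coded missing.
#'
#' @param path path to a VCF (plain or bgzipped) with a GT FORMAT field.
#' @param region optional \code{data.frame(chrom, start, end)} (0-based
#'   half-open) restricting the sites returned.
#' @param exclude_chroms chromosome names to drop at ingest (e.g. the X).
#' @return A \code{\link{genotype_matrix}} with attribute \code{dropped}, a
#'   named integer vector counting skipped multiallelic and indel records.
#' @export
read_vcf <- function(path, region = NULL, exclude_chroms = character()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0L && nrow(v@fix) == 0L) stop("VCF has no records: ", path)
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns: ", path)
  format_col <- v@gt[, 1L]
  if (!all(grepl("(^|:)GT(:|$)", format_col)))
    stop("every VCF record must carry a GT FORMAT field")

  chrom <- v@fix[, "CHROM"]
  pos <- as.integer(v@fix[, "POS"])
  ref <- v@fix[, "REF"]
  alt <- v@fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(v@fix[, "QUAL"]))
  info <- v@fix[, "INFO"]
  info[is.na(info)] <- ""
  has_dp <- grepl("(^|;)DP=", info)
  dp <- rep(NA_real_, length(info))
  dp[has_dp] <- suppressWarnings(
    as.numeric(sub(".*(?:^|;)DP=([0-9.eE+-]+).*", "\\1", info[has_dp])))

  alt[is.na(alt)] <- "."
  is_invariant <- alt == "." | alt == ""
  is_multi <- grepl(",", alt, fixed = TRUE)
  is_indel <- !is_invariant & !is_multi &
    (nchar(ref) != 1L | nchar(alt) != 1L | !alt %in% c("A", "C", "G", "T"))
  is_indel <- is_indel | (nchar(ref) != 1L & is_invariant)
  keep <- !is_multi & !is_indel & !(chrom %in% exclude_chroms)
  dropped <- c(multiallelic = sum(is_multi), indel = sum(is_indel),
               excluded_chrom = sum(chrom %in% exclude_chroms &
                                      !is_multi & !is_indel))
  if (sum(dropped) > 0L)
    message("read_vcf: skipped ", dropped[["multiallelic"]],
            " multiallelic, ", dropped[["indel"]], " indel and ",
            dropped[["excluded_chrom"]], " excluded-chromosome record(s)")

  samples <- colnames(v@gt)[-1L]
  gt <- vcfR::extract.gt(v, element = "GT")
  calls <- .gt_to_dosage(gt)
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref,
                      alt = ifelse(is_invariant, NA_character_, alt),
                      qual = qual, total_depth = dp,
                      is_variant = !is_invariant)
  sites <- sites[keep, , drop = FALSE]
  calls <- calls[keep, , drop = FALSE]
  if (!is.null(region)) {
    sel <- rep(FALSE, nrow(sites))
    for (i in seq_len(nrow(region)))
      sel <- sel | (sites$chrom == region$chrom[i] &
                      sites$pos - 1L >= region$start[i] &
                      sites$pos - 1L < region$end[i])
    sites <- sites[sel, , drop = FALSE]
    calls <- calls[sel, , drop = FALSE]
  }
  gm <- genotype_matrix(sites, samples, calls)
  attr(gm, "dropped") <- dropped
  gm
}

# "0/1", "0|1", "./.", ".|1", "1" -> dosage; any missing allele -> NA.
.gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  norm <- gsub("|", "/", gt, fixed = TRUE)
  hit <- norm %in% names(codes)
  d[hit] <- codes[norm[hit]]
  dimnames(d) <- dimnames(gt)
  d
}

#' Read gene records from a GFF3 annotation
#'
#' Returns only features of type \code{gene}, with GFF3 1-based closed
#' coordinates converted to the package's 0-based half-open convention.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open) and \code{strand}.
#' @export
read_gff3_genes <- function(path) {
  # light pre-scan so a malformed coordinate errors naming the line
  raw <- readLines(path, warn = FALSE)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  for (i in body) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) >= 5L) {
      s <- suppressWarnings(as.numeric(f[4L]))
      e <- suppressWarnings(as.numeric(f[5L]))
      if (!is.na(s) && !is.na(e) && e < s)
        stop("malformed coordinates (end < start) at line ", i, " of ", path)
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  if (any(is.na(ids) | !nzchar(ids))) stop("gene record without an ID")
  if (anyDuplicated(ids))
    stop("duplicate gene_id in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Write genomic intervals as BED3(+)
#'
#' Intervals are written 0-based half-open, tab-separated, sorted by
#' (chrom, start). Extra columns beyond chrom/start/end are appended.
#'
#' @param regions data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) and optionally more.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (nrow(regions) > 0L) {
    if (any(regions$start < 0L | regions$end <= regions$start))
      stop("intervals must satisfy 0 <= start < end")
    regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  }
  first <- c("chrom", "start", "end")
  regions <- regions[, c(first, setdiff(names(regions), first)), drop = FALSE]
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3(+) file written by \code{\link{write_bed}}
#' @param path BED path.
#' @param extra_cols names for columns beyond the first three, if any.
#' @return data.frame with \code{chrom}, \code{start}, \code{end} (+ extras).
#' @export
read_bed <- function(path, extra_cols = NULL) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_cols) && ncol(df) >= 3L + length(extra_cols))
    names(df)[3L + seq_along(extra_cols)] <- extra_cols
  df
}

#' Write / read a TSV table with header
#'
#' Numeric columns survive a round trip to 12+ significant digits.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return \code{write_table}: the path, invisibly. \code{read_table_tsv}:
#'   the data.frame.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
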