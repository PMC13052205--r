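# Small in-code fixtures shared across tests.

# genotype_matrix from a dosage matrix (sites x samples); NA = missing.
gm_from_calls <- function(calls, chrom = "chr1",
                          pos = seq_len(nrow(calls)) * 100L,
                          qual = 60, is_variant = TRUE,
                          samples = sprintf("s%02d", seq_len(ncol(calls)))) {
  n <- nrow(calls)
  if (length(is_variant) == 1L) is_variant <- rep(is_variant, n)
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A",
                      alt = ifelse(is_variant, "G", NA_character_),
                      qual = qual, total_depth = 100,
                      is_variant = is_variant)
  genotype_matrix(sites, samples, calls)
}

popmap_df <- function(samples, populations) {
  data.frame(sample = samples, population = populations)
}

write_popmap_file <- function(pm, path = tempfile(fileext = ".txt")) {
  writeLines(paste(pm$sample, pm$population, sep = "\t"), path)
  path
}

# a hand-written VCF: `records` are body lines; two samples by default
write_vcf_file <- function(records,
                           samples = c("s01", "s02"),
                           path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

vcf_rec <- function(pos, ref, alt, gts, chrom = "chr1", qual = 60,
                    info = "DP=100") {
  paste(c(chrom, pos, ".", ref, alt, qual, "PASS", info, "GT", gts),
        collapse = "\t")
}

write_gff3_file <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff3_rec <- function(chrom, start, end, type = "gene", id = "g1",
                     strand = "+") {
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
          chrom, type, start, end, strand, id, id)
}

# windows data.frame helper (0-based half-open)
windows_df <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             index = seq_along(start))
}
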