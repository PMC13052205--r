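#' Run the full divergence-scan pipeline
#'
#' Chains every stage over files on disk: ingest (VCF, popmap, GFF3, term
#' map), hard filtering, windowed pi/Dxy/Fst, empirical top-fraction
#' outliers, region merging and Fst-and-Dxy core islands, gene overlap,
#' LD pruning and relatedness, per-population LD decay, and term
#' over-representation on the candidate genes from the broader merged Fst
#' outlier regions. All stage tables are written as TSV/BED under
#' \code{outdir} together with a JSON run manifest (inputs, parameters,
#' drop counts, outputs). The pipeline is deterministic: rerunning with
#' identical inputs reproduces identical tables.
#'
#' @param vcf,popmap_path,gff3,term_map_path input files; \code{gff3} and
#'   \code{term_map_path} may be \code{NULL} to skip gene/enrichment
#'   stages.
#' @param outdir output directory (created; must be empty unless
#'   \code{overwrite}).
#' @param chrom_lengths named vector; default taken from the VCF contig
#'   headers when present, else the maximum observed position per
#'   chromosome.
#' @param filter_cfg,prune_cfg see \code{\link{filter_config}},
#'   \code{\link{prune_config}}.
#' @param window_size,window_step window geometry in bp.
#' @param outlier_fraction empirical top fraction (default 0.01).
#' @param merge_max_gap merge gap in bp, inclusive (default 10 kb).
#' @param min_variant_sites Fst windows below this are undefined.
#' @param min_term_size,display_p enrichment thresholds.
#' @param denominator pi/Dxy denominator mode (see
#'   \code{\link{summarize_windows}}).
#' @param overwrite allow writing into a non-empty directory.
#' @return the manifest, invisibly (a named list).
#' @export
run_divergence_scan <- function(vcf, popmap_path, gff3 = NULL,
                                term_map_path = NULL, outdir,
                                chrom_lengths = NULL,
                                filter_cfg = filter_config(),
                                prune_cfg = prune_config(),
                                window_size = 50000L, window_step = 10000L,
                                outlier_fraction = 0.01,
                                merge_max_gap = 10000L,
                                min_variant_sites = 1L,
                                min_term_size = 5L, display_p = 0.10,
                                denominator = "callable",
                                overwrite = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0L && !overwrite)
    stop("output directory exists and is non-empty: ", outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...)
    message(sprintf("[%s] ", stage), ...)
  out_path <- function(f) file.path(outdir, f)
  outputs <- character()
  emit <- function(x, f, writer = write_table) {
    writer(x, out_path(f))
    outputs <<- c(outputs, f)
  }

  log_stage("ingest", "reading ", vcf)
  gm <- read_vcf(vcf)
  popmap <- read_popmap(popmap_path)
  if (is.null(chrom_lengths)) {
    hdr <- readLines(vcf, n = 500L, warn = FALSE)
    contig <- grep("^##contig=", hdr, value = TRUE)
    if (length(contig) > 0L) {
      chrom_lengths <- stats::setNames(
        as.numeric(sub(".*length=([0-9]+).*", "\\1", contig)),
        sub(".*ID=([^,>]+).*", "\\1", contig))
    } else {
      chrom_lengths <- tapply(gm$sites$pos, gm$sites$chrom, max)
      chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                       names(chrom_lengths))
    }
  }

  log_stage("filter", "applying hard filters")
  filt <- apply_site_filters(gm, filter_cfg)
  log_stage("filter", paste(names(filt$drops), filt$drops,
                            sep = "=", collapse = " "),
            "; retained ", n_sites(filt$matrix), " of ", n_sites(gm))
  emit(data.frame(rule = names(filt$drops), dropped = filt$drops),
       "filter_drops.tsv")
  fm <- filt$matrix

  log_stage("windows", "pi/Dxy/Fst in ", window_size, "/", window_step,
            " bp windows")
  windows <- make_windows(chrom_lengths, size = window_size,
                          step = window_step)
  ws <- summarize_windows(fm, popmap, windows,
                          min_variant_sites = min_variant_sites,
                          denominator = denominator)
  emit(ws, "window_stats.tsv")
  emit(individual_heterozygosity(fm), "heterozygosity.tsv")

  log_stage("islands", "top ", 100 * outlier_fraction, "% outliers, merge gap ",
            merge_max_gap)
  fst_top <- empirical_top_fraction(ws$fst, outlier_fraction)
  dxy_top <- empirical_top_fraction(ws$dxy, outlier_fraction)
  fst_regions <- merge_outlier_windows(ws[fst_top$flagged, , drop = FALSE],
                                       values = ws$fst[fst_top$flagged],
                                       max_gap = merge_max_gap)
  dxy_regions <- merge_outlier_windows(ws[dxy_top$flagged, , drop = FALSE],
                                       values = ws$dxy[dxy_top$flagged],
                                       max_gap = merge_max_gap)
  core <- core_islands(fst_top$flagged, dxy_top$flagged, ws,
                       max_gap = merge_max_gap)
  emit(fst_regions, "fst_outlier_regions.tsv")
  emit(dxy_regions, "dxy_outlier_regions.tsv")
  emit(core, "core_islands.tsv")
  emit(fst_regions[, c("chrom", "start", "end")], "fst_outlier_regions.bed",
       write_bed)
  emit(core[, c("chrom", "start", "end"), drop = FALSE], "core_islands.bed",
       write_bed)

  candidate_genes <- character(); core_genes <- character()
  genes <- NULL
  if (!is.null(gff3)) {
    genes <- read_gff3_genes(gff3)
    candidate_genes <- genes_in_regions(fst_regions, genes)$union
    core_genes <- genes_in_regions(core, genes)$union
    log_stage("islands", length(candidate_genes),
              " candidate genes in merged Fst outlier regions; ",
              length(core_genes), " in core islands")
    writeLines(candidate_genes, out_path("candidate_genes.txt"))
    writeLines(core_genes, out_path("core_island_genes.txt"))
    outputs <- c(outputs, "candidate_genes.txt", "core_island_genes.txt")
  }

  log_stage("relatedness", "LD pruning and PI_HAT")
  kept <- ld_prune(fm, prune_cfg)
  pruned <- subset_sites(fm, intersect(kept, which(fm$sites$is_variant)))
  rel <- relatedness_matrix(pruned, popmap)
  emit(rel$pairs, "relatedness_pairs.tsv")
  diss <- data.frame(sample = rownames(rel$dissimilarity),
                     rel$dissimilarity, check.names = FALSE)
  emit(diss, "dissimilarity.tsv")

  log_stage("ldscan", "decay profiles per population")
  ld_files <- character()
  for (p in sort(unique(popmap$population))) {
    m <- popmap$sample[popmap$population == p]
    if (length(m) < 4L) {
      log_stage("ldscan", "skipping population ", p, " (", length(m),
                " samples): r^2 uninformative below 4 samples")
      next
    }
    f <- paste0("ld_decay_", p, ".tsv")
    emit(ld_decay(fm, samples = m), f)
    ld_files <- c(ld_files, f)
  }

  enrichment <- NULL
  if (!is.null(term_map_path) && !is.null(genes)) {
    log_stage("enrich", "term over-representation on candidate genes")
    term_map <- read_table_tsv(term_map_path)
    enrichment <- enrich_terms(candidate_genes, term_map,
                               min_term_size = min_term_size,
                               display_p = display_p)
    emit(enrichment, "enrichment.tsv")
  }

  manifest <- list(
    inputs = list(vcf = vcf, popmap = popmap_path, gff3 = gff3,
                  term_map = term_map_path),
    parameters = list(
      filter = unclass(filter_cfg), prune = unclass(prune_cfg),
      window_size = window_size, window_step = window_step,
      outlier_fraction = outlier_fraction, merge_max_gap = merge_max_gap,
      min_variant_sites = min_variant_sites,
      min_term_size = min_term_size, display_p = display_p,
      denominator = denominator),
    counts = list(
      sites_in = n_sites(gm), sites_filtered = n_sites(fm),
      drops = as.list(filt$drops), pruned_snps = n_sites(pruned),
      n_windows = nrow(ws),
      n_fst_outlier_windows = length(fst_top$flagged),
      n_dxy_outlier_windows = length(dxy_top$flagged),
      n_fst_regions = nrow(fst_regions), n_dxy_regions = nrow(dxy_regions),
      n_core_windows = attr(core, "n_core_windows"),
      n_core_islands = nrow(core),
      n_candidate_genes = length(candidate_genes),
      n_core_island_genes = length(core_genes)),
    outputs = outputs,
    package_version = as.character(utils::packageVersion("divscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
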