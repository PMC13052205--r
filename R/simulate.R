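#' Simulation configuration for the two-population generator
#'
#' Defaults emulate the study design the pipeline targets: a small
#' two-population resequencing panel (7 + 2 individuals) on a multi-Mb
#' genome with a low-divergence background and a few strongly diverged
#' islands covering ~5% of the genome, all-sites records for callable-site
#' denominators, and modest random missingness. Population allele
#' frequencies follow a Balding-Nichols distribution around a shared
#' ancestral frequency, so the divergence parameter F is also the expected
#' Weir-Cockerham Fst — which is what makes the generator a quantitative
#' oracle. The mutation rate and generation time are carried for
#' split-depth scaling of scenario descriptions only; the generator itself
#' is frequency-based, not coalescent.
#'
#' @param seed mandatory RNG seed.
#' @param n_pop1,n_pop2 diploid sample sizes (defaults 7 and 2).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param variant_density expected variant sites per bp (default 1e-3).
#' @param invariant_density expected invariant all-sites records per bp
#'   (default 4e-3).
#' @param maf_range range of the uniform ancestral-frequency draw.
#' @param f_bg background divergence parameter, in (0, 1).
#' @param f_isl island divergence parameter, in (0, 1).
#' @param islands data.frame(chrom, start, end) of planted islands
#'   (0-based half-open); default 5 x 800 kb on a 2 x 40 Mb genome (5%).
#' @param f_pop_scale length-2 multipliers of F per population, for
#'   asymmetric drift scenarios (default c(1, 1)).
#' @param missing_rate per-genotype MCAR missingness (default 0.05).
#' @param mu per-bp per-generation mutation rate (default 6e-9).
#' @param generation_time generation time in years (default 3).
#' @param split_time_gens optional split depth in generations. When set,
#'   each population additionally carries private post-split mutations:
#'   2 * mu * T * L sites per population with derived frequency uniform
#'   in (0, 1) in the owner population and 0 in the other, so expected
#'   added absolute divergence is 2 * mu * T per bp (the infinite-sites
#'   expectation). Default \code{NULL} (drift-only divergence).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed,
                       n_pop1 = 7L, n_pop2 = 2L,
                       chrom_lengths = c(chr1 = 4e7, chr2 = 4e7),
                       variant_density = 1e-3,
                       invariant_density = 4e-3,
                       maf_range = c(0.05, 0.95),
                       f_bg = 0.05, f_isl = 0.6,
                       islands = NULL,
                       f_pop_scale = c(1, 1),
                       missing_rate = 0.05,
                       mu = 6e-9, generation_time = 3,
                       split_time_gens = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (f_bg <= 0 || f_bg >= 1 || f_isl <= 0 || f_isl >= 1)
    stop("divergence parameters must lie in (0, 1)")
  if (is.null(islands))
    islands <- data.frame(
      chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
      start = c(5e6, 17e6, 30e6, 10e6, 27e6),
      end   = c(5.8e6, 17.8e6, 30.8e6, 10.8e6, 27.8e6))
  for (i in seq_len(nrow(islands))) {
    ch <- islands$chrom[i]
    if (!ch %in% names(chrom_lengths) ||
        islands$end[i] > chrom_lengths[[ch]] || islands$start[i] < 0)
      stop("island ", i, " lies outside its chromosome")
  }
  structure(list(seed = as.integer(seed), n_pop1 = as.integer(n_pop1),
                 n_pop2 = as.integer(n_pop2),
                 chrom_lengths = chrom_lengths,
                 variant_density = variant_density,
                 invariant_density = invariant_density,
                 maf_range = maf_range, f_bg = f_bg, f_isl = f_isl,
                 islands = islands, f_pop_scale = f_pop_scale,
                 missing_rate = missing_rate, mu = mu,
                 generation_time = generation_time,
                 split_time_gens = split_time_gens),
            class = "sim_config")
}

# Balding-Nichols draw: population frequency around ancestral p with
# dispersion F; F ~ 0 collapses to p.
.bn_draw <- function(p, f) {
  out <- p
  live <- f > 1e-12
  if (any(live)) {
    shape <- (1 - f[live]) / f[live]
    out[live] <- stats::rbeta(sum(live), p[live] * shape,
                              (1 - p[live]) * shape)
  }
  out
}

#' Simulate a two-population genotype panel with planted islands
#'
#' Per variant site: ancestral frequency drawn uniformly from
#' \code{maf_range}; population frequencies drawn from Balding-Nichols
#' with F = \code{f_isl} inside planted islands, else \code{f_bg}
#' (optionally scaled per population); genotypes Binomial(2, p_pop) per
#' sample (HWE within populations); missingness MCAR. Invariant sites are
#' emitted as all-sites records (no alt allele). Fully deterministic
#' given the config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{matrix} (genotype_matrix), \code{popmap}
#'   (data.frame sample/population, populations \code{"pop1"} and
#'   \code{"pop2"}) and \code{truth}: \code{sites} (per-site chrom, pos,
#'   is_variant, p_anc, p_pop1, p_pop2, divergence_f, is_island),
#'   \code{islands} and the \code{config}.
#' @export
simulate_two_pop <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n1 <- config$n_pop1; n2 <- config$n_pop2
  samples <- c(sprintf("pop1_%02d", seq_len(n1)),
               sprintf("pop2_%02d", seq_len(n2)))
  popmap <- data.frame(sample = samples,
                       population = rep(c("pop1", "pop2"), c(n1, n2)))
  site_list <- list(); truth_list <- list(); call_list <- list()
  for (ch in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[ch]]
    n_var <- round(config$variant_density * len)
    n_inv <- round(config$invariant_density * len)
    pos <- sort(sample.int(len, n_var + n_inv))
    is_var <- rep(FALSE, n_var + n_inv)
    is_var[sample.int(n_var + n_inv, n_var)] <- TRUE
    isl <- config$islands[config$islands$chrom == ch, , drop = FALSE]
    in_island <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(isl)))
      in_island <- in_island | (pos - 1 >= isl$start[i] & pos - 1 < isl$end[i])
    f <- ifelse(in_island, config$f_isl, config$f_bg)
    p_anc <- ifelse(is_var,
                    stats::runif(length(pos), config$maf_range[1L],
                                 config$maf_range[2L]), 0)
    f1 <- pmin(f * config$f_pop_scale[1L], 0.999)
    f2 <- pmin(f * config$f_pop_scale[2L], 0.999)
    p1 <- ifelse(is_var, .bn_draw(p_anc, f1), 0)
    p2 <- ifelse(is_var, .bn_draw(p_anc, f2), 0)
    mutation_origin <- rep(NA_character_, length(pos))
    if (!is.null(config$split_time_gens) && config$split_time_gens > 0) {
      # post-split private mutations: 2*mu*T*L sites per population,
      # derived frequency uniform in the owner population, absent in the
      # other; adds ~2*mu*T per bp of absolute divergence in expectation
      n_new <- round(2 * config$mu * config$split_time_gens * len)
      for (owner in 1:2) {
        if (n_new == 0L) next
        new_pos <- sample.int(len, n_new)
        u <- stats::runif(n_new)
        new_in_isl <- rep(FALSE, n_new)
        for (i in seq_len(nrow(isl)))
          new_in_isl <- new_in_isl | (new_pos - 1 >= isl$start[i] &
                                        new_pos - 1 < isl$end[i])
        pos <- c(pos, new_pos)
        is_var <- c(is_var, rep(TRUE, n_new))
        in_island <- c(in_island, new_in_isl)
        f <- c(f, rep(NA_real_, n_new))
        p_anc <- c(p_anc, rep(0, n_new))
        p1 <- c(p1, if (owner == 1L) u else rep(0, n_new))
        p2 <- c(p2, if (owner == 2L) u else rep(0, n_new))
        mutation_origin <- c(mutation_origin, rep(paste0("pop", owner),
                                                  n_new))
      }
      o <- order(pos)
      pos <- pos[o]; is_var <- is_var[o]; in_island <- in_island[o]
      f <- f[o]; p_anc <- p_anc[o]; p1 <- p1[o]; p2 <- p2[o]
      mutation_origin <- mutation_origin[o]
    }
    g1 <- matrix(stats::rbinom(length(pos) * n1, 2L, rep(p1, n1)),
                 ncol = n1)
    g2 <- matrix(stats::rbinom(length(pos) * n2, 2L, rep(p2, n2)),
                 ncol = n2)
    calls <- cbind(g1, g2)
    ref <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    site_list[[ch]] <- data.frame(
      chrom = ch, pos = pos, ref = ref,
      alt = ifelse(is_var, alt, NA_character_),
      qual = 60, total_depth = 100 * (n1 + n2),
      is_variant = is_var)
    truth_list[[ch]] <- data.frame(
      chrom = ch, pos = pos, is_variant = is_var, p_anc = p_anc,
      p_pop1 = p1, p_pop2 = p2, divergence_f = ifelse(is_var, f, NA_real_),
      is_island = in_island, mutation_origin = mutation_origin)
    call_list[[ch]] <- calls
  }
  sites <- do.call(rbind, site_list)
  calls <- do.call(rbind, call_list)
  if (config$missing_rate > 0)
    calls[stats::runif(length(calls)) < config$missing_rate] <- NA_integer_
  rownames(sites) <- NULL
  gm <- genotype_matrix(sites, samples, calls)
  truth <- list(sites = do.call(rbind, truth_list),
                islands = config$islands, config = config)
  rownames(truth$sites) <- NULL
  list(matrix = gm, popmap = popmap, truth = truth)
}

#' Simulate sample pairs of known relatedness
#'
#' Pairs are built on unlinked variant sites with founder frequencies
#' drawn uniformly from \code{maf_range}: MZ duplicates a genotype; PO
#' transmits one parental allele and draws the other from the population;
#' FS draws two children of the same parents; UN draws independently.
#' Expected PI_HAT is 1, 0.5, 0.5 and 0 respectively.
#'
#' @param relationship one of \code{"MZ"}, \code{"PO"}, \code{"FS"},
#'   \code{"UN"}.
#' @param n_sites variant sites (default 5000).
#' @param n_pairs number of replicate pairs (default 1).
#' @param maf_range founder-frequency range (default c(0.05, 0.95)).
#' @param seed RNG seed.
#' @return list with \code{matrix} (genotype_matrix; samples
#'   \code{pairK_a}/\code{pairK_b}), \code{freqs} (true founder
#'   frequencies, for the moment equations) and \code{truth}
#'   (data.frame pair / relationship / expected_pi_hat).
#' @export
simulate_relatives <- function(relationship, n_sites = 5000L, n_pairs = 1L,
                               maf_range = c(0.05, 0.95), seed) {
  if (missing(seed)) stop("seed is mandatory")
  expected <- c(MZ = 1, PO = 0.5, FS = 0.5, UN = 0)
  if (!relationship %in% names(expected))
    stop("unknown relationship: ", relationship,
         " (use MZ, PO, FS or UN)")
  set.seed(seed)
  p <- stats::runif(n_sites, maf_range[1L], maf_range[2L])
  cols <- list(); samples <- character()
  transmit <- function(g) ifelse(g == 0L, 0L,
                          ifelse(g == 2L, 1L, stats::rbinom(n_sites, 1L, 0.5)))
  for (k in seq_len(n_pairs)) {
    if (relationship == "MZ") {
      a <- stats::rbinom(n_sites, 2L, p); b <- a
    } else if (relationship == "PO") {
      a <- stats::rbinom(n_sites, 2L, p)
      b <- transmit(a) + stats::rbinom(n_sites, 1L, p)
    } else if (relationship == "FS") {
      ma <- stats::rbinom(n_sites, 2L, p)
      pa <- stats::rbinom(n_sites, 2L, p)
      a <- transmit(ma) + transmit(pa)
      b <- transmit(ma) + transmit(pa)
    } else {
      a <- stats::rbinom(n_sites, 2L, p)
      b <- stats::rbinom(n_sites, 2L, p)
    }
    cols[[length(cols) + 1L]] <- a
    cols[[length(cols) + 1L]] <- b
    samples <- c(samples, sprintf("pair%d_a", k), sprintf("pair%d_b", k))
  }
  calls <- do.call(cbind, cols)
  ref <- rep("A", n_sites); alt <- rep("G", n_sites)
  sites <- data.frame(chrom = "chr1",
                      pos = seq_len(n_sites) * 1000L,
                      ref = ref, alt = alt, qual = 60, total_depth = 100,
                      is_variant = TRUE)
  truth <- data.frame(pair = seq_len(n_pairs),
                      relationship = relationship,
                      expected_pi_hat = unname(expected[relationship]))
  list(matrix = genotype_matrix(sites, samples, calls),
       freqs = p, truth = truth)
}

#' Simulate recombining haplotypes with distance-decaying LD
#'
#' Haplotypes are mosaics of a small founder pool: along each chromosome a
#' haplotype copies its current founder and switches to a random founder
#' between adjacent sites with probability 1 - exp(-recomb_rate * gap),
#' then each allele is flipped with probability \code{mut_rate}. Nearby
#' sites share founder origin more often, so dosage r-squared decays with
#' distance toward the 1/n sampling floor.
#'
#' @param n_samples diploid samples (default 50).
#' @param n_sites variant sites (default 300).
#' @param chrom_length chromosome length in bp (default 1e6).
#' @param n_founders founder haplotypes (default 8; >= 2).
#' @param recomb_rate per-bp switch intensity.
#' @param mut_rate per-allele flip probability (default 0.01).
#' @param maf_range founder allele-frequency range (default c(0.1, 0.9)).
#' @param seed RNG seed.
#' @return a genotype_matrix on one chromosome.
#' @export
simulate_ld_haplotypes <- function(n_samples = 50L, n_sites = 300L,
                                   chrom_length = 1e6, n_founders = 8L,
                                   recomb_rate = 1e-5, mut_rate = 0.01,
                                   maf_range = c(0.1, 0.9), seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_founders < 2L) stop("founder pool must have >= 2 haplotypes")
  if (recomb_rate <= 0) stop("recomb_rate must be > 0")
  set.seed(seed)
  pos <- sort(sample.int(chrom_length, n_sites))
  p <- stats::runif(n_sites, maf_range[1L], maf_range[2L])
  founders <- matrix(stats::rbinom(n_founders * n_sites, 1L, rep(p, each = n_founders)),
                     nrow = n_founders, byrow = FALSE)
  switch_p <- 1 - exp(-recomb_rate * diff(pos))
  draw_hap <- function() {
    f <- integer(n_sites)
    f[1L] <- sample.int(n_founders, 1L)
    if (n_sites > 1L) {
      sw <- stats::runif(n_sites - 1L) < switch_p
      for (s in 2L:n_sites)
        f[s] <- if (sw[s - 1L]) sample.int(n_founders, 1L) else f[s - 1L]
    }
    h <- founders[cbind(f, seq_len(n_sites))]
    flip <- stats::runif(n_sites) < mut_rate
    h[flip] <- 1L - h[flip]
    h
  }
  calls <- vapply(seq_len(n_samples), function(i) draw_hap() + draw_hap(),
                  integer(n_sites))
  ref <- rep("A", n_sites); alt <- rep("G", n_sites)
  sites <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                      qual = 60, total_depth = 100, is_variant = TRUE)
  genotype_matrix(sites, sprintf("s%03d", seq_len(n_samples)), calls)
}

#' Write simulator output as pipeline-ready fixture files
#'
#' Emits an all-sites VCF, a popmap, a GFF3 with 10-kb genes tiled every
#' 20 kb (so planted islands overlap known genes), a gene-to-term table
#' with one term (\code{T_ISLAND}) planted on all island-overlapping genes
#' plus random background terms, the per-site truth table as TSV and the
#' island intervals as BED.
#'
#' @param sim output of \code{\link{simulate_two_pop}}.
#' @param outdir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param n_bg_terms background terms to scatter (default 40).
#' @return named character vector of file paths, invisibly.
#' @export
emit_fixtures <- function(sim, outdir, overwrite = FALSE,
                          n_bg_terms = 40L) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0L && !overwrite)
    stop("output directory exists and is non-empty: ", outdir,
         " (use overwrite = TRUE)")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gm <- sim$matrix; cfg <- sim$truth$config
  paths <- c(vcf = file.path(outdir, "sim.vcf"),
             popmap = file.path(outdir, "popmap.txt"),
             gff3 = file.path(outdir, "genes.gff3"),
             terms = file.path(outdir, "gene2term.tsv"),
             truth = file.path(outdir, "truth_sites.tsv"),
             islands = file.path(outdir, "islands.bed"))

  .write_sim_vcf(gm, cfg$chrom_lengths, paths[["vcf"]])
  utils::write.table(sim$popmap, paths[["popmap"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  genes <- .tile_genes(cfg$chrom_lengths)
  gff <- c("##gff-version 3",
           sprintf("%s\tdivscan_sim\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
                   genes$chrom, genes$start + 1L, genes$end, genes$gene_id,
                   genes$gene_id))
  writeLines(gff, paths[["gff3"]])

  set.seed(cfg$seed + 1L)
  island_genes <- genes_in_regions(sim$truth$islands, genes)$union
  bg_terms <- sprintf("T_BG%03d", seq_len(n_bg_terms))
  n_per_gene <- sample(1:3, nrow(genes), replace = TRUE)
  tm <- data.frame(
    gene_id = rep(genes$gene_id, n_per_gene),
    term_id = unlist(lapply(n_per_gene, function(k) sample(bg_terms, k))))
  tm <- rbind(tm, data.frame(gene_id = island_genes, term_id = "T_ISLAND"))
  utils::write.table(tm, paths[["terms"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)

  utils::write.table(sim$truth$sites, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  write_bed(sim$truth$islands, paths[["islands"]])
  invisible(paths)
}

# 10-kb genes tiled every 20 kb across each chromosome.
.tile_genes <- function(chrom_lengths, spacing = 20000L, width = 10000L) {
  out <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0L, chrom_lengths[[ch]] - width, by = spacing)
    data.frame(gene_id = sprintf("%s_g%04d", ch, seq_along(starts)),
               chrom = ch, start = starts, end = starts + width,
               strand = "+")
  })
  do.call(rbind, out)
}

# Minimal all-sites VCF writer for simulator fixtures.
.write_sim_vcf <- function(gm, chrom_lengths, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=divscan_simulator",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")), con)
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(gm$calls), ncol = ncol(gm$calls))
  ok <- !is.na(gm$calls)
  gt[ok] <- code[gm$calls[ok] + 1L]
  s <- gm$sites
  fixed <- list(s$chrom, s$pos, ".", s$ref,
                ifelse(s$is_variant, s$alt, "."),
                s$qual, "PASS",
                sprintf("DP=%d", as.integer(s$total_depth)), "GT")
  gt_cols <- lapply(seq_len(ncol(gt)), function(j) gt[, j])
  lines <- do.call(paste, c(fixed, gt_cols, list(sep = "\t")))
  writeLines(lines, con)
  invisible(path)
}
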