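#!/usr/bin/env Rscript
# Stage 2 — ingest the fixture VCF, hard-filter sites and LD-prune.
#
# Filters: QUAL >= 30, depth within 1/3x-2x of the mean, per-site
# missingness <= 0.10, MAF >= 0.05 (variant sites only). Pruning follows
# the 50-SNP / 10-SNP / r^2 > 0.2 greedy scan. With 9 samples a single
# missing genotype already exceeds the 10% missingness cap, so this stage
# removes a substantial fraction of sites — the same behaviour the
# thresholds produce on a real 9-sample panel.

library(divscan)

fix_dir <- "scratch/fixtures"
gm <- read_vcf(file.path(fix_dir, "sim.vcf"))
popmap <- read_popmap(file.path(fix_dir, "popmap.txt"))

filt <- apply_site_filters(gm, filter_config())
message("retained ", n_sites(filt$matrix), " of ", n_sites(gm), " sites")
write_table(data.frame(rule = names(filt$drops), dropped = filt$drops),
            "results/02_filter_drops.tsv")

kept <- ld_prune(filt$matrix)
pruned <- subset_sites(filt$matrix,
                       intersect(kept, which(filt$matrix$sites$is_variant)))
message("LD pruning kept ", n_sites(pruned), " of ",
        sum(filt$matrix$sites$is_variant), " variant sites")
write_table(data.frame(
  stage = c("input_sites", "after_hard_filters", "variant_after_filters",
            "pruned_snps"),
  n = c(n_sites(gm), n_sites(filt$matrix),
        sum(filt$matrix$sites$is_variant), n_sites(pruned))),
  "results/02_site_counts.tsv")

saveRDS(list(filtered = filt$matrix, pruned = pruned, popmap = popmap),
        "scratch/02_filtered.rds")
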