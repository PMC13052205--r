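#!/usr/bin/env Rscript
# Stage 6 — functional-term over-representation of the candidate genes.
#
# One-sided hypergeometric tests of each term against the candidate set
# from the broader merged Fst outlier regions; terms with fewer than 5
# universe genes are excluded, p-values are reported uncorrected and the
# p < 0.10 display threshold only marks rows. The generator planted the
# term T_ISLAND on every island-overlapping gene, so it should head the
# ranking by a wide margin.

library(divscan)

candidates <- readLines("results/04_candidate_genes.txt")
term_map <- read_table_tsv("scratch/fixtures/gene2term.tsv")

res <- enrich_terms(candidates, term_map)
write_table(res, "results/06_enrichment.tsv")

message("tested ", nrow(res), " terms on ", length(candidates),
        " candidate genes")
message("top of the ranking:")
message(paste(capture.output(
  print(utils::head(res[, c("term_id", "k", "K", "n", "N", "p")], 5),
        row.names = FALSE)), collapse = "\n"))
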