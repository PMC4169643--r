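#!/usr/bin/env Rscript

# Over-representation of each sample's outlier genes against the GMT
# collection; pathway score = -log10(BH-adjusted p), displayed when > 1.

suppressPackageStartupMessages(library(htxtools))

calls <- read.delim("results/outlier_calls.tsv")
sets <- read_gmt("results/cohort/sets.gmt")
counts <- read_count_matrix("results/cohort/counts.tsv")

res <- enrich_cohort(calls, sets, universe = rownames(counts))
write.table(res, "results/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

shown <- res[res$shown, ]
cat(sprintf("%d (sample, set) tests; %d shown at pathway score > 1\n",
            nrow(res), nrow(shown)))
cat(sprintf("samples with >= 1 enriched set (BH < 0.05): %d of %d\n",
            length(unique(res$sample_id[res$p_bh < 0.05])),
            length(unique(res$sample_id))))
top <- shown[order(-shown$pathway_score), ][1, ]
if (nrow(shown) > 0) {
  cat(sprintf("top: %s in %s (overlap %d/%d, score %.2f)\n",
              top$set_name, top$sample_id, top$overlap, top$set_size,
              top$pathway_score))
}
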