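#!/usr/bin/env Rscript

# Build the synthetic study cohort: 31 RNA libraries with planted outlier
# genes, labeled fusion candidates, chromoplexy-like chains and a
# tandem-duplicator genome, written to results/cohort/ in the pipeline's
# external formats (TSV/GTF/GMT/SEG/BEDPE) together with the truth tables.

suppressPackageStartupMessages(library(htxtools))

seed <- as.integer(Sys.getenv("HTX_SEED", "1"))
cfg <- sim_config(seed = seed)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "results/cohort")

cat(sprintf("cohort: %d genes x %d samples, %d planted outlier pairs\n",
            cfg$n_genes, cfg$n_samples, nrow(cohort$counts_sim$truth)))
cat(sprintf("fusion candidates: %d (%d true), junctions: %d\n",
            nrow(cohort$candidates), sum(cohort$fusion_sim$truth$is_true) +
              length(cohort$chains),
            nrow(cohort$junctions)))
cat(sprintf("tandem duplications planted: %d on sample %s\n",
            nrow(cohort$td_genome$truth), cfg$td_spec$sample_id))
cat("written to results/cohort/\n")
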