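#!/usr/bin/env Rscript

# The fusion-transcript cascade: five primary filters (with the ETS
# recurrence exemption), secondary prioritization, DNA-breakpoint
# corroboration, complex-rearrangement chain reconstruction and per-sample
# fusion load.

suppressPackageStartupMessages(library(htxtools))

cands <- read_fusion_candidates("results/cohort/candidates.tsv")
junctions <- read_bedpe("results/cohort/junctions.bedpe")
seg <- read_seg("results/cohort/copynumber.seg")
models <- read_gene_models("results/cohort/genes.gtf")
calls <- read.delim("results/outlier_calls.tsv")
truth <- read.delim("results/cohort/truth_fusions.tsv")

verdicts <- apply_primary_filters(cands)
write.table(verdicts, "results/fusion_verdicts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
retained <- cands[cands$id %in% verdicts$candidate_id[verdicts$retained], ]

flags <- flag_secondary_evidence(retained, seg, outlier_calls = calls)
write.table(flags, "results/fusion_priorities.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

coverage <- setNames(rep(10, length(unique(cands$library_id))),
                     unique(cands$library_id))
corr <- corroborate_dna(retained, junctions, coverage)
write.table(corr, "results/fusion_dna_corroboration.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

events <- build_complex_events(junctions, gene_model = models,
                               candidates = retained)
flat <- events
for (col in c("junction_ids", "genes", "fusion_ids")) {
  flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = ",")
}
write.table(flat, "results/complex_events.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

load_tab <- summarize_fusion_load(cands, verdicts, events)
write.table(load_tab, "results/fusion_load.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

planted <- truth$is_true[match(verdicts$candidate_id, truth$candidate_id)]
planted[is.na(planted)] <- TRUE  # chain fusions are planted true events
cat(sprintf("retained %d of %d candidates; agreement with planted labels %.3f\n",
            sum(verdicts$retained), nrow(verdicts),
            mean(verdicts$retained == planted)))
cat(sprintf("%d retained fusions matched to a DNA breakpoint (of %d evaluable)\n",
            sum(!is.na(corr$matched_breakpoint_id)), sum(corr$evaluable)))
cat(sprintf("%d complex events (>2 breakpoints); mean fusion load %.1f\n",
            nrow(events), mean(load_tab$fusion_load)))
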