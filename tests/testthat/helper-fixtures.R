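# Small in-code fixtures shared across test files.

# Two-gene coding model on the plus strand (and a minus-strand twin of the
# 5' gene) for reading-frame arithmetic. Coordinates are 0-based half-open.
make_frame_model <- function(offset = 0) {
  data.frame(
    gene_id = rep(c("GA", "GB", "GC", "GNC"), each = 2),
    chrom = "chr1",
    strand = rep(c("+", "+", "-", "+"), each = 2),
    feature = rep(c("exon", "CDS"), 4),
    start = offset + c(1000, 1100, 5000, 5200, 9000, 9100, 12000, NA),
    end = offset + c(2200, 2000, 6200, 6100, 10200, 10000, 13000, NA),
    stringsAsFactors = FALSE
  )[-8, ]  # GNC is non-coding: exon row only
}

make_frame_candidate <- function(id, gene5, pos5, gene3, pos3, offset = 0,
                                 lib = "S01") {
  data.frame(id = id, library_id = lib, gene5 = gene5, gene3 = gene3,
             chrom5 = "chr1", pos5 = offset + pos5, orient5 = "+",
             chrom3 = "chr1", pos3 = offset + pos3, orient3 = "-",
             split_reads = 10, spanning_reads = 10,
             is_readthrough = FALSE, multimapping = FALSE,
             repeat_fraction = 0, stringsAsFactors = FALSE)
}

# A bare fusion candidate with every filter field under control.
make_cand <- function(id, lib = "S01", gene5 = "GX", gene3 = "GY",
                      split = 10, spanning = 10, readthrough = FALSE,
                      multimap = FALSE, repfrac = 0,
                      chrom5 = "chr1", pos5 = 1e6, orient5 = "+",
                      chrom3 = "chr2", pos3 = 2e6, orient3 = "-") {
  data.frame(id = id, library_id = lib, gene5 = gene5, gene3 = gene3,
             chrom5 = chrom5, pos5 = pos5, orient5 = orient5,
             chrom3 = chrom3, pos3 = pos3, orient3 = orient3,
             split_reads = split, spanning_reads = spanning,
             is_readthrough = readthrough, multimapping = multimap,
             repeat_fraction = repfrac, stringsAsFactors = FALSE)
}

# Small cohort configuration used by integration-style tests.
small_cfg <- function(seed = 1, ...) {
  sim_config(n_samples = 12L, n_genes = 300L,
             outlier_spec = list(n_outlier_genes = 30L),
             fusion_spec = list(n_true = 5L, n_ets_true = 4L,
                                n_readthrough = 3L, n_recurrent_artifact = 3L,
                                n_multimap = 2L, n_repeat = 2L,
                                n_low_support = 3L),
             td_spec = list(n_duplications = 20L, n_subclonal = 2L),
             chain_spec = list(n_chains = 1L, breakpoints_per_chain = 5L),
             seed = seed, ...)
}
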