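test_that("each primary criterion fails exactly its engineered violation", {
  cands <- rbind(
    make_cand("ok", split = 3, spanning = 3),
    make_cand("boundary5", split = 2, spanning = 3),
    make_cand("readthrough", readthrough = TRUE),
    make_cand("multimap", multimap = TRUE),
    make_cand("repeats", repfrac = 1),
    make_cand("partrepeat", repfrac = 0.99))
  v <- apply_primary_filters(cands)
  expect_true(v$retained[v$candidate_id == "ok"])          # 6 reads > 5
  expect_false(v$retained[v$candidate_id == "boundary5"])  # 5 reads not > 5
  expect_false(v$crit5_support[v$candidate_id == "boundary5"])
  expect_false(v$crit1_rearrangement[v$candidate_id == "readthrough"])
  expect_false(v$crit3_unambiguous[v$candidate_id == "multimap"])
  expect_false(v$crit4_repeats[v$candidate_id == "repeats"])
  expect_true(v$retained[v$candidate_id == "partrepeat"])  # "entirely" means 1.0
})

test_that("the library-recurrence filter counts gene pairs and waives ETS fusions", {
  recurrent <- do.call(rbind, lapply(1:3, function(i) {
    make_cand(paste0("r", i), lib = sprintf("S%02d", i), gene5 = "GX", gene3 = "GY")
  }))
  ets <- do.call(rbind, lapply(1:15, function(i) {
    make_cand(paste0("e", i), lib = sprintf("S%02d", i), gene5 = "TMPRSS2", gene3 = "ERG")
  }))
  twolib <- do.call(rbind, lapply(1:2, function(i) {
    make_cand(paste0("t", i), lib = sprintf("S%02d", i), gene5 = "GU", gene3 = "GV")
  }))
  v <- apply_primary_filters(rbind(recurrent, ets, twolib))
  expect_false(any(v$retained[grepl("^r", v$candidate_id)]))
  expect_true(all(v$retained[grepl("^e", v$candidate_id)]))
  expect_true(all(v$ets_exemption_applied[grepl("^e", v$candidate_id)]))
  expect_true(all(v$retained[grepl("^t", v$candidate_id)]))  # 2 libraries pass
  expect_false(any(v$ets_exemption_applied[grepl("^t", v$candidate_id)]))
})

test_that("the ETS exemption never rescues violations of other criteria", {
  bad_ets <- rbind(
    make_cand("ets_rt", gene3 = "ERG", readthrough = TRUE),
    make_cand("ets_low", gene3 = "ETV1", split = 1, spanning = 1),
    make_cand("ets_rep", gene3 = "ERG", repfrac = 1),
    make_cand("ets_mm", gene3 = "ETV4", multimap = TRUE))
  v <- apply_primary_filters(bad_ets)
  expect_false(any(v$retained))
})

test_that("secondary evidence flags CNA edges, exon imbalance and 3' outliers", {
  cand <- make_cand("FC1", lib = "T1", gene5 = "GX", gene3 = "GY",
                    chrom5 = "chr1", pos5 = 1.05e6, chrom3 = "chr2", pos3 = 5e6)
  seg <- data.frame(sample = "T1", chrom = "chr1",
                    start = c(0, 1e6), end = c(1e6, 2e6),
                    log2ratio = c(0, 1), stringsAsFactors = FALSE)
  exon_depth <- data.frame(
    gene_id = "GY", sample_id = "T1",
    start = c(4.9e6, 4.95e6, 5.05e6, 5.1e6),
    end = c(4.91e6, 4.96e6, 5.06e6, 5.11e6),
    depth = c(2, 2, 20, 20), stringsAsFactors = FALSE)
  outliers <- data.frame(gene_id = "GY", sample_id = "T1", direction = "up",
                         stringsAsFactors = FALSE)
  fl <- flag_secondary_evidence(cand, seg, exon_depth, outliers)
  expect_true(fl$cna_edge)                       # 50 kb from a +1.0 boundary
  expect_true(fl$differential_exon_expression)   # 2x vs 20x across the junction
  expect_true(fl$outlier_3prime)
  expect_true(fl$prioritized)

  far <- make_cand("FC2", lib = "T1", gene3 = "GZ", chrom5 = "chr1",
                   pos5 = 1.5e6, chrom3 = "chr9", pos3 = 9e6)
  fl2 <- flag_secondary_evidence(far, seg, exon_depth = NULL, outlier_calls = outliers)
  expect_false(fl2$cna_edge)        # 500 kb away exceeds the 100 kb tolerance
  expect_true(is.na(fl2$differential_exon_expression))
  expect_false(fl2$outlier_3prime)  # no up-call for GZ in this sample
})

test_that("DNA corroboration gates on coverage and matches oriented ends", {
  cand <- make_cand("FC1", lib = "T1")
  jn <- data.frame(id = "J1", sample = "T1", chromA = "chr1", posA = 1e6 + 4,
                   orientA = "+", chromB = "chr2", posB = 2e6 - 3, orientB = "-",
                   support_reads = 20L, stringsAsFactors = FALSE)
  res <- corroborate_dna(cand, jn, coverage = c(T1 = 10))
  expect_true(res$evaluable)
  expect_equal(res$matched_breakpoint_id, "J1")

  shallow <- corroborate_dna(cand, jn, coverage = c(T1 = 4.9))
  expect_false(shallow$evaluable)
  expect_true(is.na(shallow$matched_breakpoint_id))

  flipped <- jn
  flipped$orientA <- "-"
  expect_true(is.na(corroborate_dna(cand, flipped,
                                    coverage = c(T1 = 10))$matched_breakpoint_id))

  # raising the tolerance never unmatches
  wide <- corroborate_dna(cand, jn, coverage = c(T1 = 10), match_tolerance_bp = 1000)
  expect_equal(wide$matched_breakpoint_id, "J1")
})

test_that("complex events require more than two breakpoints and partition junctions", {
  ch <- simulate_complex_chain(6, seed = 21, sample_id = "S01", id_prefix = "A")
  rec <- simulate_complex_chain(2, seed = 22, sample_id = "S01", id_prefix = "B")
  ch2 <- simulate_complex_chain(4, seed = 23, sample_id = "S01", id_prefix = "C")
  all_jn <- rbind(ch$junctions, rec$junctions, ch2$junctions)
  ev <- build_complex_events(all_jn, gene_model = rbind(ch$models, ch2$models),
                             candidates = rbind(ch$fusion, ch2$fusion))
  expect_equal(nrow(ev), 2L)
  expect_setequal(ev$n_breakpoints, c(6L, 4L))
  big <- ev[ev$n_breakpoints == 6, ]
  expect_setequal(big$junction_ids[[1]], ch$junctions$id)
  expect_setequal(big$genes[[1]], ch$genes)
  expect_equal(big$fusion_ids[[1]], ch$fusion$id)
  # partition: no junction appears in two events
  expect_equal(anyDuplicated(unlist(ev$junction_ids)), 0L)
  expect_false(any(rec$junctions$id %in% unlist(ev$junction_ids)))
})

test_that("gene effects separate disrupted, activating and neutral nodes", {
  models <- data.frame(
    gene_id = rep(c("TSG", "ONC", "BYSTANDER"), each = 2),
    chrom = rep(c("chr1", "chr2", "chr3"), each = 2),
    strand = "+",
    feature = rep(c("exon", "CDS"), 3),
    start = c(1e6, 1.01e6, 2e6, 2.01e6, 3e6, 3.01e6),
    end = c(1.1e6, 1.09e6, 2.1e6, 2.09e6, 3.1e6, 3.09e6),
    stringsAsFactors = FALSE)
  jn <- data.frame(
    id = c("J1", "J2", "J3"), sample = "S01",
    chromA = c("chr1", "chr2", "chr3"),
    posA = c(1.05e6, 2.05e6, 3.006e6),  # TSG mid-CDS; ONC mid-CDS; BYSTANDER 5' UTR
    orientA = "+",
    chromB = c("chr2", "chr3", "chr1"),
    posB = c(2.05e6 + 100, 3.005e6, 1.05e6 + 100),
    orientB = "-",
    support_reads = 10L, stringsAsFactors = FALSE)
  fusion <- make_cand("FUS", lib = "S01", gene5 = "TSG", gene3 = "ONC",
                      chrom5 = "chr1", pos5 = 1.05e6, orient5 = "+",
                      chrom3 = "chr2", pos3 = 2.05e6 + 100, orient3 = "-")
  ev <- build_complex_events(jn, gene_model = models, candidates = fusion)
  expect_equal(nrow(ev), 1L)
  frames <- data.frame(candidate_id = "FUS", status = "in_frame",
                       stringsAsFactors = FALSE)
  eff <- classify_gene_effects(ev, jn, models, candidates = fusion,
                               frames = frames)
  expect_equal(eff$effect[eff$gene_id == "ONC"], "activating")
  expect_equal(eff$effect[eff$gene_id == "TSG"], "disrupted")
  # a gene whose only breakpoints sit outside its CDS is neutral
  up_call <- data.frame(gene_id = "BYSTANDER", sample_id = "S99",
                        direction = "up", stringsAsFactors = FALSE)
  eff2 <- classify_gene_effects(ev, jn, models, candidates = fusion,
                                frames = frames, outlier_calls = up_call)
  expect_true(all(eff2$effect[eff2$gene_id == "BYSTANDER"] == "neutral"))
})

test_that("frame assessment does exact phase arithmetic in both strands", {
  models <- make_frame_model()
  # GA: CDS starts at 1100 (+); GB: CDS starts at 5200 (+)
  for (a in 0:2) {
    for (b in 0:2) {
      cand <- make_frame_candidate("X", "GA", 1100 + 300 + a, "GB", 5200 + b)
      st <- assess_frame(cand, models)$status
      expect_equal(st, if (a == b) "in_frame" else "out_of_frame",
                   label = sprintf("phase5=%d phase3=%d -> %s", a, b, st))
    }
  }
  # minus-strand 5' partner: retained CDS runs from the right
  candm <- make_frame_candidate("M", "GC", 10000 - 300, "GB", 5200)
  expect_equal(assess_frame(candm, models)$status, "in_frame")
  candm1 <- make_frame_candidate("M1", "GC", 10000 - 301, "GB", 5200)
  expect_equal(assess_frame(candm1, models)$status, "out_of_frame")
  # non-coding partner is undetermined; outside the span is an error
  nc <- make_frame_candidate("NC", "GA", 1400, "GNC", 12500)
  expect_equal(assess_frame(nc, models)$status, "undetermined")
  outside <- make_frame_candidate("OUT", "GA", 100, "GB", 5200)
  expect_error(assess_frame(outside, models), "OUT")
})

test_that("frame calls are invariant under whole-model coordinate translation", {
  for (off in c(0, 1e7, 12345)) {
    cand <- make_frame_candidate("X", "GA", 1400, "GB", 5200, offset = off)
    expect_equal(assess_frame(cand, make_frame_model(offset = off))$status,
                 "in_frame")
  }
})

test_that("fusion load summary counts retained fusions, events and ETS status", {
  cands <- rbind(
    make_cand("a", lib = "S01"), make_cand("b", lib = "S01", gene3 = "ERG"),
    make_cand("c", lib = "S01", split = 1, spanning = 1),
    make_cand("d", lib = "S02", readthrough = TRUE))
  v <- apply_primary_filters(cands)
  smry <- summarize_fusion_load(cands, v)
  expect_equal(smry$fusion_load[smry$sample_id == "S01"], 2L)
  expect_equal(smry$fusion_load[smry$sample_id == "S02"], 0L)
  expect_true(smry$ets_status[smry$sample_id == "S01"])
  expect_false(smry$ets_status[smry$sample_id == "S02"])
  ch <- simulate_complex_chain(6, seed = 30, sample_id = "S02")
  ev <- build_complex_events(ch$junctions)
  smry2 <- summarize_fusion_load(cands, v, events = ev)
  expect_equal(smry2$complex_count[smry2$sample_id == "S02"], 1L)
})
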