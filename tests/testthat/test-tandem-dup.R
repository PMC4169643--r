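test_that("focal gain detection applies the ratio threshold and length cap", {
  seg <- data.frame(
    sample = "T", chrom = "chr1",
    start = c(0, 1e6, 1.2e6, 10e6, 60e6),
    end = c(1e6, 1.2e6, 10e6, 50e6, 61e6),
    log2ratio = c(0, 0.58, 0, 0.9, 0.2), stringsAsFactors = FALSE)
  gains <- detect_focal_gains(seg, min_log2 = 0.3, max_length_bp = 5e6)
  expect_equal(nrow(gains), 1L)           # 40 Mb arm gain and 0.2 ratio excluded
  expect_equal(gains$start, 1e6)
  expect_equal(gains$length, 2e5)
  flat <- seg[seg$log2ratio == 0, ]
  expect_equal(nrow(detect_focal_gains(flat)), 0L)
})

test_that("duplication matching requires head-to-tail orientation and span agreement", {
  seg <- data.frame(sample = "T", chrom = "chr5",
                    start = c(0, 10e6, 10.5e6),
                    end = c(10e6, 10.5e6, 50e6),
                    log2ratio = c(0, 1, 0), stringsAsFactors = FALSE)
  gains <- detect_focal_gains(seg)
  dup_jn <- data.frame(id = "TD1", sample = "T", chromA = "chr5", posA = 10.5e6,
                       orientA = "-", chromB = "chr5", posB = 10e6, orientB = "+",
                       support_reads = 50L, stringsAsFactors = FALSE)
  del_jn <- data.frame(id = "DEL1", sample = "T", chromA = "chr5", posA = 10e6,
                       orientA = "-", chromB = "chr5", posB = 10.5e6, orientB = "+",
                       support_reads = 50L, stringsAsFactors = FALSE)
  tds <- match_duplications(gains, dup_jn)
  expect_equal(nrow(tds), 1L)
  expect_true(tds$gain_matched)
  # the deletion has "+" at the higher coordinate: never a duplication
  expect_equal(nrow(match_duplications(gains, del_jn)), 0L)
  tds <- estimate_copies(tds, seg)
  expect_equal(tds$estimated_copies, 2)  # log2ratio 1 -> 2*2^1 - 2
  expect_false(tds$subclonal)
})

test_that("copy estimation matches the ratio model and the junction-support route", {
  seg <- data.frame(sample = "T", chrom = "chr2",
                    start = c(0, 5e6), end = c(5e6, 5.2e6),
                    log2ratio = c(0, 0.585), stringsAsFactors = FALSE)
  gains <- detect_focal_gains(seg)
  jn <- data.frame(id = "TD1", sample = "T", chromA = "chr2", posA = 5.2e6,
                   orientA = "-", chromB = "chr2", posB = 5e6, orientB = "+",
                   support_reads = 20L, stringsAsFactors = FALSE)
  tds <- estimate_copies(match_duplications(gains, jn), seg)
  expect_equal(tds$estimated_copies, 2 * 2^0.585 - 2, tolerance = 1e-12)

  # sub-clonal event without a detectable coverage step: support route
  solo <- data.frame(id = "TD2", sample = "T", chromA = "chr2", posA = 30.2e6,
                     orientA = "-", chromB = "chr2", posB = 30e6, orientB = "+",
                     support_reads = 20L, stringsAsFactors = FALSE)
  flat <- data.frame(sample = "T", chrom = "chr2", start = 0, end = 50e6,
                     log2ratio = 0, stringsAsFactors = FALSE)
  tds2 <- estimate_copies(match_duplications(detect_focal_gains(flat), solo), flat,
                          clonal_support_reference = 50)
  expect_false(tds2$gain_matched)
  expect_equal(tds2$estimated_copies, 0.4)
  expect_true(tds2$subclonal)
})

test_that("nested serial duplications are reconstructed as a containment forest", {
  cfg <- small_cfg(seed = 13)
  sim <- simulate_tandem_dup_genome(cfg)
  gains <- detect_focal_gains(sim$seg)
  tds <- estimate_copies(match_duplications(gains, sim$junctions), sim$seg)
  truth <- sim$truth
  m <- merge(tds, truth, by = "junction_id", suffixes = c("", ".truth"))
  expect_equal(nrow(m), nrow(truth))  # every planted duplication recovered
  # copies within tolerance: exact model, so tight agreement
  expect_true(all(abs(m$estimated_copies - m$copies) < 0.25, na.rm = TRUE))
  expect_equal(m$subclonal, m$subclonal.truth)
  # nesting links mirror the planted parents (mapped through junction ids)
  planted_parent <- truth$parent[match(m$junction_id, truth$junction_id)]
  called_parent_jn <- m$junction_id[match(m$nested_parent, m$td_id)]
  expect_equal(is.na(called_parent_jn), is.na(planted_parent))
  expect_equal(called_parent_jn[!is.na(planted_parent)],
               planted_parent[!is.na(planted_parent)])
  # acyclic: walking parents always terminates
  for (i in seq_len(nrow(tds))) {
    seen <- character(0)
    p <- tds$nested_parent[i]
    while (!is.na(p)) {
      expect_false(p %in% seen)
      seen <- c(seen, p)
      p <- tds$nested_parent[tds$td_id == p]
    }
  }
})

test_that("the duplicator genotype is thresholded at >= 50 duplications", {
  fake_tds <- function(n) data.frame(td_id = sprintf("TD%d", seq_len(n)))
  expect_true(call_genotype(fake_tds(50), fake_tds(60))$is_duplicator)
  expect_false(call_genotype(fake_tds(49), fake_tds(60))$is_duplicator)
  expect_false(call_genotype(fake_tds(5), fake_tds(5))$is_duplicator)
})

test_that("cohort screening flags planted duplicator profiles, putative without junctions", {
  profiles <- list()
  junctions <- list()
  for (i in 1:12) {
    n_dup <- if (i <= 3) 80L else 5L
    cfg <- sim_config(n_samples = 3L,
                      td_spec = list(n_duplications = n_dup, n_subclonal = 0L,
                                     nested_n = 0L,
                                     sample_id = sprintf("P%02d", i)),
                      seed = 100 + i)
    sim <- simulate_tandem_dup_genome(cfg)
    profiles[[i]] <- sim$seg
    junctions[[i]] <- sim$junctions
  }
  seg <- do.call(rbind, profiles)
  screened <- screen_cohort(seg)
  expect_error(screen_cohort(seg[0, ]), "empty cohort")
  flagged <- screened$sample_id[screened$is_duplicator]
  expect_setequal(flagged, sprintf("P%02d", 1:3))
  expect_true(all(screened$status[screened$is_duplicator] == "putative"))
  expect_equal(screened$n_focal_gains, sort(screened$n_focal_gains, decreasing = TRUE))
  # supplying junctions upgrades the call to confirmed
  confirmed <- screen_cohort(seg, do.call(rbind, junctions))
  expect_true(all(confirmed$status[confirmed$is_duplicator] == "confirmed"))
  expect_setequal(confirmed$sample_id[confirmed$is_duplicator], sprintf("P%02d", 1:3))
})
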