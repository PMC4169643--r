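test_that("count simulation is deterministic and plants exactly the requested truth", {
  cfg <- small_cfg(seed = 3)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$truth), 30L)
  expect_true(all(a$truth$direction == "up"))
  expect_true(all(a$truth$gene_id %in% rownames(a$counts)))
  expect_true(all(a$truth$sample_id %in% colnames(a$counts)))

  null_sim <- simulate_counts(sim_config(n_samples = 12L, n_genes = 300L,
                                         outlier_spec = list(n_outlier_genes = 0L),
                                         seed = 3))
  expect_equal(nrow(null_sim$truth), 0L)

  expect_error(sim_config(n_samples = 5L,
                          outlier_spec = list(n_carrier_samples = 5L)),
               "n_carrier_samples")
})

test_that("non-carrier counts look negative binomial with the configured dispersion", {
  cfg <- sim_config(n_samples = 31L, n_genes = 600L,
                    outlier_spec = list(n_outlier_genes = 0L), seed = 8)
  sim <- simulate_counts(cfg)
  sf <- sim$true_size_factors
  norm <- sweep(sim$counts, 2, sf, `/`)
  mu <- rowMeans(norm)
  v <- apply(norm, 1, var)
  # regressing (var - mu) on mu^2 over genes recovers the dispersion
  keep <- mu > 50
  disp_hat <- coef(lm(I(v[keep] - mu[keep]) ~ 0 + I(mu[keep]^2)))[[1]]
  expect_gt(disp_hat, 0.15)
  expect_lt(disp_hat, 0.25)
})

test_that("noise simulation honors deterministic and stochastic modes", {
  cfg <- small_cfg(seed = 4)
  expect_equal(unname(simulate_noise(cfg)), rep(0.5, 12))
  zero <- small_cfg(seed = 4, noise_spec = list(mean_depth = 0))
  expect_equal(unname(simulate_noise(zero)), rep(0, 12))
  expect_error(sim_config(noise_spec = list(mean_depth = -1)), "mean_depth")
  sto <- small_cfg(seed = 4, noise_spec = list(stochastic = TRUE))
  expect_identical(simulate_noise(sto), simulate_noise(sto))
  expect_gt(var(simulate_noise(sto)), 0)
})

test_that("fusion candidate classes are labeled exhaustively and sized to spec", {
  cfg <- small_cfg(seed = 5)
  sim <- simulate_fusion_candidates(cfg)
  expect_equal(nrow(sim$truth), nrow(sim$candidates))
  expect_setequal(sim$truth$candidate_id, sim$candidates$id)
  tab <- table(sim$truth$class)
  expect_equal(as.integer(tab[c("true", "true_ets", "readthrough",
                                "recurrent_artifact", "multimap_artifact",
                                "repeat_artifact", "low_support")]),
               c(5L, 4L, 3L, 3L, 2L, 2L, 3L))
  # the recurrent ETS event shares one gene pair across its libraries
  ets <- sim$candidates[sim$candidates$id %in%
                          sim$truth$candidate_id[sim$truth$class == "true_ets"], ]
  expect_equal(length(unique(paste(ets$gene5, ets$gene3))), 1L)
  expect_equal(length(unique(ets$library_id)), 4L)
  expect_true(all(ets$gene3 == "ERG"))
  # low-support candidates sit on the <=5 side of the >5-read boundary
  low <- sim$candidates[sim$candidates$id %in%
                          sim$truth$candidate_id[sim$truth$class == "low_support"], ]
  expect_true(all(low$split_reads + low$spanning_reads <= 5))
  expect_true(all(low$split_reads + low$spanning_reads >= 1))
  # true fusions carry a corroborating junction; artifacts carry none
  n_true <- sum(sim$truth$is_true)
  expect_equal(nrow(sim$junctions), n_true)
})

test_that("chain simulation produces a connected chain and a reciprocal control", {
  ch <- simulate_complex_chain(6, seed = 10)
  expect_equal(nrow(ch$junctions), 6L)
  expect_identical(simulate_complex_chain(6, seed = 10)$junctions, ch$junctions)
  expect_error(simulate_complex_chain(1), ">= 2")
  rec <- simulate_complex_chain(2, seed = 11)
  expect_equal(nrow(rec$junctions), 2L)
})

test_that("tandem-duplication genome encodes copies in the segment ratios", {
  cfg <- small_cfg(seed = 6)
  sim <- simulate_tandem_dup_genome(cfg)
  expect_equal(nrow(sim$truth), 20L)
  expect_equal(sum(sim$truth$subclonal), 2L)
  expect_identical(simulate_tandem_dup_genome(cfg)$seg, sim$seg)
  # segments are a valid non-overlapping profile
  expect_silent(htxtools:::validate_seg(sim$seg))
  # an isolated clonal duplication's gain encodes log2((2+c)/2)
  iso <- sim$truth[is.na(sim$truth$parent) & !sim$truth$subclonal, ][1, ]
  hit <- sim$seg[sim$seg$chrom == iso$chrom & sim$seg$start == iso$start, ]
  expect_equal(hit$log2ratio, log2((2 + iso$copies) / 2))
  # the nested locus: innermost junction support exceeds the outer ones
  nested <- sim$truth[!is.na(sim$truth$parent) | sim$truth$junction_id %in%
                        sim$truth$parent, ]
  if (nrow(nested) >= 3) {
    sup <- sim$junctions$support_reads[match(nested$junction_id, sim$junctions$id)]
    inner <- which.max(nested$start)
    expect_gt(sup[inner], max(sup[-inner]))
  }
  # every junction corresponds to one truth record (label exhaustiveness)
  expect_setequal(sim$junctions$id, sim$truth$junction_id)
})
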