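test_that("median-of-ratios size factors match hand-derived values", {
  ident <- matrix(rep(c(5L, 9L, 13L), 3), nrow = 3,
                  dimnames = list(paste0("G", 1:3), paste0("S", 1:3)))
  expect_equal(unname(compute_size_factors(ident)), rep(1, 3))

  m <- matrix(c(10L, 30L, 20L, 60L), nrow = 2,
              dimnames = list(c("GA", "GB"), c("S1", "S2")))
  expect_equal(unname(compute_size_factors(m)), c(1 / sqrt(2), sqrt(2)))

  scaled <- m
  scaled[, 2] <- scaled[, 2] * 10L
  sf <- compute_size_factors(scaled)
  expect_equal(unname(sf), c(1 / sqrt(2) / sqrt(10), sqrt(2) * sqrt(10) * 10 / 10))
  # scaling one of two columns by c multiplies the ratio geometry through;
  # the direct check: s2/s1 grows by exactly the scaling factor
  expect_equal(unname(sf[2] / sf[1]), 10 * sqrt(2) * sqrt(2))

  zeros <- matrix(c(0L, 5L, 3L, 0L), nrow = 2,
                  dimnames = list(c("GA", "GB"), c("S1", "S2")))
  expect_error(compute_size_factors(zeros), "all-positive")
})

test_that("size factors agree with the established median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  counts <- matrix(rnbinom(200 * 8, mu = 50, size = 5), nrow = 200,
                   dimnames = list(paste0("G", 1:200), paste0("S", 1:8)))
  # DESeq2 takes the median on the log scale; for an even gene count the
  # two central values are averaged geometrically rather than
  # arithmetically, hence agreement to ~1e-4 rather than machine precision
  expect_equal(unname(compute_size_factors(counts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(counts)),
               tolerance = 1e-3)
})

test_that("depth conversion follows k/s * read_length / gene_length", {
  counts <- matrix(c(100L, 0L), nrow = 1, dimnames = list("GA", c("S1", "S2")))
  sf <- c(S1 = 1, S2 = 1)
  d <- counts_to_depth(counts, sf, c(GA = 1000), read_length = 100)
  expect_equal(unname(d["GA", ]), c(10, 0))
  d2 <- counts_to_depth(counts, c(S1 = 2, S2 = 1), c(GA = 1000))
  expect_equal(d2["GA", "S1"], 5)
  expect_error(counts_to_depth(counts, sf, c(GX = 10)), "GA")
})

test_that("generalized ESD handles degenerate and planted cases", {
  expect_equal(generalized_esd(rep(3, 20))$n_outliers, 0L)
  expect_error(generalized_esd(c(1, 2)), "at least 3")

  set.seed(101)
  x <- c(rnorm(30), 10)
  res <- generalized_esd(x, esd_params(r_max = 15, alpha = 0.05))
  expect_equal(res$n_outliers, 1L)
  expect_equal(res$outlier_indices, 31L)
  # every emitted step must have matched the oracle recursion
  orc <- oracle_esd(x, 15, 0.05)
  expect_equal(res$steps$R, orc$R)
  expect_equal(res$steps$lambda, orc$lambda)
})

test_that("generalized ESD matches the independent Rosner recursion on random vectors", {
  set.seed(2024)
  for (rep in 1:200) {
    n <- sample(10:31, 1)
    x <- rnorm(n) + sample(c(0, 4), n, replace = TRUE, prob = c(0.9, 0.1))
    res <- generalized_esd(x, esd_params(r_max = 15, alpha = 0.05))
    orc <- oracle_esd(x, 15, 0.05)
    expect_identical(res$n_outliers, as.integer(orc$n_outliers))
    expect_identical(as.integer(res$outlier_indices), as.integer(orc$outlier_indices))
    expect_equal(res$steps$R, orc$R)
    expect_equal(res$steps$lambda, orc$lambda)
  }
})

test_that("false-positive rate of the ESD on normal samples is near alpha", {
  set.seed(77)
  hits <- replicate(2000, generalized_esd(rnorm(31))$n_outliers > 0)
  # Rosner's critical values are approximate and testing up to n/2 outliers
  # inflates the family rate slightly; sanity band, not a calibration claim
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.09)
})

test_that("outlier calls honor depth rules, recurrence cap and direction", {
  n <- 12
  samples <- sprintf("S%02d", 1:n)
  base <- matrix(50, nrow = 4, ncol = n,
                 dimnames = list(c("UP", "UPLOW", "DOWN", "WIDE"), samples))
  set.seed(5)
  base <- base + matrix(rnorm(4 * n, sd = 2), nrow = 4)
  base["UP", 1] <- 800          # strong up outlier, high depth
  base["UPLOW", ] <- 0.5        # lowly expressed gene...
  base["UPLOW", 2] <- 8         # ...its 16x outlier is below the 10x rule
  base["DOWN", 3] <- 1          # down outlier in a well-covered gene
  base["WIDE", 1:5] <- 500      # flagged in 5 of 12 samples: > floor(12/3)

  calls <- call_outliers(base, noise = 0, esd_params(r_max = 5))
  expect_true(any(calls$gene_id == "UP" & calls$sample_id == "S01" &
                    calls$direction == "up"))
  expect_false(any(calls$gene_id == "UPLOW"))
  expect_true(any(calls$gene_id == "DOWN" & calls$sample_id == "S03" &
                    calls$direction == "down"))
  expect_false(any(calls$gene_id == "WIDE"))
  expect_true(all(calls$esd_statistic > calls$critical_value))
})

test_that("rescaling a sample's counts rescales depth uniformly and keeps calls stable", {
  cfg <- small_cfg(seed = 31)
  sim <- simulate_counts(cfg)
  sf_a <- compute_size_factors(sim$counts)
  depth_a <- counts_to_depth(sim$counts, sf_a, sim$models)
  scaled <- sim$counts
  scaled[, 3] <- scaled[, 3] * 7L
  sf_b <- compute_size_factors(scaled)
  depth_b <- counts_to_depth(scaled, sf_b, sim$models)
  # median-of-ratios spreads a single-column rescaling c across the cohort
  # as a uniform depth factor c^(1/m); per-sample calls cannot depend on
  # which column carried the library-size change
  m <- ncol(sim$counts)
  expect_equal(depth_b, depth_a * 7^(1 / m), tolerance = 1e-12)
  a <- call_outliers(depth_a, noise = 0)
  b <- call_outliers(depth_b, noise = 0)
  # away from the min-depth boundary the call sets coincide exactly
  key <- function(x) paste(x$gene_id, x$sample_id, x$direction)
  clear_a <- a[a$noise_corrected_depth > 15, ]
  clear_b <- b[b$noise_corrected_depth > 15 * 7^(1 / m), ]
  expect_setequal(key(clear_a), key(clear_b))
})

test_that("raising a sample's noise never creates a new up-call there", {
  cfg <- small_cfg(seed = 32)
  sim <- simulate_counts(cfg)
  sf <- compute_size_factors(sim$counts)
  depth <- counts_to_depth(sim$counts, sf, sim$models)
  low <- call_outliers(depth, noise = 0.2)
  noise <- setNames(rep(0.2, ncol(depth)), colnames(depth))
  noise["S05"] <- 25
  high <- call_outliers(depth, noise = noise)
  up_low <- low[low$direction == "up" & low$sample_id == "S05", ]
  up_high <- high[high$direction == "up" & high$sample_id == "S05", ]
  expect_true(all(up_high$gene_id %in% up_low$gene_id))
})
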