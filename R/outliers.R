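## Cohort outlier-expression calling.
##
## Counts are normalized by median-of-ratios size factors, converted to
## x-fold sequence depth, corrected by a per-sample background-noise
## estimate (mean intergenic/intronic coverage), and screened per gene by
## the Generalized Extreme Studentized Deviate (ESD) test. Up-regulated
## calls must exceed a minimum corrected depth; down-regulated calls
## require the non-outlier samples to exceed it; genes flagged in more
## than a fixed fraction of the cohort are dropped as non-outliers.

#' Parameters for the Generalized ESD test
#'
#' @param r_max Maximum number of outliers tested per gene (Rosner's upper
#'   bound). The effective bound is capped at half the cohort size.
#' @param alpha Significance level for the step-wise critical values.
#' @param two_sided Test deviations in both directions (default) or only
#'   upward.
#' @return List of class `esd_params`.
#' @export
esd_params <- function(r_max = 15L, alpha = 0.05, two_sided = TRUE) {
  assert_that(r_max >= 1L, "esd_params: r_max must be >= 1")
  assert_that(alpha > 0 && alpha < 1, "esd_params: alpha must be in (0,1)")
  structure(list(r_max = as.integer(r_max), alpha = alpha,
                 two_sided = isTRUE(two_sided)),
            class = "esd_params")
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors \eqn{s_j} computed as the median over genes of
#' \eqn{k_{ij} / (\prod_v k_{iv})^{1/m}}; genes with any zero count are
#' excluded from the median (their geometric mean is zero). This is the
#' classical count-normalization used for bulk RNA-seq cohorts, correcting
#' library depth and composition.
#'
#' @param counts Integer matrix (genes x samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
compute_size_factors <- function(counts) {
  assert_that(is.matrix(counts) && nrow(counts) >= 1L && ncol(counts) >= 1L,
              "compute_size_factors: counts must be a non-empty matrix")
  log_geo <- rowMeans(log(counts))
  keep <- is.finite(log_geo)
  if (!any(keep)) {
    stop_format(paste0("compute_size_factors: no gene has all-positive counts; ",
                       "median-of-ratios is undefined (pseudo-reference fallback is disabled)"))
  }
  sf <- apply(counts, 2L, function(col) {
    stats::median(exp(log(col[keep]) - log_geo[keep]))
  })
  stats::setNames(sf, colnames(counts))
}

#' Convert normalized counts to x-fold sequence depth
#'
#' `depth_ij = (k_ij / s_j) * read_length / gene_length_i`, making the
#' "depth greater than 10X" rules computable from gene-level counts.
#'
#' @param counts Integer matrix (genes x samples).
#' @param size_factors Named per-sample size factors (see
#'   [compute_size_factors()]).
#' @param gene_len Named vector of exonic gene lengths in bp, or a
#'   gene-model `data.frame` (converted via [gene_lengths()]).
#' @param read_length Read length in bp (default 100).
#' @return Numeric matrix of the same shape as `counts`, in x-coverage
#'   units.
#' @export
counts_to_depth <- function(counts, size_factors, gene_len, read_length = 100) {
  if (is.data.frame(gene_len)) gene_len <- gene_lengths(gene_len)
  missing <- setdiff(rownames(counts), names(gene_len))
  if (length(missing) > 0L) {
    stop_format("counts_to_depth: no gene model for: %s",
                paste(utils::head(missing, 10L), collapse = ", "))
  }
  len <- gene_len[rownames(counts)]
  assert_that(all(len > 0), "counts_to_depth: gene lengths must be positive")
  sf <- size_factors[colnames(counts)]
  assert_that(!anyNA(sf), "counts_to_depth: size factor missing for some sample")
  sweep(counts, 2L, sf, `/`) * read_length / len
}

## step-wise two-sided critical value of Rosner's procedure
esd_lambda <- function(n, i, alpha, two_sided = TRUE) {
  p <- if (two_sided) 1 - alpha / (2 * (n - i + 1)) else 1 - alpha / (n - i + 1)
  t <- stats::qt(p, df = n - i - 1)
  (n - i) * t / sqrt((n - i - 1 + t^2) * (n - i + 1))
}

#' Generalized ESD (Rosner) outlier test
#'
#' Iteratively removes the most extreme studentized deviate: at step
#' \eqn{i}, \eqn{R_i = \max_k |x_k - \bar x| / s} over the remaining
#' values, compared against \eqn{\lambda_i = (n-i)\,t_{p,n-i-1} /
#' \sqrt{(n-i-1+t^2_{p,n-i-1})(n-i+1)}} with
#' \eqn{p = 1 - \alpha/(2(n-i+1))}. The declared number of outliers is the
#' largest \eqn{i} with \eqn{R_i > \lambda_i}.
#'
#' A zero standard deviation at any step is degenerate (no further
#' deviates can be ranked); testing stops there without error, so a
#' constant vector yields zero outliers.
#'
#' @param values Numeric vector, length >= 3.
#' @param params [esd_params()] list; `r_max` must be < `length(values)`.
#' @return List with `n_outliers`, `outlier_indices` (into `values`, in
#'   removal order), and `steps`, a `data.frame` of per-step `i`, `index`,
#'   `R`, `lambda`.
#' @export
generalized_esd <- function(values, params = esd_params()) {
  n <- length(values)
  assert_that(n >= 3L, "generalized_esd: need at least 3 values (got %d)", n)
  # the step-i critical value needs n - i - 1 >= 1 degrees of freedom
  r_max <- min(params$r_max, n - 2L)
  assert_that(r_max >= 1L, "generalized_esd: r_max must be >= 1")
  x <- as.numeric(values)
  idx <- seq_len(n)
  steps <- data.frame(i = integer(0), index = integer(0),
                      R = numeric(0), lambda = numeric(0))
  for (i in seq_len(r_max)) {
    m <- mean(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- if (params$two_sided) abs(x - m) else (x - m)
    k <- which.max(dev)
    R <- dev[k] / s
    lambda <- esd_lambda(n, i, params$alpha, params$two_sided)
    steps <- rbind(steps, data.frame(i = i, index = idx[k], R = R, lambda = lambda))
    x <- x[-k]
    idx <- idx[-k]
  }
  n_out <- if (nrow(steps) > 0L && any(steps$R > steps$lambda)) {
    max(steps$i[steps$R > steps$lambda])
  } else 0L
  list(n_outliers = as.integer(n_out),
       outlier_indices = steps$index[seq_len(n_out)],
       steps = steps)
}

#' Call per-sample outlier genes across a cohort
#'
#' For each gene the ESD test is run across samples on
#' `log2(max(depth - noise, 0) + 1)`. Flagged samples become calls with a
#' direction given by the sign of the deviation from the mean of the
#' non-flagged samples. Calls are then screened by the depth rules:
#' up-regulated calls need a noise-corrected depth greater than
#' `min_depth` in the outlier sample; down-regulated calls need the mean
#' corrected depth of the non-outlier samples to exceed `min_depth`.
#' Genes flagged in more than `floor(recurrence_fraction * n_samples)`
#' samples are dropped entirely (an "outlier" shared by a third of the
#' cohort is cohort structure, not an outlier).
#'
#' @param depth Numeric matrix (genes x samples) of x-fold depth.
#' @param noise Named per-sample background depth estimates (x units); a
#'   single scalar is recycled.
#' @param params [esd_params()].
#' @param min_depth Depth threshold in x units (default 10).
#' @param recurrence_fraction Maximum tolerated flagged fraction of the
#'   cohort (default 1/3).
#' @param log_transform Run the ESD on log2(depth+1) (default) rather than
#'   raw corrected depth.
#' @return `data.frame` with columns `gene_id`, `sample_id`, `direction`
#'   (`"up"`/`"down"`), `esd_statistic`, `critical_value`,
#'   `noise_corrected_depth`.
#' @export
call_outliers <- function(depth, noise = 0, params = esd_params(),
                          min_depth = 10, recurrence_fraction = 1 / 3,
                          log_transform = TRUE) {
  n <- ncol(depth)
  assert_that(n >= 3L, "call_outliers: need at least 3 samples")
  if (length(noise) == 1L && is.null(names(noise))) {
    noise <- stats::setNames(rep(noise, n), colnames(depth))
  }
  assert_that(all(colnames(depth) %in% names(noise)),
              "call_outliers: noise estimates and depth matrix have inconsistent sample ids")
  noise <- noise[colnames(depth)]
  assert_that(all(noise >= 0), "call_outliers: noise estimates must be >= 0")

  corrected <- pmax(sweep(depth, 2L, noise, `-`), 0)
  y <- if (log_transform) log2(corrected + 1) else corrected
  eff <- params
  eff$r_max <- max(1L, min(params$r_max, floor(n / 2)))
  max_flagged <- floor(recurrence_fraction * n)

  calls <- vector("list", nrow(depth))
  for (g in seq_len(nrow(depth))) {
    res <- generalized_esd(y[g, ], eff)
    if (res$n_outliers == 0L || res$n_outliers > max_flagged) next
    flagged <- res$outlier_indices
    ref_mean <- mean(y[g, -flagged])
    nonout_depth <- mean(corrected[g, -flagged])
    rows <- lapply(seq_along(flagged), function(r) {
      j <- flagged[r]
      up <- y[g, j] > ref_mean
      cd <- corrected[g, j]
      keep <- if (up) cd > min_depth else nonout_depth > min_depth
      if (!keep) return(NULL)
      data.frame(gene_id = rownames(depth)[g],
                 sample_id = colnames(depth)[j],
                 direction = if (up) "up" else "down",
                 esd_statistic = res$steps$R[r],
                 critical_value = res$steps$lambda[r],
                 noise_corrected_depth = cd,
                 stringsAsFactors = FALSE)
    })
    calls[[g]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, calls)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), sample_id = character(0),
                      direction = character(0), esd_statistic = numeric(0),
                      critical_value = numeric(0),
                      noise_corrected_depth = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
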