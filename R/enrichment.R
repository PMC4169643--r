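## Over-representation analysis of per-sample outlier gene sets against a
## user-supplied GMT collection. The per-set p-value is the exact
## hypergeometric upper tail; per-sample p-values are Benjamini-Hochberg
## adjusted across all sets tested for that sample, and reported as a
## pathway score -log10(adjusted p), displayed when the score exceeds 1
## (adjusted p < 0.1).

#' Exact hypergeometric over-representation p-value
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(`N`, `K`, `n`): the
#' probability of drawing at least `k` set members in a query of size `n`
#' from a universe of `N` genes of which `K` are in the set.
#'
#' @param k Observed overlap.
#' @param K Set size (within the universe).
#' @param n Query size.
#' @param N Universe size.
#' @return p-value in (0, 1].
#' @export
hypergeometric_p <- function(k, K, n, N) {
  assert_that(k >= 0 && K >= 0 && n >= 0 && N >= 1,
              "hypergeometric_p: negative or empty arguments")
  assert_that(K <= N && n <= N, "hypergeometric_p: K and n must be <= N")
  assert_that(k <= min(K, n), "hypergeometric_p: k must be <= min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted values \eqn{q_{(k)} = \min_{j \ge k} \min(1,
#' p_{(j)} m / j)}, returned in the original order.
#'
#' @param p Vector of raw p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  assert_that(length(p) > 0L, "bh_adjust: empty input")
  assert_that(all(p > 0 & p <= 1), "bh_adjust: p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Enrichment of one sample's outlier genes
#'
#' Tests every set in the collection (intersected with the universe)
#' against the sample's outlier gene set; BH adjustment is across all
#' sets tested for this sample. The `shown` flag reproduces the display
#' rule pathway_score > 1 (i.e. adjusted p < 0.1), strictly.
#'
#' @param outlier_genes Character vector of this sample's outlier genes;
#'   must be a subset of `universe`.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector of testable genes (conventionally all
#'   genes in the count matrix).
#' @param sample_id Optional sample label carried into the result.
#' @return `data.frame` with one row per set: `sample_id`, `set_name`,
#'   `overlap`, `set_size`, `query_size`, `universe_size`, `p_value`,
#'   `p_bh`, `pathway_score`, `shown`.
#' @export
enrich_sample <- function(outlier_genes, sets, universe, sample_id = NA_character_) {
  universe <- unique(universe)
  assert_that(length(universe) > 0L, "enrich_sample: empty universe")
  outlier_genes <- unique(outlier_genes)
  stray <- setdiff(outlier_genes, universe)
  assert_that(length(stray) == 0L,
              "enrich_sample: outlier genes outside the universe: %s",
              paste(utils::head(stray, 5L), collapse = ", "))
  assert_that(length(sets) > 0L, "enrich_sample: empty gene-set collection")
  N <- length(universe)
  n <- length(outlier_genes)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    k <- length(intersect(outlier_genes, members))
    data.frame(sample_id = sample_id, set_name = nm,
               overlap = k, set_size = length(members),
               query_size = n, universe_size = N,
               p_value = hypergeometric_p(k, length(members), n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bh <- bh_adjust(res$p_value)
  res$pathway_score <- -log10(res$p_bh)
  res$shown <- res$pathway_score > 1
  res
}

#' Enrichment across all samples of an outlier-call table
#'
#' Convenience wrapper running [enrich_sample()] per sample of a
#' [call_outliers()] result.
#'
#' @param outlier_calls Outlier-call `data.frame`.
#' @param sets Named list of gene sets.
#' @param universe Character vector of testable genes.
#' @param directions Which call directions enter the query (default both).
#' @return Long `data.frame`, one row per (sample, set).
#' @export
enrich_cohort <- function(outlier_calls, sets, universe,
                          directions = c("up", "down")) {
  calls <- outlier_calls[outlier_calls$direction %in% directions, , drop = FALSE]
  samples <- sort(unique(calls$sample_id))
  out <- lapply(samples, function(s) {
    genes <- unique(calls$gene_id[calls$sample_id == s])
    enrich_sample(genes, sets, universe, sample_id = s)
  })
  if (length(out) == 0L) {
    return(enrich_sample(character(0), sets, universe)[0, , drop = FALSE])
  }
  do.call(rbind, out)
}
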