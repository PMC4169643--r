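## Simplified gene models: per-gene exon (and optional CDS) intervals,
## used for depth conversion, exon-level breakpoint logic and reading-frame
## assessment. On disk this is plain GTF restricted to exon/CDS features
## with a gene_id attribute; internally coordinates are 0-based half-open.

#' Read simplified gene models from GTF
#'
#' Only `exon` and `CDS` feature rows are kept; each must carry a
#' `gene_id` attribute. Coordinates are converted from GTF's 1-based
#' inclusive to 0-based half-open. Exons of one gene must be
#' non-overlapping and any CDS must lie within the exon span.
#'
#' @param path GTF file.
#' @return `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `feature` (`"exon"` or `"CDS"`), `start`, `end`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- as.character(gr$type) %in% c("exon", "CDS")
  gr <- gr[keep]
  assert_that(length(gr) > 0L, "gene models '%s': no exon/CDS rows", path)
  assert_that(!is.null(gr$gene_id) && !anyNA(gr$gene_id),
              "gene models '%s': every exon/CDS row needs a gene_id attribute", path)
  models <- data.frame(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = as.character(gr$type),
    start = GenomicRanges::start(gr) - 1,  # 1-based inclusive -> 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    stringsAsFactors = FALSE)
  assert_that(all(models$strand %in% c("+", "-")),
              "gene models '%s': strand must be '+' or '-'", path)
  models <- models[order(models$gene_id, models$feature, models$start), , drop = FALSE]
  rownames(models) <- NULL
  validate_gene_models(models, path)
  models
}

validate_gene_models <- function(models, what = "gene models") {
  for (g in unique(models$gene_id)) {
    sub <- models[models$gene_id == g, , drop = FALSE]
    assert_that(length(unique(sub$chrom)) == 1L && length(unique(sub$strand)) == 1L,
                "%s: gene '%s' spans multiple chromosomes/strands", what, g)
    ex <- sub[sub$feature == "exon", , drop = FALSE]
    assert_that(nrow(ex) > 0L, "%s: gene '%s' has no exons", what, g)
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
      stop_format("%s: overlapping exons in gene '%s'", what, g)
    }
    cds <- sub[sub$feature == "CDS", , drop = FALSE]
    if (nrow(cds) > 0L) {
      assert_that(min(cds$start) >= min(ex$start) && max(cds$end) <= max(ex$end),
                  "%s: CDS outside exon span in gene '%s'", what, g)
    }
  }
  invisible(TRUE)
}

#' Write simplified gene models as GTF
#' @param models Gene-model `data.frame` in internal coordinates.
#' @param path Output path.
#' @export
write_gene_models <- function(models, path) {
  lines <- sprintf("%s\thtxtools\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                   models$chrom, models$feature,
                   as.integer(models$start + 1), as.integer(models$end),
                   models$strand, models$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Summarize gene models to one row per gene
#'
#' @param models Gene-model `data.frame` (see [read_gene_models()]).
#' @return `data.frame` with one row per gene: `gene_id`, `chrom`,
#'   `strand`, `span_start`, `span_end`, `gene_length` (sum of exon
#'   lengths, bp), `cds_start`, `cds_end` (NA when non-coding).
#' @export
gene_model_summary <- function(models) {
  genes <- unique(models$gene_id)
  out <- lapply(genes, function(g) {
    sub <- models[models$gene_id == g, , drop = FALSE]
    ex <- sub[sub$feature == "exon", , drop = FALSE]
    cds <- sub[sub$feature == "CDS", , drop = FALSE]
    data.frame(gene_id = g, chrom = sub$chrom[1L], strand = sub$strand[1L],
               span_start = min(ex$start), span_end = max(ex$end),
               gene_length = sum(ex$end - ex$start),
               cds_start = if (nrow(cds) > 0L) min(cds$start) else NA_real_,
               cds_end = if (nrow(cds) > 0L) max(cds$end) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract per-gene exonic lengths
#' @param models Gene-model `data.frame`.
#' @return Named numeric vector of summed exon lengths (bp).
#' @export
gene_lengths <- function(models) {
  smry <- gene_model_summary(models)
  stats::setNames(smry$gene_length, smry$gene_id)
}
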