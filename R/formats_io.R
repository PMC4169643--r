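## Readers/writers for the tabular formats the pipeline consumes.
##
## All genomic coordinates are held internally as 0-based half-open
## intervals. SEG files are treated as 1-based inclusive on disk (the
## common dialect) and converted on read/write; BEDPE is 0-based half-open
## on disk already. Junction-end "orientation" encodes which genomic side
## is retained at a rearrangement junction ("+" = left side retained) and
## is carried in the BEDPE strand columns.

#' Read a gene-by-sample count matrix from TSV
#'
#' The first column holds gene identifiers, the header row holds sample
#' identifiers, and every cell must be a non-negative integer raw read
#' count. Row and column order are preserved.
#'
#' @param path Path to a tab-separated file.
#' @return Integer matrix (genes x samples) with `rownames` = gene ids and
#'   `colnames` = sample ids.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  assert_that(ncol(df) >= 2L, "count matrix '%s': need a gene id column plus >=1 sample", path)
  genes <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(genes)) {
    stop_format("count matrix '%s': duplicate gene id '%s'",
                path, genes[duplicated(genes)][1L])
  }
  if (anyDuplicated(samples)) {
    stop_format("count matrix '%s': duplicate sample id '%s'",
                path, samples[duplicated(samples)][1L])
  }
  mat <- matrix(NA_integer_, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    cell <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | num < 0 | num != floor(num))
    if (length(bad) > 0L) {
      stop_format("count matrix '%s': cell for gene '%s', sample '%s' is '%s' (must be a non-negative integer)",
                  path, genes[bad[1L]], samples[j], cell[bad[1L]])
    }
    mat[, j] <- as.integer(num)
  }
  mat
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_matrix()]; round-trips bit-identically.
#'
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts),
                   as.data.frame(counts, check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are dropped.
#'
#' @param path GMT file.
#' @return Named list of character vectors (one per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  assert_that(length(lines) > 0L, "GMT '%s': file is empty", path)
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop_format("GMT '%s': line %d has %d field(s); need at least 3 (name, description, >=1 gene)",
                  path, i, length(fields))
    }
    name <- fields[1L]
    assert_that(!name %in% names(sets), "GMT '%s': duplicate set name '%s' (line %d)", path, name, i)
    sets[[name]] <- unique(fields[-(1:2)])
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read copy-number segments (SEG)
#'
#' SEG dialect: header plus columns `sample`, `chrom`, `start`, `end`,
#' `log2ratio`; 1-based inclusive coordinates on disk, converted to
#' 0-based half-open internally. Segments are grouped by sample and
#' sorted; overlapping segments within one sample/chromosome are an error.
#'
#' @param path SEG file.
#' @return `data.frame` with columns `sample`, `chrom`, `start`, `end`
#'   (0-based half-open), `log2ratio`, sorted by sample, chrom, start.
#' @export
read_seg <- function(path) {
  df <- read_tsv(path)
  check_columns(df, c("sample", "chrom", "start", "end", "log2ratio"),
                sprintf("SEG '%s'", path))
  for (col in c("start", "end", "log2ratio")) {
    df[[col]] <- as.numeric(df[[col]])
    assert_that(!anyNA(df[[col]]), "SEG '%s': non-numeric value in column '%s'", path, col)
  }
  seg <- data.frame(sample = as.character(df$sample),
                    chrom = as.character(df$chrom),
                    start = df$start - 1,   # 1-based inclusive -> 0-based half-open
                    end = df$end,
                    log2ratio = df$log2ratio,
                    stringsAsFactors = FALSE)
  assert_that(all(seg$end > seg$start), "SEG '%s': segment with end <= start", path)
  seg <- seg[order(seg$sample, seg$chrom, seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  validate_seg(seg, path)
  seg
}

validate_seg <- function(seg, what = "segments") {
  for (key in unique(paste(seg$sample, seg$chrom))) {
    sub <- seg[paste(seg$sample, seg$chrom) == key, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop_format("%s: overlapping segments for sample '%s' chrom '%s'",
                  what, sub$sample[1L], sub$chrom[1L])
    }
  }
  invisible(TRUE)
}

#' Write copy-number segments (SEG)
#'
#' Inverse of [read_seg()]; emits 1-based inclusive coordinates.
#' @param seg Segment `data.frame` in internal coordinates.
#' @param path Output path.
#' @export
write_seg <- function(seg, path) {
  out <- data.frame(sample = seg$sample, chrom = seg$chrom,
                    start = seg$start + 1, end = seg$end,
                    log2ratio = seg$log2ratio)
  write_tsv(out, path)
}

#' Read DNA rearrangement junctions (BEDPE)
#'
#' BEDPE with >= 10 columns: chrom1 start1 end1 chrom2 start2 end2 name
#' score strand1 strand2, plus an optional 11th `sample` column. The
#' score column is read as split/spanning read support and the strand
#' columns as junction-end orientations (`+` = genomic left side retained
#' at the junction). End positions are taken from the start columns
#' (0-based).
#'
#' @param path BEDPE file (no header).
#' @return `data.frame` with columns `id`, `sample`, `chromA`, `posA`,
#'   `orientA`, `chromB`, `posB`, `orientB`, `support_reads`.
#' @export
read_bedpe <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 10L, "BEDPE '%s': %d column(s); need >= 10", path, ncol(df))
  strands <- c(df[[9L]], df[[10L]])
  bad <- strands[!strands %in% c("+", "-")]
  if (length(bad) > 0L) {
    stop_format("BEDPE '%s': malformed strand '%s' (must be '+' or '-')", path, bad[1L])
  }
  support <- suppressWarnings(as.integer(df[[8L]]))
  assert_that(!anyNA(support) && all(support >= 0L),
              "BEDPE '%s': score column must hold non-negative integer read support", path)
  data.frame(id = as.character(df[[7L]]),
             sample = if (ncol(df) >= 11L) as.character(df[[11L]]) else NA_character_,
             chromA = as.character(df[[1L]]), posA = as.numeric(df[[2L]]),
             orientA = df[[9L]],
             chromB = as.character(df[[4L]]), posB = as.numeric(df[[5L]]),
             orientB = df[[10L]],
             support_reads = support,
             stringsAsFactors = FALSE)
}

#' Write junctions as BEDPE
#' @param junctions Junction `data.frame` as returned by [read_bedpe()].
#' @param path Output path.
#' @export
write_bedpe <- function(junctions, path) {
  out <- data.frame(junctions$chromA, junctions$posA, junctions$posA + 1,
                    junctions$chromB, junctions$posB, junctions$posB + 1,
                    junctions$id, junctions$support_reads,
                    junctions$orientA, junctions$orientB,
                    junctions$sample)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

fusion_required_cols <- c("id", "library_id", "gene5", "gene3",
                          "chrom5", "pos5", "orient5",
                          "chrom3", "pos3", "orient3",
                          "split_reads", "spanning_reads",
                          "is_readthrough", "multimapping", "repeat_fraction")

#' Read fusion-transcript candidates
#'
#' A minimal tabular dialect holding the fields the filtering cascade
#' needs, one candidate per row. For deFuse output the mapping is:
#' `gene5`/`gene3` = upstream/downstream gene, `split_reads` =
#' `splitr_count`, `spanning_reads` = `span_count`, `is_readthrough` =
#' `adjacent & !deletion`, `multimapping` = `!(break_predict == "split")`
#' ambiguity flag, `repeat_fraction` = `repeat_proportion`. Any extra
#' columns (for example PCR-primer bookkeeping) are carried through
#' untouched.
#'
#' @param path TSV with a header containing at least the required columns.
#' @return `data.frame` of candidates in file order.
#' @export
read_fusion_candidates <- function(path) {
  df <- read_tsv(path)
  check_columns(df, fusion_required_cols, sprintf("fusion candidates '%s'", path))
  df$id <- as.character(df$id)
  assert_that(!anyDuplicated(df$id), "fusion candidates '%s': duplicate candidate id", path)
  for (col in c("pos5", "pos3", "split_reads", "spanning_reads", "repeat_fraction")) {
    df[[col]] <- as.numeric(df[[col]])
    assert_that(!anyNA(df[[col]]), "fusion candidates '%s': non-numeric value in '%s'", path, col)
  }
  assert_that(all(df$split_reads >= 0) && all(df$spanning_reads >= 0),
              "fusion candidates '%s': negative read counts", path)
  if (any(df$repeat_fraction < 0 | df$repeat_fraction > 1)) {
    bad <- which(df$repeat_fraction < 0 | df$repeat_fraction > 1)[1L]
    stop_format("fusion candidates '%s': repeat_fraction %s for candidate '%s' outside [0,1]",
                path, df$repeat_fraction[bad], df$id[bad])
  }
  for (col in c("is_readthrough", "multimapping")) {
    df[[col]] <- as.logical(df[[col]])
    assert_that(!anyNA(df[[col]]), "fusion candidates '%s': column '%s' must be logical", path, col)
  }
  ok <- c(df$orient5, df$orient3) %in% c("+", "-")
  assert_that(all(ok), "fusion candidates '%s': orientations must be '+' or '-'", path)
  df
}

#' Write fusion-transcript candidates
#' @param candidates Candidate `data.frame`.
#' @param path Output path.
#' @export
write_fusion_candidates <- function(candidates, path) {
  write_tsv(candidates, path)
}
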