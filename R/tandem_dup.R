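## Tandem-duplication calling: focal copy-number gains are intersected
## with duplication-orientation DNA junctions; per-duplication copy
## numbers are estimated from the log2-ratio steps (with correction for
## nested/serial duplications) or, when only junction evidence exists,
## from junction read support relative to a clonal reference. Genomes
## with tens to hundreds of dispersed tandem duplications are called as
## the tandem-duplicator genotype.
##
## Orientation convention (mirrored by the synthetic generator): a
## tandem-duplication junction joins the end of the gained segment
## (orientation "-") back to its start (orientation "+"), i.e. the "+"
## end sits at the lower coordinate. Deletion junctions carry the
## opposite orientations and are never matched.

#' Detect focal copy-number gains
#'
#' Every segment with `log2ratio >= min_log2` and length at most
#' `max_length_bp` — the focal-gain pattern distinctive of tandem
#' duplications, excluding arm-level gains.
#'
#' @param seg Segment `data.frame` (see [read_seg()]).
#' @param min_log2 Gain threshold on the log2 ratio (default 0.3).
#' @param max_length_bp Focality cap (default 5 Mb).
#' @return Subset of `seg` with an added `length` column, sorted by
#'   position.
#' @export
detect_focal_gains <- function(seg, min_log2 = 0.3, max_length_bp = 5e6) {
  len <- seg$end - seg$start
  gains <- seg[seg$log2ratio >= min_log2 & len <= max_length_bp, , drop = FALSE]
  gains$length <- gains$end - gains$start
  gains <- gains[order(gains$chrom, gains$start), , drop = FALSE]
  rownames(gains) <- NULL
  gains
}

## candidate gain spans: raw gain segments plus every contiguous run of
## adjacent gain segments (a nested/serial duplication locus flattens into
## several abutting segments; the outer duplication's span is such a run)
gain_candidate_spans <- function(gains) {
  if (nrow(gains) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  spans <- list()
  for (chrom in unique(gains$chrom)) {
    g <- gains[gains$chrom == chrom, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    run_id <- cumsum(c(1L, as.integer(g$start[-1L] != g$end[-nrow(g)])))
    for (r in unique(run_id)) {
      gr <- g[run_id == r, , drop = FALSE]
      m <- nrow(gr)
      for (i in seq_len(m)) {
        for (j in i:m) {
          spans[[length(spans) + 1L]] <- data.frame(
            chrom = chrom, start = gr$start[i], end = gr$end[j])
        }
      }
    }
  }
  unique(do.call(rbind, spans))
}

## normalize junctions to duplication orientation: "+" end at the lower
## coordinate (gain start), "-" end at the higher (gain end)
dup_oriented_junctions <- function(junctions) {
  same_chrom <- junctions$chromA == junctions$chromB
  plus_pos <- ifelse(junctions$orientA == "+", junctions$posA, junctions$posB)
  minus_pos <- ifelse(junctions$orientA == "-", junctions$posA, junctions$posB)
  one_each <- (junctions$orientA == "+") != (junctions$orientB == "+")
  ok <- same_chrom & one_each & plus_pos < minus_pos
  out <- junctions[ok, , drop = FALSE]
  out$span_start <- plus_pos[ok]
  out$span_end <- minus_pos[ok]
  out
}

#' Match focal gains to duplication-orientation junctions
#'
#' A gain matches a junction when they share a chromosome, the junction
#' span coincides with the gain span within `boundary_tolerance_bp` at
#' both boundaries, and the junction orientations are head-to-tail.
#' Nested/serial loci are handled by also considering spans formed by
#' contiguous runs of gain segments. Each junction matches at most one
#' gain span (nearest boundaries win). Head-to-tail junctions without a
#' coinciding gain (for example sub-clonal duplications whose coverage
#' step is below the gain threshold) are emitted with
#' `gain_matched = FALSE` provided their span respects `max_length_bp`.
#' `nested_parent` links each duplication to the smallest strictly
#' containing one.
#'
#' @param gains [detect_focal_gains()] result for one sample.
#' @param junctions Junction `data.frame` for the same sample.
#' @param boundary_tolerance_bp Boundary tolerance (default 10 kb).
#' @param max_length_bp Span cap for junction-only duplications
#'   (default 5 Mb).
#' @return `data.frame` with one row per tandem duplication: `td_id`,
#'   `junction_id`, `sample`, `chrom`, `start`, `end`, `length`,
#'   `support_reads`, `gain_matched`, `nested_parent`.
#' @export
match_duplications <- function(gains, junctions, boundary_tolerance_bp = 1e4,
                               max_length_bp = 5e6) {
  dup <- dup_oriented_junctions(junctions)
  spans <- gain_candidate_spans(gains)
  rows <- list()
  for (i in seq_len(nrow(dup))) {
    j <- dup[i, , drop = FALSE]
    cand <- spans[spans$chrom == j$chromA, , drop = FALSE]
    matched <- FALSE
    if (nrow(cand) > 0L) {
      d_start <- abs(cand$start - j$span_start)
      d_end <- abs(cand$end - j$span_end)
      ok <- d_start <= boundary_tolerance_bp & d_end <= boundary_tolerance_bp
      if (any(ok)) matched <- TRUE
    }
    if (!matched && (j$span_end - j$span_start) > max_length_bp) next
    rows[[length(rows) + 1L]] <- data.frame(
      junction_id = j$id, sample = j$sample, chrom = j$chromA,
      start = j$span_start, end = j$span_end,
      length = j$span_end - j$span_start,
      support_reads = j$support_reads, gain_matched = matched,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(td_id = character(0), junction_id = character(0),
                      sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), length = numeric(0),
                      support_reads = integer(0), gain_matched = logical(0),
                      nested_parent = character(0), stringsAsFactors = FALSE))
  }
  tds <- do.call(rbind, rows)
  tds <- tds[order(tds$chrom, tds$start, -tds$end), , drop = FALSE]
  tds$td_id <- sprintf("TD%04d", seq_len(nrow(tds)))
  tds$nested_parent <- NA_character_
  for (i in seq_len(nrow(tds))) {
    enclosing <- which(tds$chrom == tds$chrom[i] &
                         tds$start <= tds$start[i] & tds$end >= tds$end[i] &
                         (tds$start < tds$start[i] | tds$end > tds$end[i]))
    if (length(enclosing) > 0L) {
      smallest <- enclosing[which.min(tds$end[enclosing] - tds$start[enclosing])]
      tds$nested_parent[i] <- tds$td_id[smallest]
    }
  }
  rownames(tds) <- NULL
  tds[, c("td_id", "junction_id", "sample", "chrom", "start", "end",
          "length", "support_reads", "gain_matched", "nested_parent")]
}

## subtract a set of intervals from [start, end]; returns remaining pieces
interval_subtract <- function(start, end, minus) {
  pieces <- data.frame(start = start, end = end)
  if (nrow(minus) > 0L) {
    for (i in seq_len(nrow(minus))) {
      nxt <- list()
      for (p in seq_len(nrow(pieces))) {
        s <- pieces$start[p]; e <- pieces$end[p]
        ms <- minus$start[i]; me <- minus$end[i]
        if (me <= s || ms >= e) {
          nxt[[length(nxt) + 1L]] <- data.frame(start = s, end = e)
        } else {
          if (ms > s) nxt[[length(nxt) + 1L]] <- data.frame(start = s, end = ms)
          if (me < e) nxt[[length(nxt) + 1L]] <- data.frame(start = me, end = e)
        }
      }
      pieces <- if (length(nxt) > 0L) do.call(rbind, nxt) else pieces[0, ]
      if (nrow(pieces) == 0L) break
    }
  }
  pieces
}

#' Estimate per-duplication copy numbers
#'
#' For gain-matched duplications the coverage route is used:
#' `copies = ploidy * 2^log2ratio - ploidy`, where the log2 ratio is the
#' length-weighted mean over the part of the duplication span not covered
#' by nested child duplications, and the contributions of enclosing
#' (ancestor) duplications are subtracted. Junction-only duplications use
#' the support route `copies = support_reads / clonal_support_reference`.
#' Estimates below one copy flag sub-clonality (the duplication is
#' present in only a fraction of tumor cells). A coverage estimate that
#' is non-positive after ancestor correction is recorded as a
#' `copy_error` with undetermined copies.
#'
#' @param tds [match_duplications()] result.
#' @param seg Segment `data.frame` for the same sample.
#' @param baseline_ploidy Baseline copy number (default 2).
#' @param clonal_support_reference Expected junction read support of one
#'   clonal copy (default 50).
#' @return `tds` with added `estimated_copies`, `subclonal`, `copy_error`.
#' @export
estimate_copies <- function(tds, seg, baseline_ploidy = 2,
                            clonal_support_reference = 50) {
  tds$estimated_copies <- NA_real_
  tds$subclonal <- NA
  tds$copy_error <- FALSE
  if (nrow(tds) == 0L) return(tds)
  ancestors_of <- function(i) {
    out <- character(0)
    p <- tds$nested_parent[i]
    while (!is.na(p)) {
      out <- c(out, p)
      p <- tds$nested_parent[tds$td_id == p]
    }
    out
  }
  ord <- order(-(tds$end - tds$start))  # outermost first
  for (i in ord) {
    if (tds$gain_matched[i]) {
      children <- tds[!is.na(tds$nested_parent) & tds$nested_parent == tds$td_id[i],
                      c("start", "end"), drop = FALSE]
      excl <- interval_subtract(tds$start[i], tds$end[i], children)
      sub <- seg[seg$chrom == tds$chrom[i] &
                   seg$end > tds$start[i] & seg$start < tds$end[i], , drop = FALSE]
      w <- 0; acc <- 0
      for (p in seq_len(nrow(excl))) {
        ov_len <- pmax(0, pmin(sub$end, excl$end[p]) - pmax(sub$start, excl$start[p]))
        acc <- acc + sum(ov_len * sub$log2ratio)
        w <- w + sum(ov_len)
      }
      if (w == 0) {
        tds$copy_error[i] <- TRUE
        next
      }
      l2 <- acc / w
      anc <- ancestors_of(i)
      anc_copies <- sum(tds$estimated_copies[tds$td_id %in% anc], na.rm = TRUE)
      copies <- baseline_ploidy * 2^l2 - baseline_ploidy - anc_copies
      if (copies <= 0) {
        tds$copy_error[i] <- TRUE
        next
      }
      tds$estimated_copies[i] <- copies
    } else {
      tds$estimated_copies[i] <- tds$support_reads[i] / clonal_support_reference
    }
    ## strict "< 1 copy" rule with a float tolerance: a clonal single-copy
    ## duplication sits exactly on the boundary
    tds$subclonal[i] <- tds$estimated_copies[i] < 1 - 1e-9
  }
  tds
}

#' Call the tandem-duplicator genotype for one sample
#'
#' @param tds [match_duplications()] result for the sample.
#' @param gains [detect_focal_gains()] result for the sample.
#' @param genotype_threshold Minimum duplication count (default 50,
#'   "tens to hundreds").
#' @param sample_id Optional sample label.
#' @return One-row `data.frame`: `sample_id`, `n_tandem_duplications`,
#'   `n_focal_gains`, `is_duplicator`.
#' @export
call_genotype <- function(tds, gains, genotype_threshold = 50,
                          sample_id = NA_character_) {
  data.frame(sample_id = sample_id,
             n_tandem_duplications = nrow(tds),
             n_focal_gains = nrow(gains),
             is_duplicator = nrow(tds) >= genotype_threshold,
             stringsAsFactors = FALSE)
}

#' Screen a cohort of copy-number profiles for the duplicator genotype
#'
#' Categorical detection of tandem duplications is not possible from copy
#' number alone, so samples without junction data are flagged from their
#' focal-gain counts and labeled `"putative"`; samples with junctions are
#' upgraded to `"confirmed"` when the matched-duplication count reaches
#' the threshold.
#'
#' @param seg Multi-sample segment `data.frame`.
#' @param junctions Optional junction `data.frame` (matched per sample).
#' @param min_log2,max_length_bp Focal-gain parameters.
#' @param boundary_tolerance_bp Matching tolerance (default 10 kb).
#' @param genotype_threshold Duplication/gain count threshold (default 50).
#' @return `data.frame` sorted by descending focal-gain count:
#'   `sample_id`, `n_focal_gains`, `n_tandem_duplications` (NA without
#'   junctions), `is_duplicator`, `status` in
#'   `"confirmed"`/`"putative"`/`"none"`.
#' @export
screen_cohort <- function(seg, junctions = NULL, min_log2 = 0.3,
                          max_length_bp = 5e6, boundary_tolerance_bp = 1e4,
                          genotype_threshold = 50) {
  samples <- unique(seg$sample)
  assert_that(length(samples) > 0L, "screen_cohort: empty cohort")
  rows <- lapply(samples, function(s) {
    sub <- seg[seg$sample == s, , drop = FALSE]
    gains <- detect_focal_gains(sub, min_log2, max_length_bp)
    n_td <- NA_integer_
    if (!is.null(junctions)) {
      jn <- junctions[!is.na(junctions$sample) & junctions$sample == s, , drop = FALSE]
      if (nrow(jn) > 0L) {
        n_td <- nrow(match_duplications(gains, jn, boundary_tolerance_bp, max_length_bp))
      }
    }
    dup <- if (!is.na(n_td)) n_td >= genotype_threshold else
      nrow(gains) >= genotype_threshold
    data.frame(sample_id = s, n_focal_gains = nrow(gains),
               n_tandem_duplications = n_td,
               is_duplicator = dup,
               status = if (!dup) "none" else if (!is.na(n_td)) "confirmed" else "putative",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_focal_gains), , drop = FALSE]
  rownames(out) <- NULL
  out
}
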