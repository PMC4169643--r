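## Fusion-transcript filtering, prioritization, DNA corroboration,
## complex-rearrangement (chromoplexy-like) chain reconstruction, gene
## effect classification and reading-frame assessment.

#' Default ETS transcription-factor gene list
#'
#' ETS fusions (e.g. TMPRSS2-ERG) recur across a large fraction of
#' prostate tumors, so the "no more than two libraries" recurrent-artifact
#' filter is waived for candidates touching these genes.
#' @export
ets_default_genes <- c("ERG", "ETV1", "ETV4", "ETV5", "FLI1")

#' Apply the primary fusion filtering cascade
#'
#' A candidate is retained only if it passes all five criteria:
#' (1) arises from genome rearrangement rather than a readthrough event;
#' (2) is predicted in no more than `max_libraries` distinct sequence
#' libraries sharing its (5', 3') gene pair — waived for ETS candidates,
#' which recur biologically; (3) maps unambiguously on both sides (no
#' multi-mapping); (4) does not map entirely to repetitive elements
#' (`repeat_fraction == 1`); (5) is detected in more than `min_reads`
#' reads, split plus spanning.
#'
#' @param candidates Candidate `data.frame` (see
#'   [read_fusion_candidates()]).
#' @param ets_genes Genes whose fusions are exempt from criterion 2.
#' @param max_libraries Library-recurrence cap for criterion 2 (default 2).
#' @param min_reads Read-support threshold for criterion 5; support must
#'   be strictly greater (default 5).
#' @return `data.frame` with one row per candidate: `candidate_id`,
#'   `crit1_rearrangement` .. `crit5_support`, `ets_exemption_applied`,
#'   `retained`.
#' @export
apply_primary_filters <- function(candidates, ets_genes = ets_default_genes,
                                  max_libraries = 2L, min_reads = 5L) {
  assert_that(!anyNA(candidates$library_id),
              "apply_primary_filters: every candidate needs a library_id")
  pair <- paste(candidates$gene5, candidates$gene3, sep = "~")
  n_libs <- vapply(pair, function(p) {
    length(unique(candidates$library_id[pair == p]))
  }, integer(1))
  is_ets <- candidates$gene5 %in% ets_genes | candidates$gene3 %in% ets_genes

  crit1 <- !candidates$is_readthrough
  crit2_raw <- n_libs <= max_libraries
  crit2 <- crit2_raw | is_ets
  crit3 <- !candidates$multimapping
  crit4 <- candidates$repeat_fraction < 1
  crit5 <- (candidates$split_reads + candidates$spanning_reads) > min_reads

  data.frame(candidate_id = candidates$id,
             crit1_rearrangement = crit1,
             crit2_recurrence = crit2,
             crit3_unambiguous = crit3,
             crit4_repeats = crit4,
             crit5_support = crit5,
             ets_exemption_applied = is_ets & !crit2_raw,
             retained = crit1 & crit2 & crit3 & crit4 & crit5,
             stringsAsFactors = FALSE)
}

## does junction j (1-row data.frame) match a candidate's two oriented
## breakpoints within tol bp, in either end order?
junction_matches_candidate <- function(junction, cand, tol) {
  direct <- junction$chromA == cand$chrom5 && abs(junction$posA - cand$pos5) <= tol &&
    junction$orientA == cand$orient5 &&
    junction$chromB == cand$chrom3 && abs(junction$posB - cand$pos3) <= tol &&
    junction$orientB == cand$orient3
  swapped <- junction$chromB == cand$chrom5 && abs(junction$posB - cand$pos5) <= tol &&
    junction$orientB == cand$orient5 &&
    junction$chromA == cand$chrom3 && abs(junction$posA - cand$pos3) <= tol &&
    junction$orientA == cand$orient3
  direct || swapped
}

#' Secondary prioritization of retained candidates
#'
#' Flags any of: (a) a genomic breakpoint mapping to the edge of a
#' copy-number aberration (within `edge_tolerance_bp` of a boundary
#' between segments whose log2 ratios differ by at least
#' `min_log2_delta`); (b) differential exon expression either side of the
#' breakpoint within a partner gene (mean exon depth ratio >= `min_fold`);
#' (c) outlier expression of the 3' gene in that sample. A candidate is
#' `prioritized` when any flag is true. When a gene has no exon-depth
#' rows on both sides of its breakpoint, the exon flag is recorded as NA
#' (undetermined), not fatal.
#'
#' @param candidates Retained candidate `data.frame`.
#' @param seg Copy-number segments (see [read_seg()]); candidate
#'   `library_id` is matched against the `sample` column.
#' @param exon_depth Optional per-exon depth `data.frame` with columns
#'   `gene_id`, `sample_id`, `start`, `end`, `depth`.
#' @param outlier_calls Optional [call_outliers()] result.
#' @param edge_tolerance_bp CNA-edge distance tolerance (default 100 kb).
#' @param min_log2_delta Minimum log2-ratio step at a boundary (default 0.3).
#' @param min_fold Minimum exon depth fold change (default 2).
#' @return `data.frame`: `candidate_id`, `cna_edge`,
#'   `differential_exon_expression`, `outlier_3prime`, `prioritized`.
#' @export
flag_secondary_evidence <- function(candidates, seg = NULL, exon_depth = NULL,
                                    outlier_calls = NULL,
                                    edge_tolerance_bp = 1e5,
                                    min_log2_delta = 0.3, min_fold = 2) {
  cna_boundaries <- function(sample) {
    if (is.null(seg)) return(data.frame(chrom = character(0), pos = numeric(0)))
    sub <- seg[seg$sample == sample, , drop = FALSE]
    out <- list()
    for (chrom in unique(sub$chrom)) {
      s <- sub[sub$chrom == chrom, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) < 2L) next
      step <- abs(diff(s$log2ratio))
      keep <- which(step >= min_log2_delta)
      if (length(keep) > 0L) {
        pos <- unique(c(s$end[keep], s$start[keep + 1L]))
        out[[chrom]] <- data.frame(chrom = chrom, pos = pos)
      }
    }
    if (length(out) == 0L) return(data.frame(chrom = character(0), pos = numeric(0)))
    do.call(rbind, out)
  }

  exon_sides_fold <- function(gene, sample, chrom, pos) {
    if (is.null(exon_depth)) return(NA)
    ex <- exon_depth[exon_depth$gene_id == gene & exon_depth$sample_id == sample, , drop = FALSE]
    left <- ex$depth[ex$end <= pos]
    right <- ex$depth[ex$start >= pos]
    if (length(left) == 0L || length(right) == 0L) return(NA)
    a <- mean(left); b <- mean(right)
    if (a == 0 && b == 0) return(FALSE)
    if (min(a, b) == 0) return(TRUE)
    max(a, b) / min(a, b) >= min_fold
  }

  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, , drop = FALSE]
    bounds <- cna_boundaries(cand$library_id)
    cna <- if (is.null(seg)) NA else {
      any(bounds$chrom == cand$chrom5 & abs(bounds$pos - cand$pos5) <= edge_tolerance_bp) ||
        any(bounds$chrom == cand$chrom3 & abs(bounds$pos - cand$pos3) <= edge_tolerance_bp)
    }
    f5 <- exon_sides_fold(cand$gene5, cand$library_id, cand$chrom5, cand$pos5)
    f3 <- exon_sides_fold(cand$gene3, cand$library_id, cand$chrom3, cand$pos3)
    dee <- if (is.na(f5) && is.na(f3)) NA else isTRUE(f5) || isTRUE(f3)
    out3 <- if (is.null(outlier_calls)) NA else {
      any(outlier_calls$gene_id == cand$gene3 &
            outlier_calls$sample_id == cand$library_id &
            outlier_calls$direction == "up")
    }
    data.frame(candidate_id = cand$id, cna_edge = cna,
               differential_exon_expression = dee, outlier_3prime = out3,
               prioritized = isTRUE(cna) || isTRUE(dee) || isTRUE(out3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Corroborate expressed fusions with DNA breakpoints
#'
#' A candidate is evaluable when its sample's mean DNA coverage exceeds
#' `min_coverage`; it is matched when some junction from the same sample
#' has both oriented ends within `match_tolerance_bp` of the candidate's
#' genomic breakpoints.
#'
#' @param candidates Candidate `data.frame`.
#' @param junctions Junction `data.frame` (see [read_bedpe()]).
#' @param coverage Named per-sample mean DNA depth (x units).
#' @param match_tolerance_bp Breakpoint distance tolerance (default 10).
#' @param min_coverage Evaluability threshold, strictly greater
#'   (default 5).
#' @return `data.frame`: `candidate_id`, `evaluable`,
#'   `matched_breakpoint_id` (NA when unmatched).
#' @export
corroborate_dna <- function(candidates, junctions, coverage,
                            match_tolerance_bp = 10, min_coverage = 5) {
  missing <- setdiff(unique(candidates$library_id), names(coverage))
  assert_that(length(missing) == 0L,
              "corroborate_dna: no DNA coverage for sample(s): %s",
              paste(missing, collapse = ", "))
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, , drop = FALSE]
    evaluable <- coverage[[cand$library_id]] > min_coverage
    match_id <- NA_character_
    if (evaluable && nrow(junctions) > 0L) {
      sub <- junctions[is.na(junctions$sample) | junctions$sample == cand$library_id, , drop = FALSE]
      for (j in seq_len(nrow(sub))) {
        if (junction_matches_candidate(sub[j, , drop = FALSE], cand, match_tolerance_bp)) {
          match_id <- sub$id[j]
          break
        }
      }
    }
    data.frame(candidate_id = cand$id, evaluable = evaluable,
               matched_breakpoint_id = match_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reconstruct complex rearrangement (chromoplexy-like) events
#'
#' Builds, per sample, a graph whose nodes are junction ends; edges join
#' (a) the two ends of each junction and (b) ends of different junctions
#' lying within `link_window_bp` of each other on the same chromosome.
#' Connected components containing more than two junctions are emitted as
#' complex events — a chain of interdependent breakpoints linking multiple
#' loci. Simple reciprocal pairs (two junctions) are never complex.
#'
#' @param junctions Junction `data.frame` (see [read_bedpe()]).
#' @param link_window_bp Reference-proximity linking window (default 1 Mb).
#' @param gene_model Optional gene-model `data.frame`; member genes are
#'   those whose span contains a member junction end.
#' @param candidates Optional candidate `data.frame`; expressed fusions
#'   are attached when both breakpoints match a member junction within
#'   `match_tolerance_bp`.
#' @param match_tolerance_bp Tolerance for fusion attachment (default 10).
#' @return `data.frame` with one row per event: `event_id`, `sample_id`,
#'   `n_breakpoints`, and list-columns `junction_ids`, `genes`,
#'   `fusion_ids`.
#' @export
build_complex_events <- function(junctions, link_window_bp = 1e6,
                                 gene_model = NULL, candidates = NULL,
                                 match_tolerance_bp = 10) {
  smry <- if (!is.null(gene_model)) gene_model_summary(gene_model) else NULL
  events <- list()
  for (sample in unique(junctions$sample)) {
    sub <- junctions[if (is.na(sample)) is.na(junctions$sample) else
      !is.na(junctions$sample) & junctions$sample == sample, , drop = FALSE]
    if (nrow(sub) == 0L) next
    ends <- rbind(
      data.frame(jid = sub$id, chrom = sub$chromA, pos = sub$posA,
                 node = paste0(sub$id, "/A"), stringsAsFactors = FALSE),
      data.frame(jid = sub$id, chrom = sub$chromB, pos = sub$posB,
                 node = paste0(sub$id, "/B"), stringsAsFactors = FALSE))
    edges <- cbind(paste0(sub$id, "/A"), paste0(sub$id, "/B"))
    for (chrom in unique(ends$chrom)) {
      e <- ends[ends$chrom == chrom, , drop = FALSE]
      if (nrow(e) < 2L) next
      combs <- utils::combn(nrow(e), 2L)
      near <- abs(e$pos[combs[1L, ]] - e$pos[combs[2L, ]]) <= link_window_bp &
        e$jid[combs[1L, ]] != e$jid[combs[2L, ]]
      if (any(near)) {
        edges <- rbind(edges, cbind(e$node[combs[1L, near]], e$node[combs[2L, near]]))
      }
    }
    g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE,
                                       vertices = ends$node)
    comp <- igraph::components(g)$membership
    for (cid in unique(comp)) {
      nodes <- names(comp)[comp == cid]
      jids <- unique(ends$jid[ends$node %in% nodes])
      if (length(jids) <= 2L) next
      member <- sub[sub$id %in% jids, , drop = FALSE]
      member_ends <- ends[ends$jid %in% jids, , drop = FALSE]
      genes <- character(0)
      if (!is.null(smry)) {
        hit <- vapply(seq_len(nrow(smry)), function(k) {
          any(member_ends$chrom == smry$chrom[k] &
                member_ends$pos >= smry$span_start[k] &
                member_ends$pos < smry$span_end[k])
        }, logical(1))
        genes <- smry$gene_id[hit]
      }
      fusion_ids <- character(0)
      if (!is.null(candidates) && nrow(candidates) > 0L) {
        cs <- candidates[candidates$library_id == sample | is.na(sample), , drop = FALSE]
        hit <- vapply(seq_len(nrow(cs)), function(ci) {
          any(vapply(seq_len(nrow(member)), function(ji) {
            junction_matches_candidate(member[ji, , drop = FALSE],
                                       cs[ci, , drop = FALSE], match_tolerance_bp)
          }, logical(1)))
        }, logical(1))
        fusion_ids <- cs$id[hit]
      }
      events[[length(events) + 1L]] <- data.frame(
        event_id = NA_character_, sample_id = sample,
        n_breakpoints = length(jids),
        junction_ids = I(list(sort(jids))),
        genes = I(list(sort(genes))),
        fusion_ids = I(list(sort(fusion_ids))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0L) {
    return(data.frame(event_id = character(0), sample_id = character(0),
                      n_breakpoints = integer(0),
                      junction_ids = I(list()), genes = I(list()),
                      fusion_ids = I(list()), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, events)
  out$event_id <- sprintf("CE%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Classify the effect of a complex event on each member gene
#'
#' A gene is `activating` when it is the 3' partner of an in-frame
#' expressed fusion of the event, or carries an up-regulated outlier call
#' in the event's sample; `disrupted` when a member breakpoint interrupts
#' its CDS without activating evidence; `neutral` otherwise (breakpoints
#' confined to UTR/flanking sequence).
#'
#' @param events Event `data.frame` from [build_complex_events()].
#' @param junctions Junction `data.frame` the events were built from.
#' @param gene_model Gene-model `data.frame`.
#' @param candidates Optional candidate `data.frame` (for fusion lookup).
#' @param frames Optional [assess_frame()] result.
#' @param outlier_calls Optional [call_outliers()] result.
#' @return `data.frame`: `event_id`, `gene_id`, `effect`.
#' @export
classify_gene_effects <- function(events, junctions, gene_model,
                                  candidates = NULL, frames = NULL,
                                  outlier_calls = NULL) {
  smry <- gene_model_summary(gene_model)
  rows <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, , drop = FALSE]
    jids <- ev$junction_ids[[1L]]
    member <- junctions[junctions$id %in% jids, , drop = FALSE]
    end_pos <- rbind(data.frame(chrom = member$chromA, pos = member$posA),
                     data.frame(chrom = member$chromB, pos = member$posB))
    for (g in ev$genes[[1L]]) {
      srow <- smry[smry$gene_id == g, , drop = FALSE]
      assert_that(nrow(srow) == 1L, "classify_gene_effects: no model for gene '%s'", g)
      activating <- FALSE
      if (!is.null(candidates) && !is.null(frames) && length(ev$fusion_ids[[1L]]) > 0L) {
        fus <- candidates[candidates$id %in% ev$fusion_ids[[1L]], , drop = FALSE]
        in_frame_ids <- frames$candidate_id[frames$status == "in_frame"]
        activating <- any(fus$gene3 == g & fus$id %in% in_frame_ids)
      }
      if (!activating && !is.null(outlier_calls)) {
        activating <- any(outlier_calls$gene_id == g &
                            outlier_calls$sample_id == ev$sample_id &
                            outlier_calls$direction == "up")
      }
      in_cds <- !is.na(srow$cds_start) &&
        any(end_pos$chrom == srow$chrom &
              end_pos$pos >= srow$cds_start & end_pos$pos < srow$cds_end)
      effect <- if (activating) "activating" else if (in_cds) "disrupted" else "neutral"
      rows[[length(rows) + 1L]] <- data.frame(event_id = ev$event_id, gene_id = g,
                                              effect = effect, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(event_id = character(0), gene_id = character(0),
                      effect = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

## coding nucleotides of a gene upstream (in transcription order) of a
## genomic junction position
coding_len_before <- function(cds, pos, strand) {
  if (strand == "+") {
    sum(pmax(0, pmin(cds$end, pos) - cds$start))
  } else {
    sum(pmax(0, cds$end - pmax(cds$start, pos)))
  }
}

#' Assess the reading frame across fusion junctions
#'
#' A fusion is `in_frame` when both breakpoints fall within their genes'
#' CDS spans and the coding length retained from the 5' gene's CDS start
#' to its breakpoint is congruent modulo 3 with the CDS phase of the 3'
#' gene's junction position. `undetermined` is returned only when either
#' partner lacks CDS annotation. A breakpoint outside a partner's gene
#' span is an error naming the candidate.
#'
#' @param candidates Candidate `data.frame`.
#' @param gene_model Gene-model `data.frame` with CDS rows where known.
#' @return `data.frame`: `candidate_id`, `status` in
#'   `in_frame`/`out_of_frame`/`undetermined`.
#' @export
assess_frame <- function(candidates, gene_model) {
  smry <- gene_model_summary(gene_model)
  status <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, , drop = FALSE]
    s5 <- smry[smry$gene_id == cand$gene5, , drop = FALSE]
    s3 <- smry[smry$gene_id == cand$gene3, , drop = FALSE]
    assert_that(nrow(s5) == 1L && nrow(s3) == 1L,
                "assess_frame: candidate '%s': partner gene missing from gene model", cand$id)
    if (cand$pos5 < s5$span_start || cand$pos5 > s5$span_end ||
        cand$pos3 < s3$span_start || cand$pos3 > s3$span_end) {
      stop_format("assess_frame: candidate '%s': breakpoint outside gene span", cand$id)
    }
    if (is.na(s5$cds_start) || is.na(s3$cds_start)) {
      status[i] <- "undetermined"
      next
    }
    in5 <- cand$pos5 >= s5$cds_start && cand$pos5 <= s5$cds_end
    in3 <- cand$pos3 >= s3$cds_start && cand$pos3 <= s3$cds_end
    if (!in5 || !in3) {
      status[i] <- "out_of_frame"
      next
    }
    cds5 <- gene_model[gene_model$gene_id == cand$gene5 & gene_model$feature == "CDS", , drop = FALSE]
    cds3 <- gene_model[gene_model$gene_id == cand$gene3 & gene_model$feature == "CDS", , drop = FALSE]
    len5 <- coding_len_before(cds5, cand$pos5, s5$strand)
    phase3 <- coding_len_before(cds3, cand$pos3, s3$strand) %% 3
    status[i] <- if (len5 %% 3 == phase3) "in_frame" else "out_of_frame"
  }
  data.frame(candidate_id = candidates$id, status = status,
             stringsAsFactors = FALSE)
}

#' Per-sample fusion burden summary
#'
#' @param candidates Candidate `data.frame`.
#' @param verdicts [apply_primary_filters()] result.
#' @param events Optional [build_complex_events()] result.
#' @param ets_genes ETS gene list for the ETS-status column.
#' @return `data.frame` with one row per library: `sample_id`,
#'   `fusion_load` (retained candidates), `complex_count`, `ets_status`.
#' @export
summarize_fusion_load <- function(candidates, verdicts, events = NULL,
                                  ets_genes = ets_default_genes) {
  retained_ids <- verdicts$candidate_id[verdicts$retained]
  samples <- sort(unique(c(candidates$library_id,
                           if (!is.null(events)) events$sample_id)))
  rows <- lapply(samples, function(s) {
    sub <- candidates[candidates$library_id == s, , drop = FALSE]
    kept <- sub[sub$id %in% retained_ids, , drop = FALSE]
    data.frame(sample_id = s,
               fusion_load = nrow(kept),
               complex_count = if (is.null(events)) 0L else
                 sum(events$sample_id == s),
               ets_status = any(kept$gene5 %in% ets_genes | kept$gene3 %in% ets_genes),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
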