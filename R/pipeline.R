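## End-to-end orchestration: outlier calling -> enrichment -> fusion
## cascade -> tandem-duplication genotyping from a single input/parameter
## bundle, with a consolidated per-sample report. Stages whose inputs are
## absent are skipped and marked as such; one seed governs the run.

#' Pipeline parameters with defaults
#'
#' Every tunable of the four analysis stages, echoed verbatim into the
#' run report.
#'
#' @param alpha ESD significance level.
#' @param r_max ESD outlier bound (capped at half the cohort size).
#' @param min_depth Depth rule threshold (x units).
#' @param recurrence_fraction Maximum flagged cohort fraction per gene.
#' @param read_length Read length for depth conversion (bp).
#' @param enrich_directions Outlier directions entering enrichment.
#' @param ets_genes ETS gene list.
#' @param max_libraries,min_reads Primary-filter thresholds.
#' @param edge_tolerance_bp,min_log2_delta,min_fold Secondary-evidence
#'   thresholds.
#' @param match_tolerance_bp DNA breakpoint matching tolerance.
#' @param min_dna_coverage DNA evaluability threshold (x units).
#' @param link_window_bp Chain-linking window.
#' @param gain_min_log2,gain_max_length_bp Focal-gain thresholds.
#' @param boundary_tolerance_bp Duplication matching tolerance.
#' @param genotype_threshold Duplicator-genotype count threshold.
#' @param clonal_support_reference Clonal junction support per copy.
#' @param baseline_ploidy Copy-number baseline.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(alpha = 0.05, r_max = 15L, min_depth = 10,
                            recurrence_fraction = 1 / 3, read_length = 100,
                            enrich_directions = c("up", "down"),
                            ets_genes = ets_default_genes,
                            max_libraries = 2L, min_reads = 5L,
                            edge_tolerance_bp = 1e5, min_log2_delta = 0.3,
                            min_fold = 2, match_tolerance_bp = 10,
                            min_dna_coverage = 5, link_window_bp = 1e6,
                            gain_min_log2 = 0.3, gain_max_length_bp = 5e6,
                            boundary_tolerance_bp = 1e4,
                            genotype_threshold = 50L,
                            clonal_support_reference = 50,
                            baseline_ploidy = 2) {
  as.list(environment())
}

resolve_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) {
    assert_that(file.exists(x), "run_pipeline: input file '%s' does not exist", x)
    return(reader(x))
  }
  x
}

read_noise_tsv <- function(path) {
  df <- read_tsv(path)
  check_columns(df, c("sample", "depth"), sprintf("noise table '%s'", path))
  stats::setNames(as.numeric(df$depth), df$sample)
}

#' Run the full pipeline
#'
#' Inputs may be in-memory objects or file paths (TSV/GTF/GMT/SEG/BEDPE,
#' read with the package's format readers). Stages run when their inputs
#' are present: outlier calling needs `counts` + `models`; enrichment
#' additionally needs `gene_sets`; the fusion cascade needs `candidates`
#' (with `junctions`, `seg`, `coverage` enabling corroboration, secondary
#' evidence and complex events); tandem-duplication genotyping needs
#' `seg` + `junctions`. The run is deterministic given its inputs and
#' seed.
#'
#' @param inputs Named list: `counts`, `models`, `noise`, `gene_sets`,
#'   `candidates`, `junctions`, `seg`, `coverage`.
#' @param params [pipeline_params()].
#' @param seed Integer seed recorded in, and governing, the run.
#' @return A `cohort_report` list: `metadata` (version, seed, parameters),
#'   `stages` (complete/skipped per stage), `samples` (one row per
#'   sample), and `tables` (full per-stage result tables).
#' @export
run_pipeline <- function(inputs, params = pipeline_params(), seed = 1L) {
  set.seed(seed)
  counts <- resolve_input(inputs$counts, read_count_matrix)
  models <- resolve_input(inputs$models, read_gene_models)
  noise <- resolve_input(inputs$noise, read_noise_tsv)
  gene_sets <- resolve_input(inputs$gene_sets, read_gmt)
  candidates <- resolve_input(inputs$candidates, read_fusion_candidates)
  junctions <- resolve_input(inputs$junctions, read_bedpe)
  seg <- resolve_input(inputs$seg, read_seg)
  coverage <- resolve_input(inputs$coverage, read_noise_tsv)

  stages <- list(outliers = "skipped", enrichment = "skipped",
                 fusions = "skipped", tandem_duplication = "skipped")
  tables <- list()
  outlier_calls <- NULL

  if (!is.null(counts) && !is.null(models)) {
    sf <- compute_size_factors(counts)
    depth <- counts_to_depth(counts, sf, models, params$read_length)
    outlier_calls <- call_outliers(
      depth, noise %||% 0,
      esd_params(params$r_max, params$alpha),
      min_depth = params$min_depth,
      recurrence_fraction = params$recurrence_fraction)
    tables$size_factors <- data.frame(sample = names(sf), size_factor = unname(sf))
    tables$outlier_calls <- outlier_calls
    stages$outliers <- "complete"
  }

  if (!is.null(outlier_calls) && !is.null(gene_sets)) {
    tables$enrichment <- enrich_cohort(outlier_calls, gene_sets,
                                       universe = rownames(counts),
                                       directions = params$enrich_directions)
    stages$enrichment <- "complete"
  }

  events <- NULL
  if (!is.null(candidates)) {
    verdicts <- apply_primary_filters(candidates, params$ets_genes,
                                      params$max_libraries, params$min_reads)
    tables$filter_verdicts <- verdicts
    retained <- candidates[candidates$id %in%
                             verdicts$candidate_id[verdicts$retained], , drop = FALSE]
    if (!is.null(seg) || !is.null(outlier_calls)) {
      tables$priority_flags <- flag_secondary_evidence(
        retained, seg = seg, outlier_calls = outlier_calls,
        edge_tolerance_bp = params$edge_tolerance_bp,
        min_log2_delta = params$min_log2_delta, min_fold = params$min_fold)
    }
    if (!is.null(junctions) && !is.null(coverage)) {
      tables$dna_corroboration <- corroborate_dna(
        retained, junctions, coverage,
        match_tolerance_bp = params$match_tolerance_bp,
        min_coverage = params$min_dna_coverage)
    }
    if (!is.null(junctions)) {
      events <- build_complex_events(junctions, params$link_window_bp,
                                     gene_model = models,
                                     candidates = retained,
                                     match_tolerance_bp = params$match_tolerance_bp)
      tables$complex_events <- events
    }
    if (!is.null(models)) {
      smry <- gene_model_summary(models)
      known <- candidates$gene5 %in% smry$gene_id & candidates$gene3 %in% smry$gene_id
      if (any(known)) {
        tables$frames <- assess_frame(candidates[known, , drop = FALSE], models)
      }
    }
    tables$fusion_load <- summarize_fusion_load(candidates, verdicts, events,
                                                params$ets_genes)
    stages$fusions <- "complete"
  }

  genotypes <- NULL
  if (!is.null(seg) && !is.null(junctions)) {
    td_rows <- list()
    geno_rows <- list()
    for (s in unique(seg$sample)) {
      gains <- detect_focal_gains(seg[seg$sample == s, , drop = FALSE],
                                  params$gain_min_log2, params$gain_max_length_bp)
      jn <- junctions[!is.na(junctions$sample) & junctions$sample == s, , drop = FALSE]
      tds <- match_duplications(gains, jn, params$boundary_tolerance_bp,
                                params$gain_max_length_bp)
      tds <- estimate_copies(tds, seg[seg$sample == s, , drop = FALSE],
                             params$baseline_ploidy,
                             params$clonal_support_reference)
      td_rows[[s]] <- tds
      geno_rows[[s]] <- call_genotype(tds, gains, params$genotype_threshold,
                                      sample_id = s)
    }
    tables$tandem_duplications <- do.call(rbind, td_rows)
    genotypes <- do.call(rbind, geno_rows)
    rownames(genotypes) <- NULL
    tables$duplicator_genotypes <- genotypes
    stages$tandem_duplication <- "complete"
  }

  ## consolidated per-sample view
  all_samples <- sort(unique(c(
    if (!is.null(counts)) colnames(counts),
    if (!is.null(candidates)) candidates$library_id,
    if (!is.null(seg)) seg$sample)))
  samples <- do.call(rbind, lapply(all_samples, function(s) {
    oc <- if (!is.null(outlier_calls)) sum(outlier_calls$sample_id == s) else NA_integer_
    top_set <- NA_character_; top_score <- NA_real_
    if (!is.null(tables$enrichment)) {
      en <- tables$enrichment[tables$enrichment$sample_id == s, , drop = FALSE]
      if (nrow(en) > 0L) {
        best <- which.max(en$pathway_score)
        top_set <- en$set_name[best]
        top_score <- en$pathway_score[best]
      }
    }
    fl <- cx <- NA_integer_; ets <- NA
    if (!is.null(tables$fusion_load)) {
      row <- tables$fusion_load[tables$fusion_load$sample_id == s, , drop = FALSE]
      if (nrow(row) == 1L) {
        fl <- row$fusion_load; cx <- row$complex_count; ets <- row$ets_status
      } else {
        fl <- 0L; cx <- 0L; ets <- FALSE
      }
    }
    ntd <- NA_integer_; dup <- NA
    if (!is.null(genotypes)) {
      row <- genotypes[genotypes$sample_id == s, , drop = FALSE]
      if (nrow(row) == 1L) {
        ntd <- row$n_tandem_duplications; dup <- row$is_duplicator
      }
    }
    data.frame(sample_id = s, outlier_count = oc, top_set = top_set,
               top_pathway_score = top_score, fusion_load = fl,
               complex_count = cx, ets_status = ets,
               n_tandem_duplications = ntd, is_duplicator = dup,
               stringsAsFactors = FALSE)
  }))

  report <- list(
    metadata = list(
      package = "htxtools",
      version = as.character(utils::packageVersion("htxtools")),
      seed = seed,
      parameters = params),
    stages = stages,
    samples = samples,
    tables = tables)
  class(report) <- "cohort_report"
  report
}

#' Median per-sample outlier count of a run
#'
#' Uses the lower-median convention: for an even number of samples the
#' lower of the two central values is reported.
#'
#' @param report A [run_pipeline()] report.
#' @return Integer median outlier count.
#' @export
median_outliers_per_sample <- function(report) {
  assert_that(identical(report$stages$outliers, "complete"),
              "median_outliers_per_sample: outlier stage did not run")
  counts <- report$samples$outlier_count
  counts <- counts[!is.na(counts)]
  assert_that(length(counts) > 0L, "median_outliers_per_sample: no samples")
  lower_median(counts)
}

#' Write a run report as JSON (plus TSV tables)
#'
#' The JSON serialization is deterministic: identical reports produce
#' byte-identical files.
#'
#' @param report A [run_pipeline()] report.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  for (nm in names(report$tables)) {
    tab <- report$tables[[nm]]
    if (is.data.frame(tab)) {
      flat <- tab
      for (col in names(flat)) {
        if (is.list(flat[[col]])) {
          flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = ",")
        }
      }
      write_tsv(flat, file.path(dir, paste0(nm, ".tsv")))
    }
  }
  write_tsv(report$samples, file.path(dir, "samples.tsv"))
  invisible(dir)
}
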