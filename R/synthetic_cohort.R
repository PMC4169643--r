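## Synthetic-cohort generator. Every downstream stage of the pipeline is
## exercised against cohorts with planted ground truth: negative-binomial
## counts with multiplicatively planted outlier genes, per-sample
## intergenic/intronic background depths, labeled fusion-candidate tables
## in which each artifact class violates exactly one filter criterion,
## chromoplexy-like breakpoint chains, and copy-number profiles carrying
## nested/serial tandem duplications including sub-clonal ones.
##
## Determinism: every simulate_* call seeds the RNG from `config$seed`
## (plus a fixed per-stage offset), so an identical config yields
## byte-identical output.

## toy genome: 22 autosome lengths (bp), human-like
toy_chrom_lengths <- function() {
  stats::setNames(
    c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
      115, 107, 103, 90, 81, 78, 59, 63, 48, 51) * 1e6,
    paste0("chr", 1:22))
}

#' Configuration of the synthetic cohort
#'
#' Defaults emulate, at desk scale, a 31-library high-risk tumor cohort:
#' negative-binomial counts with dispersion 0.2 spanning lowly to highly
#' expressed genes (log10 mean in \[0.5, 3.5\]), a background
#' intergenic/intronic depth of 0.5x per library, 16-fold single-carrier
#' outlier genes planted in expressed genes, fusion-candidate classes
#' engineered to violate exactly one primary filter each, 6-breakpoint
#' chromoplexy-like chains, and a tandem-duplicator genome carrying 241
#' duplications including one nested 3-duplication locus and sub-clonal
#' events at fraction 0.4.
#'
#' @param n_samples Number of sequence libraries (default 31).
#' @param n_genes Number of genes in the count matrix (default 2000).
#' @param nb_mean_log_range log10 range of per-gene NB means.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion*mu^2).
#' @param outlier_spec List: `n_outlier_genes`, `fold_change`,
#'   `n_carrier_samples`, `min_mean_log10` (outliers are planted in genes
#'   at or above this baseline expression so the depth rules are
#'   satisfiable).
#' @param noise_spec List: `mean_depth` (x units), `stochastic`, `cv`.
#' @param fusion_spec List of per-class candidate counts: `n_true`,
#'   `n_ets_true` is the number of libraries carrying a recurrent true
#'   ETS fusion, `n_readthrough`, `n_recurrent_artifact` (multiple of 3;
#'   planted as gene pairs recurring in 3 libraries), `n_multimap`,
#'   `n_repeat`, `n_low_support`.
#' @param chain_spec List: `n_chains`, `breakpoints_per_chain`.
#' @param td_spec List: `n_duplications`, `n_subclonal`,
#'   `subclonal_copies`, `nested_n` (duplications in the nested locus),
#'   `clonal_support_reference`, `copy_probs` (named probabilities of 1,
#'   2, 3 extra copies), `min_len`, `max_len`, `sample_id`.
#' @param seed Integer seed governing all stages.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_samples = 31L, n_genes = 2000L,
                       nb_mean_log_range = c(0.5, 3.5), nb_dispersion = 0.2,
                       outlier_spec = list(), noise_spec = list(),
                       fusion_spec = list(), chain_spec = list(),
                       td_spec = list(), seed = 1L) {
  outlier_spec <- utils::modifyList(
    list(n_outlier_genes = 400L, fold_change = 16, n_carrier_samples = 1L,
         min_mean_log10 = 2.5), outlier_spec)
  noise_spec <- utils::modifyList(
    list(mean_depth = 0.5, stochastic = FALSE, cv = 0.3), noise_spec)
  fusion_spec <- utils::modifyList(
    list(n_true = 20L, n_ets_true = 15L, n_readthrough = 10L,
         n_recurrent_artifact = 6L, n_multimap = 8L, n_repeat = 8L,
         n_low_support = 10L), fusion_spec)
  chain_spec <- utils::modifyList(
    list(n_chains = 2L, breakpoints_per_chain = 6L), chain_spec)
  td_spec <- utils::modifyList(
    list(n_duplications = 241L, n_subclonal = 12L, subclonal_copies = 0.4,
         nested_n = 3L, clonal_support_reference = 50,
         copy_probs = c(`1` = 0.7, `2` = 0.2, `3` = 0.1),
         min_len = 2e4, max_len = 2e6, sample_id = "T4"), td_spec)
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              nb_mean_log_range = nb_mean_log_range,
              nb_dispersion = nb_dispersion,
              outlier_spec = outlier_spec, noise_spec = noise_spec,
              fusion_spec = fusion_spec, chain_spec = chain_spec,
              td_spec = td_spec, seed = as.integer(seed))
  assert_that(cfg$n_samples >= 3L && cfg$n_genes >= 1L,
              "sim_config: need >= 3 samples and >= 1 gene")
  assert_that(outlier_spec$fold_change > 1, "sim_config: fold_change must be > 1")
  assert_that(outlier_spec$n_carrier_samples < cfg$n_samples,
              "sim_config: n_carrier_samples must be < n_samples")
  assert_that(noise_spec$mean_depth >= 0, "sim_config: noise mean_depth must be >= 0")
  counts <- unlist(fusion_spec[startsWith(names(fusion_spec), "n_")])
  assert_that(all(counts >= 0), "sim_config: fusion class counts must be >= 0")
  assert_that(fusion_spec$n_recurrent_artifact %% 3L == 0L,
              "sim_config: n_recurrent_artifact must be a multiple of 3")
  assert_that(td_spec$subclonal_copies > 0,
              "sim_config: duplication copies must be positive")
  structure(cfg, class = "sim_config")
}

sample_ids <- function(cfg) sprintf("S%02d", seq_len(cfg$n_samples))

#' Simulate a count matrix with planted outlier genes
#'
#' Background counts are NB(mean_g * s_j, dispersion) with library-size
#' factors s_j drawn log-uniformly from \[0.5, 2\]. Outlier genes are
#' planted by multiplying the NB mean by `fold_change` in the carrier
#' samples; truth records every planted (gene, sample) pair. A toy
#' single-exon gene model (with CDS) is emitted alongside so depth
#' conversion is possible.
#'
#' @param config [sim_config()].
#' @return List: `counts` (integer matrix), `truth` (`data.frame` of
#'   `gene_id`, `sample_id`, `direction`), `models` (gene-model
#'   `data.frame`), `true_size_factors`, `gene_means`.
#' @export
simulate_counts <- function(config) {
  set.seed(config$seed + 101L)
  n <- config$n_samples
  m <- config$n_genes
  genes <- sprintf("G%04d", seq_len(m))
  samples <- sample_ids(config)
  sf <- exp(stats::runif(n, log(0.5), log(2)))
  mu <- 10^stats::runif(m, config$nb_mean_log_range[1L], config$nb_mean_log_range[2L])
  size <- 1 / config$nb_dispersion
  counts <- matrix(stats::rnbinom(m * n, mu = outer(mu, sf), size = size),
                   nrow = m, dimnames = list(genes, samples))

  spec <- config$outlier_spec
  truth <- data.frame(gene_id = character(0), sample_id = character(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (spec$n_outlier_genes > 0L) {
    eligible <- which(log10(mu) >= spec$min_mean_log10)
    assert_that(length(eligible) >= spec$n_outlier_genes,
                "simulate_counts: only %d genes above min_mean_log10 but %d outlier genes requested",
                length(eligible), spec$n_outlier_genes)
    out_genes <- sort(sample(eligible, spec$n_outlier_genes))
    rows <- lapply(out_genes, function(g) {
      carriers <- sample.int(n, spec$n_carrier_samples)
      counts[g, carriers] <<- stats::rnbinom(
        length(carriers), mu = mu[g] * sf[carriers] * spec$fold_change, size = size)
      data.frame(gene_id = genes[g], sample_id = samples[carriers],
                 direction = "up", stringsAsFactors = FALSE)
    })
    truth <- do.call(rbind, rows)
  }

  ## toy single-exon gene model: genes laid round-robin on 22 chromosomes
  len <- round(stats::runif(m, 500, 3000))
  chrom <- paste0("chr", (seq_len(m) - 1L) %% 22L + 1L)
  idx_on_chrom <- stats::ave(seq_len(m), chrom, FUN = seq_along)
  start <- 1e6 + (idx_on_chrom - 1) * 2e5
  cds_len <- 3 * floor((len - 200) / 3)
  models <- rbind(
    data.frame(gene_id = genes, chrom = chrom, strand = "+", feature = "exon",
               start = start, end = start + len, stringsAsFactors = FALSE),
    data.frame(gene_id = genes, chrom = chrom, strand = "+", feature = "CDS",
               start = start + 99, end = start + 99 + cds_len,
               stringsAsFactors = FALSE))
  models <- models[order(models$gene_id, models$feature), , drop = FALSE]
  rownames(models) <- NULL
  list(counts = counts, truth = truth, models = models,
       true_size_factors = stats::setNames(sf, samples),
       gene_means = stats::setNames(mu, genes))
}

#' Simulate per-sample background depths
#'
#' Mean coverage of intergenic/intronic regions per library — the
#' background-noise estimate subtracted before outlier calling. In
#' deterministic mode every sample receives `mean_depth`; in stochastic
#' mode depths are log-normal with coefficient of variation `cv`.
#'
#' @param config [sim_config()].
#' @return Named non-negative numeric vector, one value per sample.
#' @export
simulate_noise <- function(config) {
  spec <- config$noise_spec
  assert_that(spec$mean_depth >= 0, "simulate_noise: negative depth in spec")
  n <- config$n_samples
  if (!isTRUE(spec$stochastic)) {
    return(stats::setNames(rep(spec$mean_depth, n), sample_ids(config)))
  }
  set.seed(config$seed + 202L)
  sdlog <- sqrt(log(1 + spec$cv^2))
  vals <- spec$mean_depth * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  stats::setNames(vals, sample_ids(config))
}

make_candidate <- function(id, lib, gene5, gene3, chrom5, pos5, orient5,
                           chrom3, pos3, orient3, split, spanning,
                           readthrough = FALSE, multimap = FALSE,
                           repfrac = 0) {
  data.frame(id = id, library_id = lib, gene5 = gene5, gene3 = gene3,
             chrom5 = chrom5, pos5 = pos5, orient5 = orient5,
             chrom3 = chrom3, pos3 = pos3, orient3 = orient3,
             split_reads = split, spanning_reads = spanning,
             is_readthrough = readthrough, multimapping = multimap,
             repeat_fraction = repfrac, stringsAsFactors = FALSE)
}

random_breakend <- function(n, lens) {
  chrom <- sample(names(lens), n, replace = TRUE)
  pos <- round(stats::runif(n, 1e6, lens[chrom] - 1e6))
  orient <- sample(c("+", "-"), n, replace = TRUE)
  list(chrom = chrom, pos = pos, orient = orient)
}

#' Simulate labeled fusion candidates with corroborating DNA junctions
#'
#' Emits one candidate class per primary filter criterion, each violating
#' exactly that criterion: readthroughs (criterion 1), recurrent
#' artifacts predicted in three libraries (criterion 2), multi-mapping
#' candidates (criterion 3), candidates mapping entirely to repeats
#' (criterion 4), and low-support candidates with 1-5 total reads
#' (criterion 5). True fusions pass all criteria and receive a
#' corroborating DNA breakpoint pair; artifacts do not. One recurrent
#' true ETS fusion (3' gene ERG) is planted across `n_ets_true`
#' libraries, exercising the ETS exemption of criterion 2.
#'
#' @param config [sim_config()].
#' @return List: `candidates`, `junctions`, `truth` (`candidate_id`,
#'   `class`, `is_true`).
#' @export
simulate_fusion_candidates <- function(config) {
  set.seed(config$seed + 303L)
  spec <- config$fusion_spec
  libs <- sample_ids(config)
  lens <- toy_chrom_lengths()
  cands <- list()
  juncs <- list()
  truth <- list()
  cid <- 0L
  jid <- 0L
  add <- function(class, is_true, cand, junction = NULL) {
    cands[[length(cands) + 1L]] <<- cand
    truth[[length(truth) + 1L]] <<- data.frame(
      candidate_id = cand$id, class = class, is_true = is_true,
      stringsAsFactors = FALSE)
    if (!is.null(junction)) juncs[[length(juncs) + 1L]] <<- junction
  }
  new_cid <- function() {
    cid <<- cid + 1L
    sprintf("FC%04d", cid)
  }
  new_junction <- function(cand) {
    jid <<- jid + 1L
    data.frame(id = sprintf("FJ%04d", jid), sample = cand$library_id,
               chromA = cand$chrom5, posA = cand$pos5, orientA = cand$orient5,
               chromB = cand$chrom3, posB = cand$pos3, orientB = cand$orient3,
               support_reads = sample(10:50, 1L), stringsAsFactors = FALSE)
  }

  gene_counter <- 0L
  new_gene <- function() {
    gene_counter <<- gene_counter + 1L
    sprintf("FG%03d", gene_counter)
  }

  for (i in seq_len(spec$n_true)) {
    e5 <- random_breakend(1L, lens)
    e3 <- random_breakend(1L, lens)
    cand <- make_candidate(new_cid(), sample(libs, 1L), new_gene(), new_gene(),
                           e5$chrom, e5$pos, e5$orient, e3$chrom, e3$pos, e3$orient,
                           sample(3:30, 1L), sample(3:30, 1L),
                           repfrac = stats::runif(1, 0, 0.5))
    add("true", TRUE, cand, new_junction(cand))
  }

  if (spec$n_ets_true > 0L) {
    assert_that(spec$n_ets_true <= length(libs),
                "simulate_fusion_candidates: n_ets_true exceeds the number of libraries")
    g5 <- new_gene()
    e5 <- random_breakend(1L, lens)
    e3 <- random_breakend(1L, lens)
    for (lib in sample(libs, spec$n_ets_true)) {
      cand <- make_candidate(new_cid(), lib, g5, "ERG",
                             e5$chrom, e5$pos + sample(-500:500, 1L), e5$orient,
                             e3$chrom, e3$pos + sample(-500:500, 1L), e3$orient,
                             sample(3:30, 1L), sample(3:30, 1L),
                             repfrac = stats::runif(1, 0, 0.5))
      add("true_ets", TRUE, cand, new_junction(cand))
    }
  }

  for (i in seq_len(spec$n_readthrough)) {
    chrom <- sample(names(lens), 1L)
    pos <- round(stats::runif(1, 1e6, lens[chrom] - 1e6))
    cand <- make_candidate(new_cid(), sample(libs, 1L), new_gene(), new_gene(),
                           chrom, pos, "+", chrom, pos + sample(2e4:5e4, 1L), "-",
                           sample(3:30, 1L), sample(3:30, 1L), readthrough = TRUE)
    add("readthrough", FALSE, cand)
  }

  n_groups <- spec$n_recurrent_artifact %/% 3L
  for (gi in seq_len(n_groups)) {
    g5 <- new_gene(); g3 <- new_gene()
    e5 <- random_breakend(1L, lens)
    e3 <- random_breakend(1L, lens)
    for (lib in sample(libs, 3L)) {
      cand <- make_candidate(new_cid(), lib, g5, g3,
                             e5$chrom, e5$pos, e5$orient,
                             e3$chrom, e3$pos, e3$orient,
                             sample(3:30, 1L), sample(3:30, 1L))
      add("recurrent_artifact", FALSE, cand)
    }
  }

  for (i in seq_len(spec$n_multimap)) {
    e5 <- random_breakend(1L, lens); e3 <- random_breakend(1L, lens)
    cand <- make_candidate(new_cid(), sample(libs, 1L), new_gene(), new_gene(),
                           e5$chrom, e5$pos, e5$orient, e3$chrom, e3$pos, e3$orient,
                           sample(3:30, 1L), sample(3:30, 1L), multimap = TRUE)
    add("multimap_artifact", FALSE, cand)
  }

  for (i in seq_len(spec$n_repeat)) {
    e5 <- random_breakend(1L, lens); e3 <- random_breakend(1L, lens)
    cand <- make_candidate(new_cid(), sample(libs, 1L), new_gene(), new_gene(),
                           e5$chrom, e5$pos, e5$orient, e3$chrom, e3$pos, e3$orient,
                           sample(3:30, 1L), sample(3:30, 1L), repfrac = 1)
    add("repeat_artifact", FALSE, cand)
  }

  for (i in seq_len(spec$n_low_support)) {
    e5 <- random_breakend(1L, lens); e3 <- random_breakend(1L, lens)
    total <- sample(1:5, 1L)
    split <- sample.int(total, 1L) - 1L
    cand <- make_candidate(new_cid(), sample(libs, 1L), new_gene(), new_gene(),
                           e5$chrom, e5$pos, e5$orient, e3$chrom, e3$pos, e3$orient,
                           split, total - split)
    add("low_support", FALSE, cand)
  }

  list(candidates = do.call(rbind, cands),
       junctions = if (length(juncs) > 0L) do.call(rbind, juncs) else NULL,
       truth = do.call(rbind, truth))
}

#' Simulate a chromoplexy-like breakpoint chain
#'
#' Generates `k_breakpoints` junctions forming a single closed chain over
#' `k_breakpoints` gene loci: each locus is cut once and its ends are
#' joined to the neighboring loci's ends, the topology of complex
#' rearrangements that disrupt several genes while expressing only one
#' fusion transcript. The designated expressed fusion joins the first two
#' loci. `k_breakpoints = 2` produces a simple reciprocal event (a
#' negative control for complex calling).
#'
#' @param k_breakpoints Number of junctions (>= 2).
#' @param genes Optional character vector of `k_breakpoints` gene ids.
#' @param sample_id Library carrying the chain.
#' @param seed RNG seed.
#' @param id_prefix Prefix for junction ids.
#' @return List: `junctions`, `models` (single-exon gene models with CDS),
#'   `fusion` (the expressed fusion candidate), `genes`.
#' @export
simulate_complex_chain <- function(k_breakpoints, genes = NULL,
                                   sample_id = "S01", seed = 1L,
                                   id_prefix = "CJ") {
  assert_that(k_breakpoints >= 2L, "simulate_complex_chain: k_breakpoints must be >= 2")
  set.seed(seed + 404L)
  k <- as.integer(k_breakpoints)
  if (is.null(genes)) genes <- sprintf("CG%02d", seq_len(k))
  assert_that(length(genes) == k, "simulate_complex_chain: need one gene per breakpoint")
  lens <- toy_chrom_lengths()
  chroms <- names(lens)[(seq_len(k) - 1L) %% length(lens) + 1L]
  center <- round(stats::runif(k, 10e6, lens[chroms] - 10e6))
  span <- 5e4
  cut <- center + sample(-1e4:1e4, k, replace = TRUE)
  nxt <- c(seq_len(k)[-1L], 1L)
  junctions <- data.frame(
    id = sprintf("%s%03d", id_prefix, seq_len(k)),
    sample = sample_id,
    chromA = chroms, posA = cut + sample(0:2000, k, replace = TRUE),
    orientA = sample(c("+", "-"), k, replace = TRUE),
    chromB = chroms[nxt], posB = cut[nxt] + sample(0:2000, k, replace = TRUE),
    orientB = sample(c("+", "-"), k, replace = TRUE),
    support_reads = sample(10:40, k, replace = TRUE),
    stringsAsFactors = FALSE)
  cds_len <- 3 * floor((2 * span - 2e4) / 3)
  models <- rbind(
    data.frame(gene_id = genes, chrom = chroms, strand = "+", feature = "exon",
               start = center - span, end = center + span, stringsAsFactors = FALSE),
    data.frame(gene_id = genes, chrom = chroms, strand = "+", feature = "CDS",
               start = center - span + 5e3, end = center - span + 5e3 + cds_len,
               stringsAsFactors = FALSE))
  fusion <- make_candidate(paste0(id_prefix, "_FUS"), sample_id,
                           genes[1L], genes[2L],
                           junctions$chromA[1L], junctions$posA[1L], junctions$orientA[1L],
                           junctions$chromB[1L], junctions$posB[1L], junctions$orientB[1L],
                           sample(6:20, 1L), sample(6:20, 1L))
  list(junctions = junctions, models = models, fusion = fusion, genes = genes)
}

#' Simulate a tandem-duplicator genome
#'
#' Plants `n_duplications` head-to-tail duplications on a toy 22-autosome
#' genome: dispersed non-overlapping focal events plus one nested serial
#' locus of `nested_n` duplications (an MDM2-amplification-like
#' configuration), with `n_subclonal` events at fractional copies
#' `subclonal_copies`. The copy-number profile is the flattened
#' piecewise-constant log2 ratio `log2((2 + total extra copies) / 2)`;
#' each duplication also emits a duplication-orientation junction whose
#' read support is `clonal_support_reference * copies`, multiplied for
#' nested duplications by the enclosing events' `(1 + copies)` factors
#' (a duplicated breakpoint is itself re-duplicated).
#'
#' @param config [sim_config()]; `config$td_spec` drives the genome.
#' @return List: `seg` (segment `data.frame`), `junctions`, `truth`
#'   (`junction_id`, `chrom`, `start`, `end`, `copies`, `subclonal`,
#'   `parent`).
#' @export
simulate_tandem_dup_genome <- function(config) {
  set.seed(config$seed + 505L)
  spec <- config$td_spec
  lens <- toy_chrom_lengths()
  assert_that(spec$n_duplications >= spec$nested_n,
              "simulate_tandem_dup_genome: n_duplications smaller than the nested locus")
  assert_that(spec$subclonal_copies > 0,
              "simulate_tandem_dup_genome: copies must be positive")

  dups <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                     copies = numeric(0), stringsAsFactors = FALSE)
  ## nested serial locus on chr12 (outermost 3 Mb, shrinking by ~60% each)
  if (spec$nested_n > 0L) {
    base <- round(stats::runif(1, 20e6, lens[["chr12"]] - 20e6))
    width <- 3e6
    s <- base; e <- base + width
    for (i in seq_len(spec$nested_n)) {
      copies <- if (i == spec$nested_n) 2 else 1
      dups <- rbind(dups, data.frame(chrom = "chr12", start = s, end = e,
                                     copies = copies))
      margin <- (e - s) * 0.2
      s <- round(s + margin); e <- round(e - margin)
    }
  }

  n_single <- spec$n_duplications - spec$nested_n
  placed <- split(dups[, c("start", "end")], dups$chrom)
  probs <- lens / sum(lens)
  attempts <- 0L
  while (n_single > 0L && attempts < spec$n_duplications * 200L) {
    attempts <- attempts + 1L
    chrom <- sample(names(lens), 1L, prob = probs)
    len <- round(10^stats::runif(1, log10(spec$min_len), log10(spec$max_len)))
    start <- round(stats::runif(1, 1e6, lens[[chrom]] - len - 1e6))
    end <- start + len
    prev <- placed[[chrom]]
    ## keep dispersed singles non-overlapping and clear of other events
    if (!is.null(prev) && nrow(prev) > 0L &&
        any(pmin(prev$end + 5e4, end) > pmax(prev$start - 5e4, start))) next
    copies <- as.numeric(sample(names(spec$copy_probs), 1L, prob = spec$copy_probs))
    dups <- rbind(dups, data.frame(chrom = chrom, start = start, end = end,
                                   copies = copies))
    placed[[chrom]] <- rbind(prev, data.frame(start = start, end = end))
    n_single <- n_single - 1L
  }
  assert_that(n_single == 0L, "simulate_tandem_dup_genome: could not place all duplications")

  ## sub-clonal subset among the dispersed singles
  single_idx <- setdiff(seq_len(nrow(dups)), seq_len(spec$nested_n))
  if (spec$n_subclonal > 0L && length(single_idx) > 0L) {
    sub <- sample(single_idx, min(spec$n_subclonal, length(single_idx)))
    dups$copies[sub] <- spec$subclonal_copies
  }
  dups$junction_id <- sprintf("TDJ%04d", seq_len(nrow(dups)))

  ## nesting relations (strict containment)
  dups$parent <- NA_character_
  for (i in seq_len(nrow(dups))) {
    enc <- which(dups$chrom == dups$chrom[i] &
                   dups$start <= dups$start[i] & dups$end >= dups$end[i] &
                   (dups$start < dups$start[i] | dups$end > dups$end[i]))
    if (length(enc) > 0L) {
      smallest <- enc[which.min(dups$end[enc] - dups$start[enc])]
      dups$parent[i] <- dups$junction_id[smallest]
    }
  }

  ## flatten to non-overlapping segments with baseline-diploid gaps
  seg_rows <- list()
  for (chrom in names(lens)) {
    d <- dups[dups$chrom == chrom, , drop = FALSE]
    bounds <- sort(unique(c(0, lens[[chrom]], d$start, d$end)))
    for (p in seq_len(length(bounds) - 1L)) {
      s <- bounds[p]; e <- bounds[p + 1L]
      extra <- sum(d$copies[d$start <= s & d$end >= e])
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        sample = spec$sample_id, chrom = chrom, start = s, end = e,
        log2ratio = log2((2 + extra) / 2), stringsAsFactors = FALSE)
    }
  }
  seg <- do.call(rbind, seg_rows)
  ## merge adjacent equal-ratio segments
  merged <- list()
  for (chrom in unique(seg$chrom)) {
    s <- seg[seg$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    keep <- s[1L, , drop = FALSE]
    for (i in seq_len(nrow(s))[-1L]) {
      last <- nrow(keep)
      if (s$log2ratio[i] == keep$log2ratio[last] && s$start[i] == keep$end[last]) {
        keep$end[last] <- s$end[i]
      } else {
        keep <- rbind(keep, s[i, , drop = FALSE])
      }
    }
    merged[[chrom]] <- keep
  }
  seg <- do.call(rbind, merged)
  rownames(seg) <- NULL

  ## duplication-orientation junctions: "+" at the gain start, "-" at the end
  ancestors_copies <- function(i) {
    total <- numeric(0)
    p <- dups$parent[i]
    while (!is.na(p)) {
      j <- which(dups$junction_id == p)
      total <- c(total, dups$copies[j])
      p <- dups$parent[j]
    }
    total
  }
  support <- vapply(seq_len(nrow(dups)), function(i) {
    mult <- prod(1 + ancestors_copies(i))
    max(1L, as.integer(round(spec$clonal_support_reference * dups$copies[i] * mult)))
  }, integer(1))
  junctions <- data.frame(
    id = dups$junction_id, sample = spec$sample_id,
    chromA = dups$chrom, posA = dups$end, orientA = "-",
    chromB = dups$chrom, posB = dups$start, orientB = "+",
    support_reads = support, stringsAsFactors = FALSE)

  truth <- data.frame(junction_id = dups$junction_id, chrom = dups$chrom,
                      start = dups$start, end = dups$end, copies = dups$copies,
                      subclonal = dups$copies < 1, parent = dups$parent,
                      stringsAsFactors = FALSE)
  list(seg = seg, junctions = junctions, truth = truth)
}

#' Simulate gene sets enriched for planted outliers
#'
#' Convenience generator for enrichment demonstrations: one set drawn
#' from the planted outlier genes plus unrelated random sets.
#'
#' @param config [sim_config()].
#' @param counts_sim A [simulate_counts()] result.
#' @param n_sets Number of random background sets.
#' @param set_size Genes per set.
#' @return Named list of gene sets.
#' @export
simulate_gene_sets <- function(config, counts_sim, n_sets = 20L, set_size = 30L) {
  set.seed(config$seed + 606L)
  genes <- rownames(counts_sim$counts)
  sets <- list()
  planted <- unique(counts_sim$truth$gene_id)
  if (length(planted) > 0L) {
    sets[["PLANTED_OUTLIERS"]] <- sample(planted, min(set_size, length(planted)))
  }
  for (i in seq_len(n_sets)) {
    sets[[sprintf("RANDOM_SET_%02d", i)]] <- sample(genes, set_size)
  }
  sets
}

#' Simulate a full cohort for an end-to-end run
#'
#' Bundles counts, noise, gene models, gene sets, fusion candidates with
#' corroborating junctions, chromoplexy-like chains and a
#' tandem-duplicator genome into one object consumable by
#' [run_pipeline()].
#'
#' @param config [sim_config()].
#' @return List with elements `config`, `counts_sim`, `noise`, `models`,
#'   `gene_sets`, `fusion_sim`, `chains`, `td_genome`, `junctions`
#'   (all junction tables combined), `candidates` (fusion candidates
#'   plus chain fusions), `coverage` (per-sample mean DNA depth, 10x).
#' @export
simulate_cohort <- function(config) {
  counts_sim <- simulate_counts(config)
  noise <- simulate_noise(config)
  fusion_sim <- simulate_fusion_candidates(config)
  chains <- lapply(seq_len(config$chain_spec$n_chains), function(i) {
    simulate_complex_chain(config$chain_spec$breakpoints_per_chain,
                           sample_id = sample_ids(config)[i],
                           seed = config$seed + i, id_prefix = sprintf("C%d_", i))
  })
  td_genome <- simulate_tandem_dup_genome(config)
  models <- rbind(counts_sim$models,
                  do.call(rbind, lapply(chains, `[[`, "models")))
  junctions <- do.call(rbind, c(
    list(fusion_sim$junctions),
    lapply(chains, `[[`, "junctions"),
    list(td_genome$junctions)))
  candidates <- do.call(rbind, c(list(fusion_sim$candidates),
                                 lapply(chains, `[[`, "fusion")))
  coverage <- stats::setNames(rep(10, config$n_samples), sample_ids(config))
  coverage[config$td_spec$sample_id] <- 10
  list(config = config, counts_sim = counts_sim, noise = noise,
       models = models, gene_sets = simulate_gene_sets(config, counts_sim),
       fusion_sim = fusion_sim, chains = chains, td_genome = td_genome,
       junctions = junctions, candidates = candidates, coverage = coverage)
}

#' Write a simulated cohort to disk in the pipeline's external formats
#'
#' @param cohort [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(cohort$counts_sim$counts, file.path(dir, "counts.tsv"))
  write_tsv(data.frame(sample = names(cohort$noise), depth = unname(cohort$noise)),
            file.path(dir, "noise.tsv"))
  write_gene_models(cohort$models, file.path(dir, "genes.gtf"))
  write_gmt(cohort$gene_sets, file.path(dir, "sets.gmt"))
  write_fusion_candidates(cohort$candidates, file.path(dir, "candidates.tsv"))
  write_bedpe(cohort$junctions, file.path(dir, "junctions.bedpe"))
  write_seg(cohort$td_genome$seg, file.path(dir, "copynumber.seg"))
  write_tsv(cohort$counts_sim$truth, file.path(dir, "truth_outliers.tsv"))
  write_tsv(cohort$fusion_sim$truth, file.path(dir, "truth_fusions.tsv"))
  write_tsv(cohort$td_genome$truth, file.path(dir, "truth_tandem_dups.tsv"))
  invisible(dir)
}
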