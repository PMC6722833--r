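#' Simulate transcript (unigene) counts for the integration stage
#'
#' Unigene counts arrive as a table in the real analysis; the simulator
#' provides an equivalent with known structure: NB counts per transcript
#' over the 3v3 design. Transcripts hosting the true target site of a
#' differential miRNA are themselves differential (|log2FC| =
#' `target_lfc`), anti-regulated with probability `p_anti` (cleavage
#' lowers the target when the miRNA rises) and co-regulated otherwise.
#'
#' @param truth a `ground_truth`.
#' @param expression the `expression` truth from
#'   [simulate_srna_libraries()].
#' @param depth approximate per-sample total count.
#' @param dispersion NB dispersion alpha.
#' @param target_lfc true |log2FC| of affected targets.
#' @param p_anti probability a DEM's target is anti-regulated.
#' @param n_reps replicates per condition.
#' @param seed non-negative integer.
#' @return list: `counts` (transcript x sample matrix), `condition`,
#'   `truth` (data.frame `transcript`, `true_lfc`, `regulation`).
#' @export
simulate_mrna_counts <- function(truth, expression, depth = 5e5,
                                 dispersion = 0.05, target_lfc = 1.5,
                                 p_anti = 0.6, n_reps = 3L, seed = 1L) {
  with_seed(seed, {
    tids <- names(truth$transcripts)
    n <- length(tids)
    true_lfc <- numeric(n)
    regulation <- rep(NA_character_, n)
    dem <- expression[expression$is_dem, , drop = FALSE]
    for (i in seq_len(nrow(dem))) {
      s <- truth$sites[truth$sites$mirna == dem$mirna[i], , drop = FALSE]
      ti <- match(s$transcript, tids)
      anti <- stats::runif(length(ti)) < p_anti
      sgn <- ifelse(anti, -sign(dem$true_lfc[i]), sign(dem$true_lfc[i]))
      true_lfc[ti] <- sgn * target_lfc
      regulation[ti] <- ifelse(anti, "anti", "positive")
    }
    base <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
    base <- base / sum(base) * depth
    condition <- factor(rep(c("LR", "HR"), each = n_reps),
                        levels = c("LR", "HR"))
    counts <- sapply(seq_len(2L * n_reps), function(j) {
      mu <- if (condition[j] == "LR") base else base * 2^true_lfc
      stats::rnbinom(n, mu = mu, size = 1 / dispersion)
    })
    rownames(counts) <- tids
    colnames(counts) <- paste0(condition, rep(seq_len(n_reps), 2L))
    list(counts = counts, condition = condition,
         truth = data.frame(transcript = tids, true_lfc = true_lfc,
                            regulation = regulation,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a term-to-gene annotation map
#'
#' Assigns every transcript to 1-3 generic terms and adds one focal
#' pathway term concentrated on the miRNA-targeted transcripts, so that
#' enrichment of a target-derived gene set is detectable by construction.
#'
#' @param truth a `ground_truth`.
#' @param n_terms number of generic background terms.
#' @param focal_term id of the target-enriched term.
#' @param seed non-negative integer.
#' @return named list: term -> character vector of transcript ids.
#' @export
simulate_term_map <- function(truth, n_terms = 10L,
                              focal_term = "terpenoid_backbone",
                              seed = 1L) {
  with_seed(seed, {
    tids <- names(truth$transcripts)
    terms <- sprintf("term%02d", seq_len(n_terms))
    map <- stats::setNames(vector("list", n_terms), terms)
    for (tid in tids) {
      mine <- sample(terms, sample(1:3, 1L))
      for (tm in mine) map[[tm]] <- c(map[[tm]], tid)
    }
    targeted <- unique(truth$sites$transcript)
    extra <- sample(setdiff(tids, targeted),
                    min(3L, length(setdiff(tids, targeted))))
    map[[focal_term]] <- c(targeted, extra)
    map
  })
}

#' Run the full pipeline end to end on simulated data
#'
#' Executes every stage in order under a single master seed: simulate the
#' ground truth and libraries, preprocess and classify reads, discover
#' known and novel miRNAs, quantify and test differential expression,
#' predict targets, validate cleavage against the simulated degradome,
#' and integrate differential miRNAs and targets into the regulatory
#' network with term enrichment. All stage outputs are returned in one
#' list; with `out_dir` set, the standard text artifacts (TSV/FASTA) are
#' also written. Results are byte-reproducible for a fixed configuration.
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @param out_dir optional output directory for text artifacts.
#' @return list with elements `truth`, `srna`, `reports`, `clean`,
#'   `catalog`, `counts`, `de_mirna`, `mrna`, `de_mrna`, `hits`,
#'   `degradome`, `profiles`, `events`, `edges`, `enrichment`,
#'   `scatter`, `length_hist`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  validate_config(config)
  seed <- config$seed
  sim <- config$simulate

  # --- simulate -----------------------------------------------------------
  tx <- generate_transcriptome(sim$n_transcripts, sim$transcript_length,
                               sim$gc, seed = seed)
  truth <- plant_hairpins(tx, n_mirnas = sim$n_mirnas, seed = seed + 1L)
  srna <- simulate_srna_libraries(
    truth, depth = sim$depth, dispersion = sim$dispersion,
    frac_dem = sim$frac_dem, lfc_magnitude = sim$lfc_magnitude,
    adaptor = sim$adaptor, bg_ncrna_frac = sim$background_ncrna_frac,
    bg_random24_frac = sim$background_random24_frac, seed = seed + 2L)
  degradome <- simulate_degradome(
    truth, site_spike_factor = sim$degradome_spike_factor,
    background_rate = sim$degradome_background_rate, seed = seed + 3L)

  # --- preprocess ---------------------------------------------------------
  pp <- config$preprocess
  clean <- list(); reports <- list()
  for (lib in names(srna$libraries)) {
    fr <- filter_reads(srna$libraries[[lib]], adaptor = sim$adaptor,
                       min_len = pp$min_len, max_len = pp$max_len,
                       max_n_frac = pp$max_n_frac,
                       min_mean_q = pp$min_mean_q)
    fr$reads$class <- classify_ncrna(fr$reads, truth$ncrna_refs)
    clean[[lib]] <- fr$reads
    reports[[lib]] <- fr$report
  }
  length_hist <- length_histogram(do.call(rbind, clean))

  # --- discover (pooled unannotated reads) --------------------------------
  pooled <- do.call(rbind, lapply(clean, function(x) {
    x[x$class == "unannotated", c("seq", "count")]
  }))
  pooled <- stats::aggregate(count ~ seq, pooled, sum)
  pooled <- pooled[order(-pooled$count, pooled$seq), , drop = FALSE]
  # discovery at desk scale: reads seen at least a handful of times;
  # singleton random background is not a credible miRNA candidate
  pooled <- pooled[pooled$count >= 5L, , drop = FALSE]
  dc <- config$discovery
  catalog <- discover_mirnas(
    pooled, truth$references, truth$references2, truth$precursors,
    max_mm = dc$max_mm, max_shift = dc$max_shift, max_mm2 = dc$max_mm2,
    mfe_max = dc$mfe_max, min_paired_frac = dc$min_paired_frac,
    max_mature_bulge = dc$max_mature_bulge)

  # --- quantify + differential expression ---------------------------------
  counts <- vapply(names(clean), function(lib) {
    idx <- match(catalog$seq, clean[[lib]]$seq)
    ifelse(is.na(idx), 0L, clean[[lib]]$count[idx])
  }, integer(nrow(catalog)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(catalog))
  rownames(counts) <- catalog$id
  colnames(counts) <- names(clean)
  cond <- factor(config$samples$condition[
    match(colnames(counts), config$samples$sample)],
    levels = c("LR", "HR"))
  total_reads <- vapply(clean, function(x) sum(x$count), numeric(1))
  de <- config$de
  de_mirna <- differential_expression(
    counts, cond, lfc_threshold = de$lfc_threshold,
    fdr_threshold = de$fdr_threshold,
    dispersion_floor = de$dispersion_floor,
    pseudocount = de$pseudocount, total_reads = total_reads)

  # --- mRNA side ----------------------------------------------------------
  mrna <- simulate_mrna_counts(truth, srna$expression, seed = seed + 4L)
  de_mrna <- differential_expression(
    mrna$counts, mrna$condition, lfc_threshold = de$lfc_threshold,
    fdr_threshold = de$fdr_threshold,
    dispersion_floor = de$dispersion_floor, pseudocount = de$pseudocount)

  # --- target prediction --------------------------------------------------
  tg <- config$targets
  matures <- stats::setNames(catalog$seq, catalog$id)
  hits <- scan_transcriptome(
    matures, truth$transcripts, cutoff = tg$cutoff,
    penalty_gu = tg$penalty_gu, penalty_mismatch = tg$penalty_mismatch,
    penalty_gap = tg$penalty_gap, seed_start = tg$seed_start,
    seed_end = tg$seed_end, seed_multiplier = tg$seed_multiplier,
    max_gaps = tg$max_gaps)

  # --- degradome validation -----------------------------------------------
  dg <- config$degradome
  profiles <- build_profile(degradome$tags, truth$transcripts)
  events <- validate_cleavage(hits, profiles, max_mm = dg$max_mm,
                              gu_counts_as = dg$gu_counts_as)

  # --- integration --------------------------------------------------------
  links <- unique(rbind(
    data.frame(mirna = events$mirna, target = events$transcript,
               evidence = "degradome", stringsAsFactors = FALSE),
    data.frame(mirna = hits$mirna, target = hits$transcript,
               evidence = "predicted", stringsAsFactors = FALSE)))
  links <- links[!duplicated(links[, c("mirna", "target")]), , drop = FALSE]
  edges <- build_network(de_mirna, de_mrna, links)
  scatter <- if (nrow(edges)) {
    correlation_scatter_data(de_mirna, de_mrna, edges)
  } else NULL
  term_map <- simulate_term_map(truth, seed = seed + 5L)
  target_set <- intersect(unique(events$transcript),
                          unique(unlist(term_map)))
  enrichment <- hypergeom_enrich(target_set, term_map,
                                 alpha = config$enrichment$alpha,
                                 adjust = config$enrichment$adjust)

  res <- list(truth = truth, srna = srna, reports = reports, clean = clean,
              catalog = catalog, counts = counts, de_mirna = de_mirna,
              mrna = mrna, de_mrna = de_mrna, hits = hits,
              degradome = degradome, profiles = profiles, events = events,
              edges = edges, enrichment = enrichment, scatter = scatter,
              length_hist = length_hist, term_map = term_map,
              config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Standard text artifacts of a pipeline run.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_sequences(seq_collection(names(res$truth$transcripts),
                                 unname(res$truth$transcripts)),
                  p("transcripts.fasta"))
  write_sequences(seq_collection(names(res$truth$precursors),
                                 unname(res$truth$precursors)),
                  p("precursors.fasta"))
  for (lib in names(res$clean)) {
    write_tsv(res$clean[[lib]], p(sprintf("clean_%s.tsv", lib)))
  }
  rep_df <- do.call(rbind, lapply(names(res$reports), function(lib) {
    data.frame(library = lib, as.data.frame(unclass(res$reports[[lib]])),
               stringsAsFactors = FALSE)
  }))
  write_tsv(rep_df, p("filter_report.tsv"))
  cat_df <- res$catalog
  cat_df$pos_state <- NULL
  write_tsv(cat_df, p("mirna_catalog.tsv"))
  write_count_table(res$counts, p("mirna_counts.tsv"))
  write_tsv(as.data.frame(res$de_mirna), p("de_mirna.tsv"))
  write_tsv(as.data.frame(res$de_mrna), p("de_mrna.tsv"))
  write_target_hits(res$hits, p("target_hits.tsv"))
  write_tsv(as.data.frame(res$events), p("cleavage_events.tsv"))
  zm <- zscore_rows(attr(res$de_mirna, "tpm"))
  write_count_table(round(zm, 6), p("zscore_mirna.tsv"))
  write_network(res$edges, p("network_nodes.tsv"), p("network_edges.tsv"))
  write_tsv(res$enrichment, p("enrichment.tsv"))
  invisible(out_dir)
}
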