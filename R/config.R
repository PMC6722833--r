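#' Default pipeline configuration
#'
#' Returns the full per-stage parameter set as a nested list. Constants
#' mirror the study design they emulate: read length bounds 18-30 nt and N
#' content < 10% for cleaning; at most 3 mismatches for known-miRNA matching
#' (0 for the secondary published set); at most 5 duplex mismatches with
#' miRNA positions 10-11 strictly Watson-Crick paired for degradome
#' validation; |log2FC| >= 1 and FDR <= 0.05 for differential calls;
#' enrichment significance 0.05.
#'
#' @param seed non-negative integer master seed.
#' @return a list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    samples = data.frame(
      sample = c("LR01", "LR02", "LR03", "HR01", "HR02", "HR03"),
      condition = rep(c("LR", "HR"), each = 3L),
      replicate = rep(1:3, 2L),
      stringsAsFactors = FALSE),
    conditions = data.frame(
      condition = c("LR", "HR"),
      rubber_content_pct = c(1.39, 4.80),
      stringsAsFactors = FALSE),
    simulate = list(
      n_transcripts = 40L,
      transcript_length = c(500L, 1500L),
      gc = 0.45,
      n_mirnas = 20L,
      depth = 2e5,
      dispersion = 0.1,
      frac_dem = 0.3,
      lfc_magnitude = 2,
      background_ncrna_frac = 0.35,
      background_random24_frac = 0.30,
      adaptor = "AGATCGGAAGAGCACACGTCT",
      degradome_spike_factor = 50,
      degradome_background_rate = 0.02),
    preprocess = list(
      min_len = 18L, max_len = 30L,
      max_n_frac = 0.10, min_mean_q = 20),
    discovery = list(
      max_mm = 3L, max_mm2 = 0L, max_shift = 2L,
      mfe_max = -15.8, min_paired_frac = 0.6, max_mature_bulge = 4L),
    de = list(
      lfc_threshold = 1, fdr_threshold = 0.05,
      dispersion_floor = 0.01, pseudocount = 0.5),
    targets = list(
      cutoff = 5.0, seed_start = 2L, seed_end = 13L,
      seed_multiplier = 1.5,
      penalty_gu = 0.5, penalty_mismatch = 1, penalty_gap = 2,
      max_gaps = 1L),
    degradome = list(
      max_mm = 5, gu_counts_as = 0.5, median_covered_only = TRUE),
    enrichment = list(
      alpha = 0.05, adjust = "BH"))
  class(cfg) <- c("pipeline_config", "list")
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks that every threshold lies in its documented range, sample ids are
#' unique, and the seed is a non-negative integer.
#'
#' @param cfg a `pipeline_config` list.
#' @return `cfg`, invisibly for chaining (errors on violation).
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.null(cfg$seed) || cfg$seed < 0 || cfg$seed != as.integer(cfg$seed)) {
    stop("seed must be a non-negative integer")
  }
  if (anyDuplicated(cfg$samples$sample)) stop("sample ids must be unique")
  if (!all(cfg$samples$condition %in% cfg$conditions$condition)) {
    stop("sample sheet references unknown condition labels")
  }
  p <- cfg$preprocess
  stopifnot(p$min_len >= 1, p$max_len >= p$min_len,
            p$max_n_frac >= 0, p$max_n_frac <= 1, p$min_mean_q >= 0)
  d <- cfg$discovery
  stopifnot(d$max_mm >= 0, d$max_mm2 >= 0, d$max_shift >= 0,
            d$mfe_max <= 0, d$min_paired_frac >= 0, d$min_paired_frac <= 1,
            d$max_mature_bulge >= 0)
  de <- cfg$de
  stopifnot(de$lfc_threshold >= 0, de$fdr_threshold > 0,
            de$fdr_threshold <= 1, de$dispersion_floor > 0)
  tg <- cfg$targets
  stopifnot(tg$cutoff >= 0, tg$seed_start >= 1, tg$seed_end >= tg$seed_start,
            tg$seed_multiplier >= 1, tg$max_gaps >= 0)
  dg <- cfg$degradome
  stopifnot(dg$max_mm >= 0, dg$gu_counts_as >= 0, dg$gu_counts_as <= 1)
  stopifnot(cfg$enrichment$alpha > 0, cfg$enrichment$alpha <= 1,
            cfg$enrichment$adjust %in% c("BH", "bonferroni"))
  invisible(cfg)
}

#' Read a configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default. The sample sheet may be given as a list of
#' `{sample, condition, replicate}` records.
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_config(user$seed %||% 1L))
  if (!is.null(user$samples)) {
    user$samples <- do.call(rbind, lapply(user$samples, as.data.frame))
  }
  cfg <- utils::modifyList(cfg, user)
  class(cfg) <- c("pipeline_config", "list")
  validate_config(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  samples:", paste(x$samples$sample, collapse = " "), "\n")
  cat("  stages:", paste(setdiff(names(x), c("seed", "samples", "conditions")),
                         collapse = ", "), "\n")
  invisible(x)
}
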