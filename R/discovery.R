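#' Match candidate reads to known mature miRNAs
#'
#' A candidate matches a reference when the two sequences have equal length
#' and Hamming distance at most `max_mm`, or when the candidate aligns to
#' the reference with a terminal shift of at most `max_shift` nt at either
#' end (isomiR-style end variation) and the overlapping region has Hamming
#' distance at most `max_mm`. The best (fewest-mismatch) reference wins;
#' ties break to the lexicographically smallest reference id, so the result
#' is independent of reference-set order. The family label is inherited
#' from the reference id (the token before the first `-`).
#'
#' @param candidates character vector of candidate sequences (unannotated
#'   clean reads), DNA or RNA alphabet.
#' @param references named character vector of mature reference sequences;
#'   ids formatted `family-...`.
#' @param max_mm maximum mismatches in the overlap.
#' @param max_shift maximum terminal shift, nt, at each end.
#' @return data.frame: `seq` (as supplied), `ref_id`, `family`,
#'   `mismatches`; one row per matched candidate.
#' @export
match_known <- function(candidates, references, max_mm = 3L,
                        max_shift = 2L) {
  if (length(references) == 0L) {
    message("empty mature reference set: no known miRNA calls")
    return(data.frame(seq = character(), ref_id = character(),
                      family = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  cand <- rna2dna(toupper(candidates))
  refs <- rna2dna(toupper(references))
  ref_ids <- names(refs)
  ord <- order(ref_ids)
  refs <- refs[ord]; ref_ids <- ref_ids[ord]
  ref_split <- strsplit(refs, "")

  rows <- lapply(seq_along(cand), function(i) {
    cs <- strsplit(cand[i], "")[[1]]
    lc <- length(cs)
    best_mm <- Inf; best_ref <- NA_character_
    for (r in seq_along(refs)) {
      rs <- ref_split[[r]]
      lr <- length(rs)
      for (o in -max_shift:max_shift) {
        # candidate position 1 sits at reference position 1 + o
        end_shift <- (o + lc) - lr
        if (abs(end_shift) > max_shift) next
        ov_c <- max(1L, 1L - o):min(lc, lr - o)
        if (length(ov_c) < 1L) next
        ov_r <- ov_c + o
        mm <- sum(cs[ov_c] != rs[ov_r])
        if (mm <= max_mm && mm < best_mm) {
          best_mm <- mm; best_ref <- ref_ids[r]
        }
      }
    }
    if (is.infinite(best_mm)) return(NULL)
    data.frame(seq = candidates[i], ref_id = best_ref,
               family = sub("-.*$", "", best_ref),
               mismatches = as.integer(best_mm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(seq = character(), ref_id = character(),
                      family = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' First-nucleotide and per-position composition of a mature miRNA set
#'
#' @param matures character vector of mature sequences (DNA or RNA; the
#'   summary is reported on the RNA alphabet).
#' @param max_pos last position reported in the positional matrix.
#' @return list with `first` (matrix: length x base, first-nucleotide
#'   frequencies, rows sum to 1) and `position` (matrix: base x position
#'   1..`max_pos`, columns sum to 1; positions beyond a miRNA's length do
#'   not contribute).
#' @export
nucleotide_bias <- function(matures, max_pos = 25L) {
  if (length(matures) == 0L) stop("empty mature set")
  seqs <- dna2rna(toupper(rna2dna(matures)))
  bases <- c("A", "C", "G", "U")
  lens <- nchar(seqs)
  first <- substr(seqs, 1L, 1L)
  len_levels <- sort(unique(lens))
  fm <- t(vapply(len_levels, function(l) {
    tab <- table(factor(first[lens == l], levels = bases))
    as.numeric(tab) / sum(tab)
  }, numeric(4)))
  dimnames(fm) <- list(len_levels, bases)
  pm <- vapply(seq_len(max_pos), function(p) {
    ch <- substr(seqs[lens >= p], p, p)
    tab <- table(factor(ch, levels = bases))
    n <- sum(tab)
    if (n == 0L) rep(NA_real_, 4L) else as.numeric(tab) / n
  }, numeric(4))
  dimnames(pm) <- list(bases, seq_len(max_pos))
  list(first = fm, position = pm)
}

#' Count known-miRNA family membership
#'
#' @param known data.frame with a `family` column (as produced by
#'   [match_known()] or [discover_mirnas()]).
#' @return named integer vector, family -> member count, sorted by
#'   decreasing count then family name.
#' @export
family_summary <- function(known) {
  fam <- if (is.data.frame(known)) known$family else known
  fam <- fam[!is.na(fam)]
  if (length(fam) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(fam)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(-out, names(out))]
}

#' Discover known and novel miRNAs from the unannotated read pool
#'
#' Known miRNAs are identified by mismatch-bounded matching against the
#' primary mature reference set (at most `max_mm` mismatches) and, for the
#' remainder, exact matching (`max_mm2`) against a secondary published set.
#' Reads still unassigned are tested as novel miRNAs: a read is novel when
#' it occurs within a candidate precursor whose hairpin passes
#' [evaluate_precursor()] with the mature interval at the read's position.
#'
#' @param reads data.frame of unique unannotated reads (`seq`, `count`).
#' @param references primary mature reference set (named character vector).
#' @param references2 optional secondary mature set (exact matching).
#' @param precursors optional named character vector of candidate precursor
#'   sequences (hairpin candidates, e.g. excised from a genome or supplied
#'   by the simulator).
#' @param max_mm,max_shift see [match_known()].
#' @param max_mm2 mismatch bound for the secondary set.
#' @param mfe_max,min_paired_frac,max_mature_bulge see
#'   [evaluate_precursor()].
#' @param min_len,max_len mature length bounds for any miRNA call.
#' @return data.frame of class `mirna_catalog`: `id`, `seq` (DNA
#'   alphabet), `mature_rna` (RNA alphabet), `count`, `status`
#'   (known/novel), `family`, `ref_id`, `mismatches`, `precursor_id`,
#'   `mfe`, `structure`.
#' @export
discover_mirnas <- function(reads, references, references2 = NULL,
                            precursors = NULL,
                            max_mm = 3L, max_shift = 2L, max_mm2 = 0L,
                            mfe_max = -15.8, min_paired_frac = 0.6,
                            max_mature_bulge = 4L,
                            min_len = 18L, max_len = 25L) {
  lens <- nchar(reads$seq)
  pool <- reads[lens >= min_len & lens <= max_len, , drop = FALSE]
  empty <- data.frame(
    id = character(), seq = character(), mature_rna = character(),
    count = integer(), status = character(), family = character(),
    ref_id = character(), mismatches = integer(),
    precursor_id = character(), mfe = numeric(), structure = character(),
    stringsAsFactors = FALSE)
  recs <- list()

  known1 <- match_known(pool$seq, references, max_mm = max_mm,
                        max_shift = max_shift)
  taken <- pool$seq %in% known1$seq
  if (nrow(known1)) {
    idx <- match(known1$seq, pool$seq)
    recs$known1 <- data.frame(
      id = paste0("eu-", sub("^[^-]*-", "", known1$ref_id)),
      seq = known1$seq, mature_rna = dna2rna(known1$seq),
      count = pool$count[idx], status = "known", family = known1$family,
      ref_id = known1$ref_id, mismatches = known1$mismatches,
      precursor_id = NA_character_, mfe = NA_real_,
      structure = NA_character_, stringsAsFactors = FALSE)
  }
  if (!is.null(references2) && length(references2)) {
    rest <- pool[!taken, , drop = FALSE]
    known2 <- match_known(rest$seq, references2, max_mm = max_mm2,
                          max_shift = 0L)
    if (nrow(known2)) {
      idx <- match(known2$seq, pool$seq)
      recs$known2 <- data.frame(
        id = paste0("eu-", sub("^[^-]*-", "", known2$ref_id)),
        seq = known2$seq, mature_rna = dna2rna(known2$seq),
        count = pool$count[idx], status = "known", family = known2$family,
        ref_id = known2$ref_id, mismatches = known2$mismatches,
        precursor_id = NA_character_, mfe = NA_real_,
        structure = NA_character_, stringsAsFactors = FALSE)
      taken <- taken | pool$seq %in% known2$seq
    }
  }
  if (!is.null(precursors) && length(precursors)) {
    rest <- pool[!taken, , drop = FALSE]
    novel_n <- 0L
    for (i in seq_len(nrow(rest))) {
      s <- rest$seq[i]
      hitp <- NA_character_; hit_eval <- NULL
      for (pid in sort(names(precursors))) {
        pos <- regexpr(s, precursors[[pid]], fixed = TRUE)
        if (pos == -1L) next
        ev <- evaluate_precursor(
          precursors[[pid]], as.integer(pos),
          as.integer(pos) + nchar(s) - 1L,
          mfe_max = mfe_max, min_paired_frac = min_paired_frac,
          max_mature_bulge = max_mature_bulge)
        if (ev$accept) { hitp <- pid; hit_eval <- ev; break }
      }
      if (!is.na(hitp)) {
        novel_n <- novel_n + 1L
        recs[[paste0("novel", i)]] <- data.frame(
          id = sprintf("n-eu-miR%d", novel_n),
          seq = s, mature_rna = dna2rna(s), count = rest$count[i],
          status = "novel", family = NA_character_,
          ref_id = NA_character_, mismatches = NA_integer_,
          precursor_id = hitp, mfe = hit_eval$mfe,
          structure = hit_eval$structure, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, c(recs, make.row.names = FALSE))
         else empty
  out$id <- make.unique(out$id, sep = "_") # isomiRs of one reference
  # deterministic ids for novel records: renumber in (count desc, seq) order
  if (any(out$status == "novel")) {
    nv <- which(out$status == "novel")
    ordv <- nv[order(-out$count[nv], out$seq[nv])]
    out$id[ordv] <- sprintf("n-eu-miR%d", seq_along(ordv))
    out <- out[order(out$status, out$id), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("mirna_catalog", "data.frame")
  out
}

#' @export
print.mirna_catalog <- function(x, ...) {
  cat(sprintf("<mirna_catalog> %d miRNAs (%d known, %d novel)\n",
              nrow(x), sum(x$status == "known"), sum(x$status == "novel")))
  if (nrow(x)) {
    print.data.frame(utils::head(
      x[, c("id", "mature_rna", "status", "family", "mismatches", "mfe")],
      10L))
  }
  invisible(x)
}
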