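#' Complementarity expectation score for a miRNA against a target window
#'
#' Aligns the miRNA 3'->5' against a target window 5'->3' by banded dynamic
#' programming (at most `max_gaps` gaps) and returns the minimal expectation
#' score under the standard plant-target penalty schema: Watson-Crick pair
#' 0, G:U wobble 0.5, mismatch 1, gap 2, with penalties at seed positions
#' (miRNA positions 2-13 from the 5' end) multiplied by 1.5. Ties are broken
#' deterministically (fewest gaps, then the alignment found leftmost).
#'
#' @param mirna miRNA sequence (RNA or DNA alphabet, no ambiguity codes).
#' @param window target window sequence; its length must be within the
#'   miRNA length +/- `max_gaps`.
#' @param penalty_gu,penalty_mismatch,penalty_gap position penalties.
#' @param seed_start,seed_end 1-based miRNA positions of the seed region.
#' @param seed_multiplier penalty multiplier inside the seed.
#' @param max_gaps maximum gaps in the alignment.
#' @return list with `score`, `alignment` (string over `|` pair, `o`
#'   wobble, `.` mismatch, `-` gap, written along the miRNA 3'->5'),
#'   `gaps`, `pos_state` (per miRNA position: 2 = WC, 1 = G:U,
#'   0 = mismatch, -1 = gap), `pos_target` (0-based window index opposite
#'   each miRNA position, -1 at gaps).
#' @export
complementarity_score <- function(mirna, window,
                                  penalty_gu = 0.5, penalty_mismatch = 1,
                                  penalty_gap = 2,
                                  seed_start = 2L, seed_end = 13L,
                                  seed_multiplier = 1.5, max_gaps = 1L) {
  m <- rna2dna(toupper(mirna))
  w <- rna2dna(toupper(window))
  if (grepl("[^ACGT]", m) || grepl("[^ACGT]", w)) {
    stop("ambiguous base in input: only A/C/G/U(T) allowed")
  }
  comp_align_cpp(m, w, penalty_gu, penalty_mismatch, penalty_gap,
                 as.integer(seed_start), as.integer(seed_end),
                 seed_multiplier, as.integer(max_gaps))
}

#' Scan transcripts for miRNA target sites
#'
#' Slides each miRNA over every transcript, scoring all windows of miRNA
#' length +/- `max_gaps` with [complementarity_score()]'s schema, and
#' reports every window at or below the expectation cutoff. Overlapping
#' hits of the same miRNA on the same transcript are merged, keeping the
#' best-scoring (then leftmost) one. Output is sorted by (miRNA,
#' transcript, position) and is invariant to transcript input order.
#'
#' @param mirnas named character vector of miRNA sequences (names are ids),
#'   or a `seq_collection`.
#' @param transcripts named character vector of transcript sequences, or a
#'   `seq_collection`.
#' @param cutoff maximum expectation score reported.
#' @inheritParams complementarity_score
#' @return data.frame of class `target_hits`: `mirna`, `transcript`,
#'   `start`, `end` (1-based inclusive target interval), `score`,
#'   `alignment`, `gaps`, `site` (target position opposite the miRNA
#'   position-10 nucleotide: the inferred cleavage coordinate), plus
#'   list-columns `pos_state` and `pos_target`.
#' @export
scan_transcriptome <- function(mirnas, transcripts, cutoff = 5.0,
                               penalty_gu = 0.5, penalty_mismatch = 1,
                               penalty_gap = 2,
                               seed_start = 2L, seed_end = 13L,
                               seed_multiplier = 1.5, max_gaps = 1L) {
  mirnas <- as_named_seqs(mirnas)
  transcripts <- as_named_seqs(transcripts)
  if (length(transcripts) == 0L) stop("no transcripts supplied")
  transcripts <- transcripts[order(names(transcripts))]
  rows <- list()
  for (mid in sort(names(mirnas))) {
    mseq <- rna2dna(toupper(mirnas[[mid]]))
    for (tid in names(transcripts)) {
      wins <- scan_windows_cpp(mseq, transcripts[[tid]], cutoff,
                               penalty_gu, penalty_mismatch, penalty_gap,
                               as.integer(seed_start), as.integer(seed_end),
                               seed_multiplier, as.integer(max_gaps))
      if (nrow(wins) == 0L) next
      wins$end0 <- wins$start0 + wins$len
      # merge overlapping windows: best score, then fewest gaps via the
      # re-alignment below, then leftmost
      wins <- wins[order(wins$score, wins$start0, wins$len), , drop = FALSE]
      kept <- list()
      for (r in seq_len(nrow(wins))) {
        w <- wins[r, ]
        overlaps <- any(vapply(kept, function(k) {
          w$start0 < k$end0 && k$start0 < w$end0
        }, logical(1)))
        if (!overlaps) kept[[length(kept) + 1L]] <- w
      }
      for (k in kept) {
        window <- substr(transcripts[[tid]], k$start0 + 1L, k$end0)
        aln <- complementarity_score(
          mseq, window, penalty_gu, penalty_mismatch, penalty_gap,
          seed_start, seed_end, seed_multiplier, max_gaps)
        tpos10 <- aln$pos_target[10L]
        site <- if (length(tpos10) && !is.na(tpos10) && tpos10 >= 0L) {
          k$start0 + tpos10 + 1L
        } else NA_integer_
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mid, transcript = tid,
          start = k$start0 + 1L, end = k$end0,
          score = aln$score, alignment = aln$alignment,
          gaps = aln$gaps, site = site,
          pos_state = I(list(aln$pos_state)),
          pos_target = I(list(aln$pos_target)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    mirna = character(), transcript = character(), start = integer(),
    end = integer(), score = numeric(), alignment = character(),
    gaps = integer(), site = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$transcript, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_hits", "data.frame")
  out
}

#' @export
print.target_hits <- function(x, ...) {
  cat(sprintf("<target_hits> %d hits, %d miRNAs, %d transcripts\n",
              nrow(x), length(unique(x$mirna)),
              length(unique(x$transcript))))
  if (nrow(x)) {
    print.data.frame(utils::head(
      x[, c("mirna", "transcript", "start", "end", "score", "alignment")],
      10L))
  }
  invisible(x)
}

# Coerce seq_collection / named vector to a named character vector.
as_named_seqs <- function(x) {
  if (inherits(x, "seq_collection") ||
      (is.data.frame(x) && all(c("id", "seq") %in% names(x)))) {
    stats::setNames(as.character(x$seq), x$id)
  } else if (is.character(x) && !is.null(names(x))) {
    x
  } else {
    stop("expected a seq_collection or a named character vector")
  }
}

#' Write target hits as TSV
#' @param hits a `target_hits` data.frame.
#' @param path output path.
#' @export
write_target_hits <- function(hits, path) {
  write_tsv(hits[, c("mirna", "transcript", "start", "end", "score",
                     "alignment", "site")], path)
}
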