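#' Fold a precursor candidate with a pseudo-energy pairing model
#'
#' Computes the maximum-weight nested (pseudoknot-free) secondary structure
#' of a sequence by dynamic programming, with pair pseudo-energies
#' G:C = -3, A:U = -2, G:U = -1 kcal/mol and a minimum hairpin loop of 3 nt.
#' This is a deliberately simple surrogate for a full nearest-neighbour
#' thermodynamic model: its pseudo-MFE values live on a scale comparable to
#' reported plant pre-miRNA MFEs and are used only to rank and threshold
#' hairpin candidates. Traceback is deterministic (pairing preferred, then
#' the leftmost partner), so refolding a sequence always yields the same
#' structure.
#'
#' @param seq a single sequence, 60-300 nt, RNA or DNA alphabet.
#' @return list with `structure` (dot-bracket string) and `mfe`
#'   (pseudo-MFE, kcal/mol pseudo-units, always <= 0).
#' @export
fold_pseudo_mfe <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- rna2dna(toupper(seq))
  n <- nchar(s)
  if (n < 60L || n > 300L) {
    stop("precursor length must be in [60, 300] nt; got ", n)
  }
  if (grepl("[^ACGT]", s)) stop("sequence contains non-ACGU characters")
  fold_dp(s)
}

# dot-bracket -> integer partner vector (NA = unpaired), 1-based
pairing_partners <- function(db) {
  chars <- strsplit(db, "")[[1]]
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  partner
}

# terminal (hairpin) loops: maximal runs of unpaired bases enclosed by a
# directly adjacent base pair, i.e. "(...)" motifs in the dot-bracket
terminal_loops <- function(db) {
  m <- gregexpr("\\(\\.*\\)", db)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m) + 1L,
             end = as.integer(m) + attr(m, "match.length") - 2L)
}

#' Evaluate a candidate miRNA precursor hairpin
#'
#' Applies the five structural screening rules for a novel-miRNA precursor:
#' the fold must have exactly one terminal loop (a single stem-loop); the
#' mature sequence must lie entirely on one arm without crossing the loop;
#' at least `min_paired_frac` of mature bases must be paired; at most
#' `max_mature_bulge` mature bases may be unpaired; and the pseudo-MFE must
#' be at or below `mfe_max`. The default MFE ceiling matches the upper end
#' of the range observed for accepted plant pre-miRNA hairpins
#' (-15.8 kcal/mol).
#'
#' @param precursor precursor sequence (60-300 nt).
#' @param mature_start,mature_end 1-based inclusive interval of the mature
#'   sequence within the precursor.
#' @param mfe_max maximum (least negative) acceptable pseudo-MFE.
#' @param min_paired_frac minimum fraction of mature bases paired.
#' @param max_mature_bulge maximum number of unpaired mature bases.
#' @return list with `accept` (logical), `reasons` (character vector, empty
#'   when accepted), `structure`, `mfe`, `paired_frac`.
#' @export
evaluate_precursor <- function(precursor, mature_start, mature_end,
                               mfe_max = -15.8, min_paired_frac = 0.6,
                               max_mature_bulge = 4L) {
  n <- nchar(rna2dna(toupper(precursor)))
  if (mature_start < 1L || mature_end > n || mature_start > mature_end) {
    stop("mature interval [", mature_start, ", ", mature_end,
         "] out of precursor bounds (length ", n, ")")
  }
  fold <- fold_pseudo_mfe(precursor)
  db <- fold$structure
  partner <- pairing_partners(db)
  loops <- terminal_loops(db)
  reasons <- character(0)
  if (nrow(loops) == 0L) {
    reasons <- c(reasons, "no stem-loop")
  } else if (nrow(loops) > 1L) {
    reasons <- c(reasons, "multiple loops")
  }
  mature_idx <- mature_start:mature_end
  if (nrow(loops) >= 1L) {
    loop <- loops[1L, ]
    crosses <- !(mature_end < loop$start || mature_start > loop$end)
    if (crosses) reasons <- c(reasons, "crosses loop")
  }
  paired <- !is.na(partner[mature_idx])
  paired_frac <- mean(paired)
  if (paired_frac < min_paired_frac) {
    reasons <- c(reasons, "low paired fraction")
  }
  if (sum(!paired) > max_mature_bulge) {
    reasons <- c(reasons, "mature bulge too large")
  }
  if (fold$mfe > mfe_max) {
    reasons <- c(reasons, "MFE above threshold")
  }
  list(accept = length(reasons) == 0L, reasons = reasons,
       structure = db, mfe = fold$mfe, paired_frac = paired_frac)
}
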