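#' Filter and trim raw small-RNA reads
#'
#' Applies the standard small-RNA cleaning cascade: drop reads with N
#' content at or above `max_n_frac` (default 10%), drop reads lacking the
#' 3' adaptor, trim the adaptor, drop low-quality reads (mean Phred below
#' `min_mean_q` over the trimmed insert; skipped for FASTA input), and drop
#' inserts shorter than `min_len` (18 nt) or longer than `max_len` (30 nt).
#' Survivors are deduplicated to (sequence, count) per library. The adaptor
#' is located by the rightmost exact occurrence of its first 8 nt.
#'
#' @param reads a `seq_collection` (columns `id`, `seq`, optional `qual`).
#' @param adaptor 3' adaptor sequence (non-empty; >= 8 nt recommended).
#' @param min_len,max_len inclusive insert length bounds, nt.
#' @param max_n_frac reads with N fraction >= this are removed.
#' @param min_mean_q minimum mean Phred quality (Phred+33) of the insert.
#' @return list with `reads` (data.frame `seq`, `count`, deduplicated,
#'   sorted by decreasing count then sequence) and `report` (a
#'   `read_filter_report`: raw, removed_n, removed_no_adaptor,
#'   removed_low_quality, removed_length, clean counts).
#' @export
filter_reads <- function(reads, adaptor, min_len = 18L, max_len = 30L,
                         max_n_frac = 0.10, min_mean_q = 20) {
  if (!nzchar(adaptor)) stop("adaptor must be non-empty")
  key <- toupper(substr(rna2dna(adaptor), 1L, 8L))
  seqs <- reads$seq
  qual <- reads$qual %||% rep(NA_character_, length(seqs))
  raw <- length(seqs)

  # rightmost exact occurrence of the adaptor key
  hit <- vapply(seqs, function(s) {
    m <- gregexpr(key, s, fixed = TRUE)[[1]]
    if (m[1] == -1L) NA_integer_ else as.integer(m[length(m)])
  }, integer(1), USE.NAMES = FALSE)
  insert <- substr(seqs, 1L, ifelse(is.na(hit), nchar(seqs), hit - 1L))
  insert[is.na(hit)] <- seqs[is.na(hit)]

  # N content is judged on the biological insert (whole read if untrimmed)
  n_frac <- (nchar(insert) - nchar(gsub("N", "", insert, fixed = TRUE))) /
    pmax(nchar(insert), 1L)
  fail_n <- n_frac >= max_n_frac
  fail_adaptor <- !fail_n & is.na(hit)
  iqual <- ifelse(is.na(qual), NA_character_,
                  substr(qual, 1L, ifelse(is.na(hit), nchar(qual), hit - 1L)))
  mean_q <- vapply(iqual, function(q) {
    if (is.na(q) || !nchar(q)) return(NA_real_)
    mean(utf8ToInt(q) - 33)
  }, numeric(1), USE.NAMES = FALSE)
  fail_q <- !fail_n & !fail_adaptor & !is.na(mean_q) & mean_q < min_mean_q

  len <- nchar(insert)
  fail_len <- !fail_n & !fail_adaptor & !fail_q &
    (len < min_len | len > max_len)

  keep <- !(fail_n | fail_adaptor | fail_q | fail_len)
  kept <- insert[keep]
  tab <- table(kept)
  dedup <- data.frame(seq = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
  dedup <- dedup[order(-dedup$count, dedup$seq), , drop = FALSE]
  rownames(dedup) <- NULL

  report <- structure(list(
    raw = raw,
    removed_n = sum(fail_n),
    removed_no_adaptor = sum(fail_adaptor),
    removed_low_quality = sum(fail_q),
    removed_length = sum(fail_len),
    clean = sum(keep)), class = "read_filter_report")
  list(reads = dedup, report = report)
}

#' @export
print.read_filter_report <- function(x, ...) {
  cat("<read_filter_report>\n")
  cat(sprintf("  raw reads:          %d\n", x$raw))
  cat(sprintf("  removed (N >= 10%%): %d\n", x$removed_n))
  cat(sprintf("  removed (no 3'ad):  %d\n", x$removed_no_adaptor))
  cat(sprintf("  removed (low qual): %d\n", x$removed_low_quality))
  cat(sprintf("  removed (length):   %d\n", x$removed_length))
  cat(sprintf("  clean reads:        %d\n", x$clean))
  invisible(x)
}

#' Classify unique reads into non-coding RNA classes
#'
#' A read is assigned the first class, in the fixed priority order
#' rRNA > tRNA > snRNA > snoRNA > repeat, for which it is an exact
#' substring of any reference sequence of that class; unmatched reads are
#' `"unannotated"` (the pool that feeds miRNA discovery).
#'
#' @param reads character vector of unique read sequences (or the `reads`
#'   data.frame from [filter_reads()]).
#' @param references named list of character vectors of reference
#'   sequences; recognised names: `rRNA`, `tRNA`, `snRNA`, `snoRNA`,
#'   `repeat`.
#' @return character vector of class labels, parallel to `reads`.
#' @export
classify_ncrna <- function(reads, references) {
  if (is.data.frame(reads)) reads <- reads$seq
  priority <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")
  labels <- rep("unannotated", length(reads))
  unresolved <- rep(TRUE, length(reads))
  for (cls in priority) {
    refs <- references[[cls]]
    if (is.null(refs) || length(refs) == 0L) {
      message("no reference sequences for class ", cls,
              "; class never assigned")
      next
    }
    # '#' never occurs in sequences, so substring hits cannot span records
    blob <- paste(toupper(refs), collapse = "#")
    idx <- which(unresolved)
    hit <- vapply(reads[idx], function(s) grepl(s, blob, fixed = TRUE),
                  logical(1), USE.NAMES = FALSE)
    labels[idx[hit]] <- cls
    unresolved[idx[hit]] <- FALSE
  }
  labels
}

#' Read-length histogram
#'
#' Count-weighted frequency of insert lengths in a cleaned library.
#'
#' @param reads data.frame with `seq` and `count` (as from
#'   [filter_reads()]).
#' @return named numeric vector: length -> frequency, summing to 1
#'   (empty input returns an empty vector).
#' @export
length_histogram <- function(reads) {
  if (nrow(reads) == 0L) return(stats::setNames(numeric(0), character(0)))
  len <- nchar(reads$seq)
  tot <- tapply(reads$count, len, sum)
  out <- as.numeric(tot) / sum(reads$count)
  names(out) <- names(tot)
  out
}
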