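#' Build per-transcript degradome T-plot profiles
#'
#' Maps 20-21 nt degradome tags to the transcript set by exact full-length
#' substring matching (only perfectly matched tags contribute) and
#' accumulates, for every transcript position, the count of tag 5' ends
#' starting there. Under 5'-monophosphate (PARE) chemistry the tag start
#' marks the decay/cleavage position. Multi-mapping tags increment every
#' exact locus.
#'
#' @param tags data.frame with `seq` and `count` (unique tags), or a
#'   `seq_collection` (each record then counts once per occurrence of its
#'   id).
#' @param transcripts named character vector or `seq_collection`.
#' @return list of class `degradome_profiles`: per transcript a list with
#'   `transcript`, `counts` (numeric vector over 1-based positions),
#'   `max`, `argmax` (positions attaining the maximum), `median_covered`
#'   (median over positions with count >= 1). Attribute `unmapped` holds
#'   the total count of tags with no exact match.
#' @export
build_profile <- function(tags, transcripts) {
  transcripts <- as_named_seqs(transcripts)
  if (inherits(tags, "seq_collection") || !"count" %in% names(tags)) {
    tab <- table(tags$seq)
    tags <- data.frame(seq = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
  }
  widths <- nchar(tags$seq)
  if (any(widths < 20L | widths > 21L)) {
    stop("degradome tags must be 20-21 nt")
  }
  subj <- Biostrings::DNAStringSet(transcripts)
  profiles <- lapply(names(transcripts), function(tid) {
    list(transcript = tid,
         counts = numeric(nchar(transcripts[[tid]])))
  })
  names(profiles) <- names(transcripts)
  mapped <- rep(FALSE, nrow(tags))
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(tags$seq[idx]))
    for (tid in names(transcripts)) {
      m <- Biostrings::matchPDict(pd, subj[[tid]])
      starts <- IRanges::start(m)
      hit <- which(lengths(starts) > 0L)
      for (h in hit) {
        mapped[idx[h]] <- TRUE
        for (s in starts[[h]]) {
          profiles[[tid]]$counts[s] <-
            profiles[[tid]]$counts[s] + tags$count[idx[h]]
        }
      }
    }
  }
  profiles <- lapply(profiles, function(p) {
    cnt <- p$counts
    covered <- cnt[cnt >= 1]
    p$max <- if (length(covered)) max(cnt) else 0
    p$argmax <- if (p$max > 0) which(cnt == p$max) else integer(0)
    p$median_covered <- if (length(covered)) stats::median(covered) else NA_real_
    p
  })
  attr(profiles, "unmapped") <- sum(tags$count[!mapped])
  class(profiles) <- "degradome_profiles"
  profiles
}

#' @export
print.degradome_profiles <- function(x, ...) {
  covered <- vapply(x, function(p) sum(p$counts >= 1), numeric(1))
  cat(sprintf(
    "<degradome_profiles> %d transcripts, %d with tags, %g unmapped tag reads\n",
    length(x), sum(covered > 0), attr(x, "unmapped")))
  invisible(x)
}

#' Classify a cleavage site into T-plot category 0-4
#'
#' CleaveLand-style categories rank the tag abundance at the site against
#' the whole transcript profile: category 4 — exactly one raw read at the
#' position; 0 — more than one read, equal to the transcript maximum, and
#' the maximum is unique; 1 — more than one read, equal to the maximum, but
#' several positions attain it; 2 — more than one read, below the maximum
#' but above the median; 3 — more than one read, at or below the median.
#' The median is computed over covered positions (count >= 1). The rules
#' are applied in the order 4, 0, 1, 2, 3, which resolves the only overlap
#' (a single-read site that is also the unique maximum is category 4).
#'
#' @param profile one element of [build_profile()]'s result (a list with
#'   `counts`), or a bare numeric count vector.
#' @param site 1-based transcript position.
#' @return integer category in 0..4.
#' @export
classify_category <- function(profile, site) {
  counts <- if (is.list(profile)) profile$counts else profile
  if (site < 1L || site > length(counts)) stop("site outside transcript")
  if (!any(counts >= 1)) stop("profile has no covered position")
  x <- counts[site]
  if (x < 1) stop("no degradome support at site ", site)
  mx <- max(counts)
  n_arg <- sum(counts == mx)
  med <- stats::median(counts[counts >= 1])
  if (x == 1) return(4L)
  if (x == mx && n_arg == 1L) return(0L)
  if (x == mx) return(1L)
  if (x > med) return(2L)
  3L
}

#' Validate miRNA-guided cleavage with degradome evidence
#'
#' Keeps a predicted target hit when (i) its duplex mismatch load is within
#' `max_mm` (G:U wobbles counted as `gu_counts_as` mismatches; gaps count
#' as full mismatches), (ii) miRNA positions 10 and 11 are both
#' Watson-Crick paired (no mismatch is tolerated at the cleavage bond), and
#' (iii) the degradome profile has at least one tag starting at the site
#' opposite the miRNA 10/11 bond. Each retained event is assigned its
#' T-plot category.
#'
#' @param hits a `target_hits` data.frame from [scan_transcriptome()]
#'   (alignments attached).
#' @param profiles a `degradome_profiles` object.
#' @param max_mm maximum effective mismatches in the duplex.
#' @param gu_counts_as weight of a G:U wobble toward `max_mm`.
#' @return data.frame of class `cleavage_events`: `mirna`, `transcript`,
#'   `site`, `mismatches` (effective count), `gu`, `site_abundance`,
#'   `category`. Attribute `dropped` tabulates rejection reasons.
#' @export
validate_cleavage <- function(hits, profiles, max_mm = 5,
                              gu_counts_as = 0.5) {
  rows <- list()
  dropped <- c(no_profile = 0L, too_many_mismatches = 0L,
               site_10_11_unpaired = 0L, no_degradome_support = 0L,
               no_site = 0L)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    st <- h$pos_state[[1L]]
    if (is.na(h$site)) { dropped["no_site"] <- dropped["no_site"] + 1L; next }
    n_mm <- sum(st == 0L)
    n_gu <- sum(st == 1L)
    n_gap <- sum(st == -1L) + max(0L, h$gaps - sum(st == -1L))
    eff <- n_mm + n_gap + gu_counts_as * n_gu
    if (eff > max_mm) {
      dropped["too_many_mismatches"] <- dropped["too_many_mismatches"] + 1L
      next
    }
    if (length(st) < 11L || st[10L] != 2L || st[11L] != 2L) {
      dropped["site_10_11_unpaired"] <- dropped["site_10_11_unpaired"] + 1L
      next
    }
    prof <- profiles[[h$transcript]]
    if (is.null(prof)) {
      dropped["no_profile"] <- dropped["no_profile"] + 1L
      next
    }
    ab <- if (h$site >= 1L && h$site <= length(prof$counts))
      prof$counts[h$site] else 0
    if (ab < 1) {
      dropped["no_degradome_support"] <- dropped["no_degradome_support"] + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      mirna = h$mirna, transcript = h$transcript, site = h$site,
      mismatches = eff, gu = n_gu, site_abundance = ab,
      category = classify_category(prof, h$site),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    mirna = character(), transcript = character(), site = integer(),
    mismatches = numeric(), gu = integer(), site_abundance = numeric(),
    category = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$transcript, out$site), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("cleavage_events", "data.frame")
  out
}

#' @export
print.cleavage_events <- function(x, ...) {
  cat(sprintf("<cleavage_events> %d events; categories: %s\n", nrow(x),
              paste(sprintf("%d:%d", 0:4,
                            vapply(0:4, function(k) sum(x$category == k),
                                   integer(1))), collapse = " ")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 8L))
  invisible(x)
}

#' T-plot series for one transcript
#'
#' @param profile one element of a `degradome_profiles` object.
#' @param events `cleavage_events` rows (may span several transcripts;
#'   rows for other transcripts are ignored).
#' @return list with `series` (data.frame `position`, `abundance`, one row
#'   per transcript position) and `markers` (data.frame `site`,
#'   `abundance`, `mirna`, sorted by site).
#' @export
tplot_data <- function(profile, events) {
  ev <- events[events$transcript == profile$transcript, , drop = FALSE]
  series <- data.frame(position = seq_along(profile$counts),
                       abundance = profile$counts)
  markers <- data.frame(site = ev$site,
                        abundance = profile$counts[ev$site],
                        mirna = ev$mirna, stringsAsFactors = FALSE)
  markers <- markers[order(markers$site, markers$mirna), , drop = FALSE]
  rownames(markers) <- NULL
  list(series = series, markers = markers)
}
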