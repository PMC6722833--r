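#' Generate a random transcript set
#'
#' Transcripts are i.i.d. base sequences with the requested GC content;
#' lengths are uniform over `length_range`. Reproducible for a fixed seed.
#'
#' @param n_transcripts number of transcripts (>= 1).
#' @param length_range length bounds, nt; minimum 200 (shorter transcripts
#'   cannot host a cleavage window with flanks).
#' @param gc target GC fraction.
#' @param seed non-negative integer.
#' @return named character vector (`tx0001`...) of DNA sequences.
#' @export
generate_transcriptome <- function(n_transcripts, length_range = c(500L, 1500L),
                                   gc = 0.45, seed = 1L) {
  if (n_transcripts < 1L) stop("n_transcripts must be >= 1")
  if (min(length_range) < 200L) {
    stop("transcript length must be >= 200 nt (too short to host a cleavage window)")
  }
  stopifnot(gc > 0, gc < 1)
  with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n_transcripts,
                   replace = TRUE)
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(lens, function(n) {
      paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    stats::setNames(seqs, sprintf("tx%04d", seq_len(n_transcripts)))
  })
}

# fraction of G+C characters over a set of sequences
gc_content <- function(seqs) {
  nch <- sum(nchar(seqs))
  ngc <- sum(nchar(gsub("[AT]", "", seqs)))
  ngc / nch
}

random_seq <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Default mature-length distribution: dominated by 21 nt (canonical
# miR/DCL1 product) with a substantial 24 nt class and minor neighbours.
default_mature_length_dist <- function() {
  c(`19` = 0.05, `20` = 0.10, `21` = 0.45, `22` = 0.15, `23` = 0.05,
    `24` = 0.20)
}

#' Plant miRNA hairpin precursors and target sites
#'
#' Designs `n_mirnas` mature miRNAs with lengths drawn from
#' `mature_length_dist`, builds for each a stem-loop precursor (perfect
#' mature/star duplex extended by a closing stem, joined by a
#' non-self-pairing loop) that passes [evaluate_precursor()] under default
#' parameters, and plants for each miRNA one perfectly complementary
#' target site in a transcript, recording the true cleavage position
#' (the target nucleotide opposite miRNA position 10). A subset of
#' miRNAs (`frac_known`) is designated "known" and emitted as the mature
#' reference sets: most in the primary (miRBase-style) set, the rest in a
#' secondary published set matched exactly.
#'
#' @param transcripts named character vector from
#'   [generate_transcriptome()].
#' @param n_mirnas number of miRNAs to plant.
#' @param mature_length_dist named numeric vector of probabilities over
#'   mature lengths; support must lie within 18-25 nt.
#' @param frac_known fraction of miRNAs designated known.
#' @param seed non-negative integer.
#' @return object of class `ground_truth`: list with `transcripts` (with
#'   planted sites), `hairpins` (data.frame: `mirna`, `mature`, `length`,
#'   `status`, `family`, `precursor_id`, `mature_start`, `mature_end`),
#'   `precursors` (named vector), `references` / `references2` (named
#'   mature reference vectors), `sites` (data.frame: `mirna`,
#'   `transcript`, `start`, `end`, `site`), and `ncrna_refs` (named list
#'   of reference sets for read classification).
#' @export
plant_hairpins <- function(transcripts, n_mirnas = 20L,
                           mature_length_dist = default_mature_length_dist(),
                           frac_known = 0.3, seed = 1L) {
  lens <- as.integer(names(mature_length_dist))
  if (any(lens < 18L | lens > 25L)) {
    stop("mature_length_dist must be supported on 18-25 nt")
  }
  stopifnot(abs(sum(mature_length_dist) - 1) < 1e-8, n_mirnas >= 1L)
  with_seed(seed, {
    hairpins <- list()
    precursors <- character(0)
    used <- character(0)
    for (i in seq_len(n_mirnas)) {
      for (try in 1:50) {
        L <- lens[sample.int(length(lens), 1L, prob = mature_length_dist)]
        mature <- random_seq(L, gc = 0.5)
        if (mature %in% used) next
        loop <- paste(sample(c("A", "C"), 7L, replace = TRUE, # A/C cannot pair
                             prob = c(0.5, 0.5)), collapse = "")
        stem_ext <- random_seq(8L, gc = 0.5)
        prec <- paste0(stem_ext, mature, loop, revcomp(paste0(stem_ext, mature)))
        mstart <- 9L
        mend <- 8L + L
        ev <- evaluate_precursor(prec, mstart, mend)
        if (ev$accept) {
          used <- c(used, mature)
          pid <- sprintf("prec%03d", i)
          precursors[pid] <- prec
          hairpins[[i]] <- data.frame(
            mirna = sprintf("mir%03d", i), mature = mature, length = L,
            precursor_id = pid, mature_start = mstart, mature_end = mend,
            mfe = ev$mfe, stringsAsFactors = FALSE)
          break
        }
        if (try == 50L) stop("failed to design an acceptable hairpin")
      }
    }
    hp <- do.call(rbind, hairpins)

    # known/novel designation and reference sets
    n_known <- round(frac_known * n_mirnas)
    known_idx <- if (n_known > 0) sample(n_mirnas, n_known) else integer(0)
    hp$status <- "novel"
    hp$status[known_idx] <- "known"
    hp$family <- NA_character_
    families <- c("MIR156", "MIR396", "MIR166", "MIR172", "MIR398")
    references <- character(0)
    references2 <- character(0)
    if (n_known > 0) {
      fam <- families[((seq_len(n_known) - 1L) %% length(families)) + 1L]
      hp$family[known_idx] <- fam
      # roughly one in four known miRNAs belongs to the secondary
      # (previously published, exact-match) set
      second <- seq_len(n_known) %% 4L == 0L
      for (j in seq_len(n_known)) {
        id <- sprintf("%s-miR%03d", fam[j], known_idx[j])
        if (second[j]) references2[id] <- hp$mature[known_idx[j]]
        else references[id] <- hp$mature[known_idx[j]]
      }
    }

    # plant one perfectly complementary target site per miRNA
    tx <- transcripts
    sites <- list()
    occupied <- lapply(tx, function(x) integer(0))
    for (i in seq_len(nrow(hp))) {
      L <- hp$length[i]
      for (try in 1:200) {
        tid <- sample(names(tx), 1L)
        n <- nchar(tx[[tid]])
        if (n < L + 100L) next
        s <- sample(51:(n - L - 50L), 1L)
        span <- s:(s + L - 1L)
        if (length(intersect(span, occupied[[tid]]))) next
        sitemer <- revcomp(hp$mature[i])
        substr(tx[[tid]], s, s + L - 1L) <- sitemer
        occupied[[tid]] <- c(occupied[[tid]], (s - 25L):(s + L + 24L))
        sites[[i]] <- data.frame(
          mirna = hp$mirna[i], transcript = tid,
          start = s, end = s + L - 1L,
          site = s + L - 10L, # opposite miRNA position 10
          stringsAsFactors = FALSE)
        break
      }
      if (is.null(sites[i][[1]])) stop("could not place a target site")
    }

    truth <- list(
      transcripts = tx,
      hairpins = hp,
      precursors = precursors,
      references = references,
      references2 = references2,
      sites = do.call(rbind, sites),
      ncrna_refs = make_ncrna_refs())
    class(truth) <- "ground_truth"
    truth
  })
}

# Small reference sets for the non-miRNA ncRNA classes. Sizes are desk
# scale; the simulator samples background read fragments from these same
# sequences, so classification has real work to do.
make_ncrna_refs <- function() {
  list(
    rRNA = stats::setNames(vapply(1:3, function(i) random_seq(600), ""),
                           paste0("rRNA_", 1:3)),
    tRNA = stats::setNames(vapply(1:5, function(i) random_seq(75), ""),
                           paste0("tRNA_", 1:5)),
    snRNA = stats::setNames(vapply(1:3, function(i) random_seq(150), ""),
                            paste0("snRNA_", 1:3)),
    snoRNA = stats::setNames(vapply(1:3, function(i) random_seq(110), ""),
                             paste0("snoRNA_", 1:3)),
    `repeat` = stats::setNames(vapply(1:3, function(i) random_seq(300), ""),
                               paste0("repeat_", 1:3)))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d transcripts, %d planted miRNAs (%d known), %d true sites\n",
    length(x$transcripts), nrow(x$hairpins),
    sum(x$hairpins$status == "known"), nrow(x$sites)))
  invisible(x)
}

#' Simulate the six small-RNA sequencing libraries
#'
#' Generates per-sample reads for two conditions (LR: low rubber content,
#' HR: high rubber content) with `n_reps_per_condition` replicates each.
#' miRNA read counts are negative binomial
#' (`variance = mu + dispersion * mu^2`) around condition-specific means; a
#' designated fraction of miRNAs (`frac_dem`) is differentially expressed
#' with true |log2FC| = `lfc_magnitude` (half up in HR, half down).
#' Background reads — fragments of the ncRNA references and random 24-nt
#' sequences emulating the heterochromatic siRNA class — are included so
#' that preprocessing and classification are exercised; the pooled length
#' histogram peaks at 24 nt with 21 nt second. Reads carry the 3' adaptor
#' and constant high quality.
#'
#' @param truth a `ground_truth` from [plant_hairpins()].
#' @param depth approximate reads per library.
#' @param n_reps_per_condition replicates per condition (>= 2).
#' @param dispersion NB dispersion alpha.
#' @param frac_dem fraction of miRNAs truly differential.
#' @param lfc_magnitude true |log2FC| of DEMs (>= 1).
#' @param adaptor literal 3' adaptor appended to every read.
#' @param bg_ncrna_frac,bg_random24_frac background composition fractions.
#' @param seed non-negative integer.
#' @return list: `libraries` (named list of `seq_collection`s with
#'   qualities, names `LR01..HR03`), `samples` (sample sheet),
#'   `true_counts` (miRNA x sample matrix of simulated miRNA read
#'   counts), `expression` (data.frame: `mirna`, `mean_LR`, `mean_HR`,
#'   `true_lfc`, `is_dem`).
#' @export
simulate_srna_libraries <- function(truth, depth = 2e5,
                                    n_reps_per_condition = 3L,
                                    dispersion = 0.1, frac_dem = 0.3,
                                    lfc_magnitude = 2,
                                    adaptor = "AGATCGGAAGAGCACACGTCT",
                                    bg_ncrna_frac = 0.35,
                                    bg_random24_frac = 0.30,
                                    seed = 1L) {
  stopifnot(n_reps_per_condition >= 2L, frac_dem >= 0, frac_dem <= 1)
  if (frac_dem > 0 && lfc_magnitude < 1) stop("lfc_magnitude must be >= 1")
  hp <- truth$hairpins
  n_mir <- nrow(hp)
  n_dem <- round(frac_dem * n_mir)
  mirna_frac <- 1 - bg_ncrna_frac - bg_random24_frac
  if (n_dem > 0 && mirna_frac * depth / n_mir < 10) {
    warning("depth too small to realize the requested DEM fraction reliably")
  }
  with_seed(seed, {
    dem_idx <- if (n_dem > 0) sample(n_mir, n_dem) else integer(0)
    sign_up <- rep(FALSE, n_mir)
    if (n_dem > 0) {
      sign_up[dem_idx[seq_len(ceiling(n_dem / 2))]] <- TRUE
    }
    true_lfc <- numeric(n_mir)
    true_lfc[dem_idx] <- ifelse(sign_up[dem_idx], lfc_magnitude,
                                -lfc_magnitude)
    base <- stats::rlnorm(n_mir, meanlog = 0, sdlog = 0.8)
    base <- base / sum(base) * mirna_frac * depth
    mean_lr <- base
    mean_hr <- base * 2^true_lfc

    samples <- data.frame(
      sample = c(sprintf("LR%02d", seq_len(n_reps_per_condition)),
                 sprintf("HR%02d", seq_len(n_reps_per_condition))),
      condition = rep(c("LR", "HR"), each = n_reps_per_condition),
      replicate = rep(seq_len(n_reps_per_condition), 2L),
      stringsAsFactors = FALSE)

    true_counts <- matrix(0L, n_mir, nrow(samples),
                          dimnames = list(hp$mirna, samples$sample))
    libraries <- list()
    nc <- truth$ncrna_refs
    class_w <- c(rRNA = 0.35, tRNA = 0.25, snRNA = 0.15, snoRNA = 0.12,
                 `repeat` = 0.13)
    for (j in seq_len(nrow(samples))) {
      mu <- if (samples$condition[j] == "LR") mean_lr else mean_hr
      cnt <- stats::rnbinom(n_mir, mu = mu, size = 1 / dispersion)
      true_counts[, j] <- cnt
      mir_reads <- rep(hp$mature, cnt)

      n_nc <- round(bg_ncrna_frac * depth)
      cls <- sample(names(class_w), n_nc, replace = TRUE, prob = class_w)
      refs_of <- lapply(nc, function(r) r[sample(length(r), n_nc,
                                                 replace = TRUE)])
      nc_reads <- vapply(seq_len(n_nc), function(k) {
        ref <- refs_of[[cls[k]]][k]
        l <- sample(18:30, 1L)
        s <- sample(nchar(ref) - l + 1L, 1L)
        substr(ref, s, s + l - 1L)
      }, character(1))

      n_rd <- round(bg_random24_frac * depth)
      rd_reads <- vapply(seq_len(n_rd), function(k) random_seq(24L), "")

      reads <- c(mir_reads, nc_reads, rd_reads)
      reads <- reads[sample(length(reads))]
      reads <- paste0(reads, adaptor)
      libraries[[samples$sample[j]]] <- seq_collection(
        sprintf("%s_read%07d", samples$sample[j], seq_along(reads)),
        reads, strrep("I", nchar(reads)))
    }
    expression <- data.frame(
      mirna = hp$mirna, mean_LR = mean_lr, mean_HR = mean_hr,
      true_lfc = true_lfc, is_dem = seq_len(n_mir) %in% dem_idx,
      stringsAsFactors = FALSE)
    list(libraries = libraries, samples = samples,
         true_counts = true_counts, expression = expression)
  })
}

#' Simulate a degradome (PARE) tag library
#'
#' Background tags are laid down per transcript position as Poisson counts
#' with mean `background_rate`; at every true cleavage site the tag-start
#' count is Poisson with mean `site_spike_factor` times the mean count of
#' a covered background position (`background_rate / (1 - e^-rate)`, which
#' tends to 1 as the background rate vanishes — with `background_rate = 0`
#' tags appear only at true sites). Every tag is a 20- or 21-nt 5'-anchored
#' subsequence of its transcript, so its start position marks the decay
#' coordinate.
#'
#' @param truth a `ground_truth` from [plant_hairpins()].
#' @param site_spike_factor spike multiplier (> 1).
#' @param background_rate expected background tags per position.
#' @param seed non-negative integer.
#' @return list: `tags` (data.frame `seq`, `count`, unique 20-21 nt tags),
#'   `sites` (the truth sites data.frame, with the simulated
#'   `site_count` appended).
#' @export
simulate_degradome <- function(truth, site_spike_factor = 50,
                               background_rate = 0.02, seed = 1L) {
  stopifnot(site_spike_factor > 1, background_rate >= 0)
  covered_mean <- if (background_rate > 0) {
    background_rate / (1 - exp(-background_rate))
  } else 1
  with_seed(seed, {
    tag_tab <- new.env(parent = emptyenv())
    add_tag <- function(tx_seq, pos, count) {
      n <- nchar(tx_seq)
      l <- sample(20:21, 1L)
      if (pos + l - 1L > n) l <- 20L
      if (pos + l - 1L > n) return(invisible())
      tg <- substr(tx_seq, pos, pos + l - 1L)
      cur <- get0(tg, envir = tag_tab, ifnotfound = 0L)
      assign(tg, cur + count, envir = tag_tab)
    }
    site_count <- integer(nrow(truth$sites))
    for (tid in names(truth$transcripts)) {
      tx_seq <- truth$transcripts[[tid]]
      n <- nchar(tx_seq)
      maxs <- n - 19L
      if (background_rate > 0) {
        cnts <- stats::rpois(maxs, background_rate)
        for (p in which(cnts > 0L)) add_tag(tx_seq, p, cnts[p])
      }
      rows <- which(truth$sites$transcript == tid)
      for (r in rows) {
        k <- stats::rpois(1L, site_spike_factor * covered_mean)
        site_count[r] <- k
        if (k > 0L) add_tag(tx_seq, truth$sites$site[r], k)
      }
    }
    tags <- data.frame(seq = ls(tag_tab),
                       count = vapply(ls(tag_tab), get, 0L,
                                      envir = tag_tab),
                       stringsAsFactors = FALSE)
    tags <- tags[order(-tags$count, tags$seq), , drop = FALSE]
    rownames(tags) <- NULL
    sites <- truth$sites
    sites$site_count <- site_count
    list(tags = tags, sites = sites)
  })
}

#' Simulate a bare negative-binomial count matrix for DE calibration
#'
#' A stripped-down generator for benchmarking the differential test: no
#' reads, just NB counts for `n_features` features over a two-condition
#' design with known differential subset.
#'
#' @param n_features number of features.
#' @param n_reps replicates per condition.
#' @param depth approximate per-sample total count.
#' @param dispersion NB dispersion alpha.
#' @param frac_dem fraction of features truly differential.
#' @param lfc_magnitude true |log2FC| of differential features.
#' @param seed non-negative integer.
#' @return list: `counts` (matrix), `condition` (factor LR/HR, LR first),
#'   `truth` (data.frame: `feature`, `true_lfc`, `is_dem`).
#' @export
simulate_count_matrix <- function(n_features = 500L, n_reps = 3L,
                                  depth = 2e5, dispersion = 0.1,
                                  frac_dem = 0.1, lfc_magnitude = 2,
                                  seed = 1L) {
  with_seed(seed, {
    n_dem <- round(frac_dem * n_features)
    dem_idx <- if (n_dem > 0) sample(n_features, n_dem) else integer(0)
    true_lfc <- numeric(n_features)
    if (n_dem > 0) {
      up <- dem_idx[seq_len(ceiling(n_dem / 2))]
      true_lfc[dem_idx] <- -lfc_magnitude
      true_lfc[up] <- lfc_magnitude
    }
    base <- stats::rlnorm(n_features, meanlog = 0, sdlog = 1)
    base <- base / sum(base) * depth
    mean_lr <- base
    mean_hr <- base * 2^true_lfc
    condition <- factor(rep(c("LR", "HR"), each = n_reps),
                        levels = c("LR", "HR"))
    counts <- sapply(seq_len(2L * n_reps), function(j) {
      mu <- if (condition[j] == "LR") mean_lr else mean_hr
      stats::rnbinom(n_features, mu = mu, size = 1 / dispersion)
    })
    rownames(counts) <- sprintf("f%04d", seq_len(n_features))
    colnames(counts) <- paste0(condition, rep(seq_len(n_reps), 2L))
    list(counts = counts, condition = condition,
         truth = data.frame(feature = rownames(counts),
                            true_lfc = true_lfc,
                            is_dem = seq_len(n_features) %in% dem_idx,
                            stringsAsFactors = FALSE))
  })
}
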