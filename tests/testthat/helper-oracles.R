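# Independent brute-force oracles used across the suite. Each one is a
# direct transcription of the mathematical definition, structured
# differently from the package implementation it checks.

# --- maximum-weight nested pairing by explicit recursion (no memoization;
# anchored at the left end, unlike the bottom-up interval DP) -------------
oracle_pair_w <- function(a, b) {
  key <- paste0(a, b)
  switch(key, GC = -3, CG = -3, AT = -2, TA = -2, GT = -1, TG = -1, NA_real_)
}

oracle_fold_mfe <- function(seq, min_loop = 3) {
  s <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j) # i unpaired
    for (k in (i + min_loop + 1):j) {
      w <- oracle_pair_w(s[i], s[k])
      if (is.na(w)) next
      cand <- w + rec(i + 1, k - 1) + (if (k < j) rec(k + 1, j) else 0)
      if (cand < best) best <- cand
    }
    best
  }
  rec(1, length(s))
}

# --- exhaustive alignment enumeration for complementarity scoring --------
# Enumerates every global alignment of the reversed miRNA against the
# window with at most max_gaps gaps, scoring columns directly.
oracle_comp_score <- function(mirna, window, penalty_gu = 0.5,
                              penalty_mm = 1, penalty_gap = 2,
                              seed_start = 2, seed_end = 13,
                              seed_mult = 1.5, max_gaps = 1) {
  m <- rev(strsplit(mirna, "")[[1]])
  w <- strsplit(window, "")[[1]]
  L <- length(m); W <- length(w)
  mult <- function(pos) if (pos >= seed_start && pos <= seed_end) seed_mult else 1
  base <- function(a, b) {
    if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) return(0)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(penalty_gu)
    penalty_mm
  }
  rec <- function(i, j, g) { # i, j: next unconsumed indices (1-based)
    if (i > L && j > W) return(0)
    best <- Inf
    pos <- L - i + 1 # 1-based miRNA position of m[i]
    if (i <= L && j <= W) {
      best <- min(best, base(m[i], w[j]) * mult(pos) + rec(i + 1, j + 1, g))
    }
    if (g < max_gaps) {
      if (i <= L) best <- min(best, penalty_gap * mult(pos) + rec(i + 1, j, g + 1))
      if (j <= W) {
        gm <- if (i <= L) mult(pos) else 1
        best <- min(best, penalty_gap * gm + rec(i, j + 1, g + 1))
      }
    }
    best
  }
  rec(1, 1, 0)
}

# --- hypergeometric upper tail by explicit subset enumeration ------------
# P(X >= k) for X = |sample ∩ annotated| when the n-subset is drawn
# uniformly from a population of size N with K annotated elements.
oracle_hyper_tail <- function(N, K, n, k) {
  population <- seq_len(N)
  annotated <- seq_len(K)
  subsets <- utils::combn(N, n)
  hits <- apply(subsets, 2, function(ss) sum(ss %in% annotated))
  mean(hits >= k)
}

# --- Benjamini-Hochberg by the textbook step-up procedure ---------------
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  cummin_rev <- Inf
  for (r in m:1) {
    cummin_rev <- min(cummin_rev, p[ord[r]] * m / r)
    adj[ord[r]] <- min(1, cummin_rev)
  }
  adj
}

# --- T-plot category by literal transcription of the printed definitions,
# with the documented precedence (4 first, then 0, 1, 2, 3) ---------------
oracle_category <- function(counts, site) {
  x <- counts[site]
  covered <- counts[counts >= 1]
  mx <- max(counts)
  n_max <- sum(counts == mx)
  med <- stats::median(covered)
  is4 <- x == 1
  is0 <- x > 1 && x == mx && n_max == 1
  is1 <- x > 1 && x == mx && n_max > 1
  is2 <- x > 1 && x < mx && x > med
  is3 <- x > 1 && x <= med
  if (is4) return(4L)
  if (is0) return(0L)
  if (is1) return(1L)
  if (is2) return(2L)
  if (is3) return(3L)
  NA_integer_
}

# --- misc helpers --------------------------------------------------------
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# dinucleotide-preserving shuffle (random Eulerian-walk style swap shuffle)
dinuc_shuffle <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  for (it in 1:(5 * n)) {
    i <- sample(2:(n - 2), 1)
    j <- sample(2:(n - 2), 1)
    if (abs(i - j) < 2) next
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    # swap s[i] and s[j] only if flanking dinucleotides are preserved
    ok <- s[i - 1] == s[j - 1] && s[i + 1] == s[j + 1]
    if (ok) { tmp <- s[i]; s[i] <- s[j]; s[j] <- tmp }
  }
  paste(s, collapse = "")
}

write_tmp <- function(lines, ext = ".fasta") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
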