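test_that("profiles accumulate exact-match tag starts only", {
  set.seed(20)
  tx <- c(t1 = random_dna(400), t2 = random_dna(400))
  tag <- substr(tx[["t1"]], 101, 120) # 20-mer starting at position 101
  tags <- data.frame(seq = tag, count = 7L, stringsAsFactors = FALSE)
  prof <- build_profile(tags, tx)
  expect_equal(prof[["t1"]]$counts[101], 7)
  expect_equal(sum(prof[["t1"]]$counts), 7)
  expect_equal(sum(prof[["t2"]]$counts), 0)

  # one mismatch -> contributes nothing, counted unmapped
  mm <- tag
  substr(mm, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mm, 5, 5))[1]
  has_mm <- grepl(mm, paste(tx, collapse = "#"), fixed = TRUE)
  if (!has_mm) {
    p2 <- build_profile(data.frame(seq = mm, count = 3L), tx)
    expect_equal(sum(p2[["t1"]]$counts) + sum(p2[["t2"]]$counts), 0)
    expect_equal(attr(p2, "unmapped"), 3)
  }

  # multi-mapping tag increments every exact locus
  shared <- substr(tx[["t1"]], 51, 71) # 21-mer
  tx2 <- c(t1 = tx[["t1"]],
           t2 = paste0(substr(tx[["t2"]], 1, 200), shared,
                       substr(tx[["t2"]], 222, 400)))
  p3 <- build_profile(data.frame(seq = shared, count = 2L), tx2)
  expect_equal(p3[["t1"]]$counts[51], 2)
  expect_equal(p3[["t2"]]$counts[201], 2)

  expect_error(build_profile(data.frame(seq = "ACGT", count = 1L), tx),
               "20-21")
})

test_that("category assignment reproduces the printed worked examples", {
  # {p1:5, p2:1, p3:1}: site p1 is the unique maximum -> 0
  expect_equal(classify_category(c(5, 1, 1), 1), 0L)
  # {p1:5, p2:5, p3:1}: two maxima -> 1
  expect_equal(classify_category(c(5, 5, 1), 1), 1L)
  # {9,3,2,2,1}: covered median 2; above median below max -> 2;
  # at/below median -> 3; single read -> 4
  prof <- c(9, 3, 2, 2, 1)
  expect_equal(classify_category(prof, 2), 2L)
  expect_equal(classify_category(prof, 3), 3L)
  expect_equal(classify_category(prof, 5), 4L)
  expect_error(classify_category(c(0, 2, 3), 1), "no degradome support")
})

test_that("category classifier agrees with the literal-definition oracle exhaustively", {
  # all profiles of length <= 5 with counts in {0,1,2,3}, all covered sites
  seen <- integer(0)
  for (len in 1:5) {
    grid <- as.matrix(expand.grid(rep(list(0:3), len)))
    for (r in seq_len(nrow(grid))) {
      counts <- as.numeric(grid[r, ])
      if (!any(counts >= 1)) next
      for (site in which(counts >= 1)) {
        got <- classify_category(counts, site)
        want <- oracle_category(counts, site)
        expect_false(is.na(want))
        if (got != want) {
          fail(sprintf("profile [%s] site %d: got %d want %d",
                       paste(counts, collapse = ","), site, got, want))
        }
        seen <- union(seen, got)
      }
    }
  }
  expect_setequal(seen, 0:4)
})

test_that("cleavage validation enforces the mismatch and 10-11 pairing rules", {
  set.seed(26)
  mir <- random_dna(21)
  site_seq <- revcomp(mir)
  tx <- c(tt = paste0(random_dna(120), site_seq, random_dna(120)))
  hits <- scan_transcriptome(c(m1 = mir), tx, cutoff = 0)
  tag <- substr(tx[["tt"]], hits$site, hits$site + 19L)
  prof <- build_profile(data.frame(seq = tag, count = 30L), tx)
  ev <- validate_cleavage(hits, prof)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$category, 0L)
  expect_equal(ev$site, hits$site)

  # mismatch exactly at miRNA position 10 -> rejected
  bad <- tx[["tt"]]
  idx10 <- hits$start + (21L - 10L) # window index L-p+1 within the site
  substr(bad, idx10, idx10) <- setdiff(c("A", "C", "G", "T"),
                                       substr(bad, idx10, idx10))[1]
  tx_bad <- c(tt = bad)
  h_bad <- scan_transcriptome(c(m1 = mir), tx_bad, cutoff = 5)
  h_bad <- h_bad[h_bad$start == hits$start, , drop = FALSE]
  expect_equal(nrow(h_bad), 1L)
  p_bad <- build_profile(
    data.frame(seq = substr(bad, hits$site, hits$site + 19L), count = 10L),
    tx_bad)
  ev_bad <- validate_cleavage(h_bad, p_bad)
  expect_equal(nrow(ev_bad), 0L)
  expect_equal(unname(attr(ev_bad, "dropped")["site_10_11_unpaired"]), 1L)

  # more than five mismatches -> rejected even with degradome support
  six <- tx[["tt"]]
  for (j in c(1, 2, 3, 4, 5, 6)) { # window indices 1..6 = miRNA 16..21
    k <- hits$start + j - 1L
    substr(six, k, k) <- setdiff(c("A", "C", "G", "T"), substr(six, k, k))[1]
  }
  tx6 <- c(tt = six)
  h6 <- scan_transcriptome(c(m1 = mir), tx6, cutoff = 20)
  h6 <- h6[h6$start == hits$start, , drop = FALSE]
  if (nrow(h6) == 1L && sum(h6$pos_state[[1]] == 0L) >= 6L) {
    p6 <- build_profile(
      data.frame(seq = substr(six, h6$site, h6$site + 19L), count = 10L), tx6)
    ev6 <- validate_cleavage(h6, p6)
    expect_equal(nrow(ev6), 0L)
  }
})

test_that("T-plot data marks events at their profile abundance", {
  counts <- c(rep(0, 10), 5, rep(0, 5), 2, rep(0, 3))
  prof <- list(transcript = "tx", counts = counts)
  ev <- data.frame(mirna = "m1", transcript = "tx", site = 11L)
  td <- tplot_data(prof, ev)
  expect_equal(nrow(td$series), length(counts))
  expect_equal(nrow(td$markers), 1L)
  expect_equal(td$markers$abundance, 5)
  td0 <- tplot_data(prof, ev[0, ])
  expect_equal(nrow(td0$markers), 0L)
})
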