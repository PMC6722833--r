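test_that("transcriptome generation is seeded, GC-controlled and guarded", {
  a <- generate_transcriptome(10, c(500, 1500), gc = 0.45, seed = 7)
  b <- generate_transcriptome(10, c(500, 1500), gc = 0.45, seed = 7)
  expect_identical(a, b)
  expect_error(generate_transcriptome(0), ">= 1")
  expect_error(generate_transcriptome(5, c(100, 300)), ">= 200")
  big <- generate_transcriptome(100, c(500, 1500), gc = 0.45, seed = 1)
  gc <- sum(nchar(gsub("[AT]", "", big))) / sum(nchar(big))
  expect_gte(gc, 0.40)
  expect_lte(gc, 0.50)
})

test_that("planted hairpins pass the precursor detector and are seeded", {
  tx <- generate_transcriptome(15, c(500, 1500), seed = 2)
  t1 <- plant_hairpins(tx, n_mirnas = 20, seed = 4)
  t2 <- plant_hairpins(tx, n_mirnas = 20, seed = 4)
  expect_identical(t1$hairpins$mature, t2$hairpins$mature)
  ok <- vapply(seq_len(nrow(t1$hairpins)), function(i) {
    h <- t1$hairpins[i, ]
    evaluate_precursor(t1$precursors[[h$precursor_id]],
                       h$mature_start, h$mature_end)$accept
  }, logical(1))
  expect_true(all(ok))
  # every true cleavage site lies within its transcript and opposite
  # miRNA position 10 of the planted complementary interval
  s <- t1$sites
  expect_true(all(s$site >= 1 &
                    s$site <= nchar(t1$transcripts[s$transcript])))
  L <- t1$hairpins$length[match(s$mirna, t1$hairpins$mirna)]
  expect_equal(s$site, s$start + L - 10L)
  # point-mass length distribution is honoured
  t21 <- plant_hairpins(tx, n_mirnas = 5,
                        mature_length_dist = c(`21` = 1), seed = 1)
  expect_true(all(t21$hairpins$length == 21L))
  expect_error(plant_hairpins(tx, 5, mature_length_dist = c(`30` = 1)),
               "18-25")
})

test_that("simulated sRNA libraries have the designed expression and length structure", {
  tx <- generate_transcriptome(15, c(500, 1500), seed = 2)
  truth <- plant_hairpins(tx, n_mirnas = 20, seed = 4)
  sim <- simulate_srna_libraries(truth, depth = 2e4, frac_dem = 0.3,
                                 lfc_magnitude = 2, seed = 9)
  sim2 <- simulate_srna_libraries(truth, depth = 2e4, frac_dem = 0.3,
                                  lfc_magnitude = 2, seed = 9)
  expect_identical(sim$libraries, sim2$libraries)
  expect_equal(names(sim$libraries),
               c("LR01", "LR02", "LR03", "HR01", "HR02", "HR03"))
  # designated DEMs carry |true lfc| exactly, others zero
  ex <- sim$expression
  expect_true(all(abs(ex$true_lfc[ex$is_dem]) == 2))
  expect_true(all(ex$true_lfc[!ex$is_dem] == 0))
  n0 <- simulate_srna_libraries(truth, depth = 1e4, frac_dem = 0, seed = 1)
  expect_true(all(n0$expression$true_lfc == 0))
  # pooled insert-length histogram peaks at 24 nt, then 21 nt
  adaptor <- "AGATCGGAAGAGCACACGTCT"
  pooled <- do.call(rbind, lapply(sim$libraries, function(l) {
    filter_reads(l, adaptor)$reads
  }))
  h <- length_histogram(pooled)
  ord <- names(sort(h, decreasing = TRUE))
  expect_equal(ord[1], "24")
  expect_equal(ord[2], "21")
})

test_that("degradome tags are 20-21 nt transcript prefixes at decay positions", {
  tx <- generate_transcriptome(12, c(500, 1200), seed = 3)
  truth <- plant_hairpins(tx, n_mirnas = 10, seed = 5)
  dg <- simulate_degradome(truth, site_spike_factor = 50,
                           background_rate = 0.02, seed = 6)
  expect_true(all(nchar(dg$tags$seq) %in% c(20L, 21L)))
  # each tag is an exact substring of some transcript
  blob <- paste(truth$transcripts, collapse = "#")
  expect_true(all(vapply(dg$tags$seq, grepl, TRUE, x = blob, fixed = TRUE)))
  # with zero background, tags exist only at true sites
  d0 <- simulate_degradome(truth, site_spike_factor = 50,
                           background_rate = 0, seed = 6)
  starts_ok <- vapply(d0$tags$seq, function(tg) {
    any(vapply(seq_len(nrow(truth$sites)), function(r) {
      tx_seq <- truth$transcripts[[truth$sites$transcript[r]]]
      substr(tx_seq, truth$sites$site[r],
             truth$sites$site[r] + nchar(tg) - 1L) == tg
    }, logical(1)))
  }, logical(1))
  expect_true(all(starts_ok))
  expect_error(simulate_degradome(truth, site_spike_factor = 1), "> 1")
})

test_that("spiked true sites dominate their transcript profiles", {
  # Monte-Carlo over >= 100 planted sites: the site spike should be the
  # unique transcript maximum nearly always at 50x
  tx <- generate_transcriptome(60, c(500, 1500), seed = 11)
  truth <- plant_hairpins(tx, n_mirnas = 60, seed = 12)
  dg <- simulate_degradome(truth, 50, 0.02, seed = 13)
  prof <- build_profile(dg$tags, truth$transcripts)
  unique_max <- vapply(seq_len(nrow(truth$sites)), function(r) {
    p <- prof[[truth$sites$transcript[r]]]
    s <- truth$sites$site[r]
    p$counts[s] == p$max && length(p$argmax) == 1L
  }, logical(1))
  # sites sharing a transcript with a bigger spike cannot both be maxima;
  # restrict to transcripts hosting a single site
  single <- names(which(table(truth$sites$transcript) == 1L))
  idx <- truth$sites$transcript %in% single
  expect_gte(sum(idx), 20)
  expect_gte(mean(unique_max[idx]), 0.95)
})
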