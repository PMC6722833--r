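mk_reads <- function(seqs, quals = NULL) {
  data.frame(id = sprintf("r%03d", seq_along(seqs)), seq = seqs,
             qual = if (is.null(quals)) NA_character_ else quals,
             stringsAsFactors = FALSE)
}
AD <- "AGATCGGAAGAGCACACGTCT"

test_that("read filtering applies the N / adaptor / quality / length cascade", {
  insert21 <- "TGGAATGTAAAGAAGTATGTA"
  reads <- mk_reads(c(
    paste0(insert21, AD),                      # clean, kept
    paste0("TNGANTGTAAAGAAGTATGNA", AD),       # 3 N in 21 (14.3%) -> N filter
    insert21,                                   # no adaptor
    paste0(substr(insert21, 1, 17), AD),        # trimmed length 17
    paste0(insert21, AD)))                      # duplicate of first
  out <- filter_reads(reads, AD)
  rep <- out$report
  expect_equal(rep$raw, 5L)
  expect_equal(rep$removed_n, 1L)
  expect_equal(rep$removed_no_adaptor, 1L)
  expect_equal(rep$removed_length, 1L)
  expect_equal(rep$clean, 2L)
  # conservation: raw = clean + sum(removed)
  expect_equal(rep$raw, rep$clean + rep$removed_n + rep$removed_no_adaptor +
                 rep$removed_low_quality + rep$removed_length)
  # dedup after trimming
  expect_equal(out$reads$seq, insert21)
  expect_equal(out$reads$count, 2L)
})

test_that("quality filter uses mean Phred of the insert, FASTA skips it", {
  insert <- "TGGAATGTAAAGAAGTATGTA"
  read <- paste0(insert, AD)
  lowq <- paste0(strrep("#", nchar(insert)), strrep("I", nchar(AD))) # Q2 insert
  highq <- strrep("I", nchar(read))
  out <- filter_reads(mk_reads(c(read, read), c(lowq, highq)), AD)
  expect_equal(out$report$removed_low_quality, 1L)
  expect_equal(out$report$clean, 1L)
  # FASTA input (no qualities): quality filter does not fire
  out2 <- filter_reads(mk_reads(read), AD)
  expect_equal(out2$report$removed_low_quality, 0L)
  expect_equal(out2$report$clean, 1L)
})

test_that("filtering already-clean inserts is idempotent", {
  set.seed(42)
  inserts <- replicate(20, random_dna(sample(18:30, 1)))
  reads <- mk_reads(paste0(inserts, AD))
  once <- filter_reads(reads, AD)
  again <- filter_reads(
    data.frame(id = sprintf("c%d", seq_len(nrow(once$reads))),
               seq = paste0(once$reads$seq, AD), qual = NA,
               stringsAsFactors = FALSE), AD)
  expect_setequal(again$reads$seq, once$reads$seq)
  expect_equal(again$report$clean, again$report$raw)
})

test_that("ncRNA classification follows priority order and matches brute force", {
  set.seed(7)
  refs <- list(rRNA = c(a = random_dna(300)), tRNA = c(b = random_dna(80)),
               snRNA = c(c = random_dna(150)), snoRNA = c(d = random_dna(110)),
               `repeat` = c(e = random_dna(200)))
  shared <- substr(refs$rRNA[[1]], 10, 30)
  refs$tRNA <- c(refs$tRNA, x = paste0("AAAA", shared, "TTTT"))
  # read present in both rRNA and tRNA references -> rRNA by priority
  expect_equal(classify_ncrna(shared, refs), "rRNA")
  expect_equal(classify_ncrna("GGGGGGGGGGGGGGGGGGGG", refs), "unannotated")

  # brute-force all-pairs substring scan agreement on a random instance
  reads <- c(
    vapply(1:30, function(i) {
      cls <- sample(names(refs), 1)
      ref <- refs[[cls]][[sample(length(refs[[cls]]), 1)]]
      l <- sample(18:25, 1); s <- sample(nchar(ref) - l, 1)
      substr(ref, s, s + l - 1)
    }, ""),
    vapply(1:20, function(i) random_dna(24), ""))
  got <- classify_ncrna(reads, refs)
  want <- vapply(reads, function(rd) {
    for (cls in c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")) {
      if (any(vapply(refs[[cls]], function(rf) grepl(rd, rf, fixed = TRUE),
                     logical(1)))) return(cls)
    }
    "unannotated"
  }, "", USE.NAMES = FALSE)
  expect_equal(got, want)
})

test_that("length histogram is count-weighted and normalized", {
  r <- data.frame(seq = c("AAAAAAAAAAAAAAAAAAAAA"), count = 5L)
  expect_equal(length_histogram(r), c(`21` = 1.0))
  r2 <- data.frame(seq = c(strrep("A", 21), strrep("C", 24)),
                   count = c(1L, 3L))
  h <- length_histogram(r2)
  expect_equal(sum(h), 1)
  expect_equal(unname(h["24"]), 0.75)
  expect_length(length_histogram(r2[0, ]), 0L)
})
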