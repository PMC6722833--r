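#' @useDynLib eumir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Run code with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA-alphabet sequences
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# RNA <-> DNA alphabet. Internally everything is DNA (T); mature miRNAs are
# reported back to users as RNA (U).
dna2rna <- function(x) chartr("Tt", "Uu", x)
rna2dna <- function(x) chartr("Uu", "Tt", x)

# 1-based inclusive <-> 0-based half-open interval converters. These are the
# only places the coordinate shift happens.
to0 <- function(start1, end1) list(start = start1 - 1L, end = end1)
to1 <- function(start0, end0) list(start = start0 + 1L, end = end0)

# Watson-Crick partner lookup
wc_partner <- c(A = "T", C = "G", G = "C", T = "A")

is_wc_pair <- function(a, b) wc_partner[a] == b

is_gu_pair <- function(a, b) {
  (a == "G" & b == "T") | (a == "T" & b == "G")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
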