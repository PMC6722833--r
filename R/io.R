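#' Read sequences from FASTA or FASTQ
#'
#' Parses a FASTA or FASTQ (Phred+33) file into an ordered sequence
#' collection. Sequences are uppercased and RNA (U) is normalized to the DNA
#' alphabet (T); the original alphabet is recorded so mature miRNAs can be
#' reported back as RNA. Only A/C/G/T/U/N are legal sequence characters.
#'
#' @param path path to an existing FASTA/FASTQ file.
#' @param format one of `"auto"`, `"fasta"`, `"fastq"`. `"auto"` decides from
#'   the file extension (`.fq`/`.fastq` => FASTQ).
#' @return a data.frame of class `seq_collection` with columns `id`, `seq`
#'   (uppercase DNA alphabet), `qual` (NA for FASTA), and attribute
#'   `alphabet` (`"DNA"` or `"RNA"`, from the input as seen).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (file.size(path) == 0L || all(!nzchar(trimws(readLines(path, n = 5L))))) {
    warning("empty sequence file: ", path)
    return(seq_collection(character(), character(), character()))
  }
  if (format == "fastq") {
    ss <- Biostrings::readBStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(ss)$qualities)
  } else {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(ss))
  }
  seqs <- toupper(as.character(ss))
  bad <- grep("[^ACGTUN]", seqs)
  if (length(bad)) {
    i <- bad[1L]
    ch <- regmatches(seqs[i], regexpr("[^ACGTUN]", seqs[i]))
    line <- locate_bad_line(path, format, i)
    stop(sprintf(
      "illegal character '%s' in sequence of record %d ('%s')%s in %s",
      ch, i, names(ss)[i],
      if (is.na(line)) "" else sprintf(" (line %d)", line), path))
  }
  alphabet <- if (any(grepl("U", seqs, fixed = TRUE))) "RNA" else "DNA"
  out <- seq_collection(names(ss), rna2dna(seqs), qual)
  attr(out, "alphabet") <- alphabet
  out
}

# Best-effort line number of the offending sequence record, for error text.
locate_bad_line <- function(path, format, rec) {
  lines <- readLines(path, warn = FALSE)
  if (format == "fastq") return(4L * (rec - 1L) + 2L)
  hdr <- grep("^>", lines)
  if (rec > length(hdr)) return(NA_integer_)
  from <- hdr[rec] + 1L
  to <- if (rec < length(hdr)) hdr[rec + 1L] - 1L else length(lines)
  bad <- grep("[^ACGTUNacgtun[:space:]]", lines[from:to])
  if (length(bad)) from + bad[1L] - 1L else NA_integer_
}

seq_collection <- function(id, seq, qual = rep(NA_character_, length(id))) {
  # first token of the header is the id, matching FASTA convention
  id <- sub("\\s.*$", "", id)
  out <- data.frame(id = id, seq = seq, qual = qual,
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_collection", "data.frame")
  out
}

#' @export
print.seq_collection <- function(x, ...) {
  cat(sprintf("<seq_collection> %d records\n", nrow(x)))
  if (nrow(x)) {
    show <- utils::head(x, 6L)
    cat(sprintf("  %s  %s\n", format(show$id, width = 20L),
                substr(show$seq, 1L, 40L)), sep = "")
    if (nrow(x) > 6L) cat(sprintf("  ... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x a `seq_collection` (or data.frame with `id`, `seq`, optional
#'   `qual`).
#' @param path output path.
#' @param format `"fasta"` or `"fastq"`; FASTQ requires qualities.
#' @param as_rna write sequences in the RNA alphabet (T -> U).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("fasta", "fastq"),
                            as_rna = FALSE) {
  format <- match.arg(format)
  seqs <- if (as_rna) dna2rna(x$seq) else x$seq
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- x$id
  if (format == "fastq") {
    qual <- x$qual
    if (is.null(qual) || anyNA(qual)) {
      qual <- strrep("I", nchar(seqs))
    }
    Biostrings::writeXStringSet(
      ss, path, format = "fastq",
      qualities = Biostrings::BStringSet(qual))
  } else {
    Biostrings::writeXStringSet(ss, path, format = "fasta")
  }
  invisible(path)
}

#' Write a regulatory network as node and edge TSV tables
#'
#' Serializes miRNA-target regulatory edges (see [build_network()]) into two
#' TSV files: a node table (`id`, `type`, `direction`) and an edge table
#' (`miRNA`, `target`, `regulation`), both deterministically sorted.
#'
#' @param edges data.frame with columns `mirna`, `target`,
#'   `mirna_direction`, `target_direction`, `regulation`.
#' @param nodes_path,edges_path output TSV paths.
#' @return invisibly, a list with the two written data.frames.
#' @export
write_network <- function(edges, nodes_path, edges_path) {
  required <- c("mirna", "target", "mirna_direction", "target_direction",
                "regulation")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols)) {
    stop("edge table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(edges)) {
    mir_dir <- tapply(edges$mirna_direction, edges$mirna, unique)
    tgt_dir <- tapply(edges$target_direction, edges$target, unique)
    if (any(lengths(mir_dir) > 1L) || any(lengths(tgt_dir) > 1L)) {
      stop("conflicting direction labels for a node")
    }
    nodes <- rbind(
      data.frame(id = names(mir_dir), type = "miRNA",
                 direction = unlist(mir_dir), stringsAsFactors = FALSE),
      data.frame(id = names(tgt_dir), type = "target",
                 direction = unlist(tgt_dir), stringsAsFactors = FALSE))
    nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
    etab <- data.frame(miRNA = edges$mirna, target = edges$target,
                       regulation = edges$regulation,
                       stringsAsFactors = FALSE)
    etab <- etab[order(etab$miRNA, etab$target), , drop = FALSE]
    known <- nodes$id
    dangling <- setdiff(c(etab$miRNA, etab$target), known)
    if (length(dangling)) {
      stop("edges reference unknown node ids: ",
           paste(dangling, collapse = ", "))
    }
  } else {
    nodes <- data.frame(id = character(), type = character(),
                        direction = character(), stringsAsFactors = FALSE)
    etab <- data.frame(miRNA = character(), target = character(),
                       regulation = character(), stringsAsFactors = FALSE)
  }
  write_tsv(nodes, nodes_path)
  write_tsv(etab, edges_path)
  invisible(list(nodes = nodes, edges = etab))
}

#' Read / write TSV tables
#'
#' TSV with a header row is the single tabular dialect used throughout.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv` returns a data.frame; `write_tsv` returns `path`
#'   invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a feature-by-sample count table (features in column 1)
#' @param path TSV path: first column feature ids, remaining columns samples.
#' @return integer matrix with feature rownames.
#' @export
read_count_table <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_count_table
#' @param counts matrix of counts with rownames.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a term-to-gene annotation map
#'
#' @param path two-column TSV: `gene <tab> term`.
#' @return named list: term -> character vector of gene ids.
#' @export
read_annotation_map <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) stop("annotation map needs two columns (gene, term)")
  split(df[[1]], df[[2]])
}
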