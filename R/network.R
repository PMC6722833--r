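#' Build the DEM-DEG regulatory network
#'
#' Joins differentially expressed miRNAs (DEMs), differentially expressed
#' target genes (DEGs) and miRNA-target links into signed regulatory
#' edges: one edge per (DEM, DEG) pair present in the links, labelled
#' `anti` when the two directions differ (the canonical
#' cleavage-repression signature) and `positive` when they agree.
#'
#' @param dem_results `expression_results` (or data.frame with `feature`,
#'   `log2FC`, `call`) for miRNAs.
#' @param deg_results same for genes/transcripts.
#' @param links data.frame with columns `mirna`, `target` (predicted or
#'   degradome-validated pairs); an optional `evidence` column is carried
#'   through.
#' @return data.frame of class `regulatory_edges`: `mirna`, `target`,
#'   `evidence`, `mirna_direction`, `target_direction`, `regulation`;
#'   deterministically sorted by (mirna, target).
#' @export
build_network <- function(dem_results, deg_results, links) {
  dem <- dem_results[dem_results$call %in% c("up", "down"), , drop = FALSE]
  deg <- deg_results[deg_results$call %in% c("up", "down"), , drop = FALSE]
  keep <- links$mirna %in% dem$feature & links$target %in% deg$feature
  lk <- links[keep, , drop = FALSE]
  lk <- lk[!duplicated(lk[, c("mirna", "target")]), , drop = FALSE]
  mdir <- dem$call[match(lk$mirna, dem$feature)]
  tdir <- deg$call[match(lk$target, deg$feature)]
  out <- data.frame(
    mirna = lk$mirna, target = lk$target,
    evidence = if ("evidence" %in% names(lk)) lk$evidence
               else rep("predicted", nrow(lk)),
    mirna_direction = mdir, target_direction = tdir,
    regulation = ifelse(mdir == tdir, "positive", "anti"),
    stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("regulatory_edges", "data.frame")
  out
}

#' @export
print.regulatory_edges <- function(x, ...) {
  cat(sprintf(
    "<regulatory_edges> %d pairs (%d anti, %d positive), %d miRNAs, %d targets\n",
    nrow(x), sum(x$regulation == "anti"), sum(x$regulation == "positive"),
    length(unique(x$mirna)), length(unique(x$target))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 8L))
  invisible(x)
}

#' Hypergeometric term enrichment
#'
#' For each term, tests over-representation of the sample gene set among
#' the term's annotated genes with the exact upper hypergeometric tail
#' `p = P(X >= k)`, `X ~ Hypergeometric(N, K, n)` (population size N, K
#' annotated, sample size n, k annotated in the sample), then adjusts
#' across terms.
#'
#' @param sample character vector of gene ids (must be a subset of
#'   `population`).
#' @param term_map named list: term -> character vector of annotated gene
#'   ids.
#' @param population character vector of background gene ids; defaults to
#'   the union of all annotated genes.
#' @param alpha significance threshold on the adjusted p-value.
#' @param adjust `"BH"` or `"bonferroni"`.
#' @return data.frame: `term`, `N`, `K`, `n`, `k`, `pvalue`, `padj`,
#'   `significant`; sorted by `pvalue` then term.
#' @export
hypergeom_enrich <- function(sample, term_map, population = NULL,
                             alpha = 0.05, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (is.null(population)) population <- unique(unlist(term_map))
  population <- unique(population)
  sample <- unique(sample)
  if (!all(sample %in% population)) {
    stop("sample contains genes outside the population")
  }
  N <- length(population)
  n <- length(sample)
  rows <- lapply(sort(names(term_map)), function(term) {
    genes <- intersect(unique(term_map[[term]]), population)
    K <- length(genes)
    if (K == 0L) {
      warning("term ", term, " annotates no population gene; skipped")
      return(NULL)
    }
    k <- length(intersect(sample, genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, N = N, K = K, n = n, k = k, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), pvalue = numeric(),
                      padj = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  out$padj <- stats::p.adjust(out$pvalue,
                              method = ifelse(adjust == "BH", "BH",
                                              "bonferroni"))
  out$significant <- out$padj < alpha
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse a pathway target table
#'
#' Reads a three-column table (`target id`, semicolon-separated miRNA
#' list, annotation) of the kind used to report pathway-annotated
#' miRNA targets, and returns exact unique counts plus the expanded
#' (miRNA, target) pair list. Entries are whitespace-trimmed and
#' deduplicated case-sensitively; the result is independent of row order
#' and idempotent.
#'
#' @param x a data.frame with >= 3 columns, or a TSV path.
#' @return list: `n_targets` (unique target ids), `n_mirnas` (unique
#'   miRNA ids), `pairs` (data.frame `mirna`, `target`, sorted,
#'   deduplicated).
#' @export
parse_pathway_table <- function(x) {
  df <- if (is.character(x) && length(x) == 1L) read_tsv(x) else x
  if (ncol(df) < 3L) stop("pathway table needs 3 columns")
  bad <- which(is.na(df[[1]]) | !nzchar(trimws(df[[1]])) |
                 is.na(df[[2]]) | !nzchar(trimws(df[[2]])))
  if (length(bad)) stop("malformed pathway table row ", bad[1L])
  targets <- trimws(df[[1]])
  mlists <- strsplit(as.character(df[[2]]), ";", fixed = TRUE)
  pairs <- do.call(rbind, lapply(seq_along(targets), function(i) {
    m <- trimws(mlists[[i]])
    m <- m[nzchar(m)]
    if (!length(m)) stop("malformed pathway table row ", i, ": no miRNA")
    data.frame(mirna = m, target = targets[i], stringsAsFactors = FALSE)
  }))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs$mirna, pairs$target), , drop = FALSE]
  rownames(pairs) <- NULL
  list(n_targets = length(unique(targets)),
       n_mirnas = length(unique(pairs$mirna)),
       pairs = pairs)
}

#' Expression scatter data for miRNA-target pairs
#'
#' One point per regulatory edge: x = miRNA log2 fold change, y = target
#' log2 fold change. Quadrants II/IV correspond to anti-regulation,
#' I/III to positive regulation.
#'
#' @param dem_results,deg_results `expression_results` for miRNAs/genes.
#' @param edges a `regulatory_edges` data.frame.
#' @return data.frame: `mirna`, `target`, `x`, `y`, `regulation`.
#' @export
correlation_scatter_data <- function(dem_results, deg_results, edges) {
  x <- dem_results$log2FC[match(edges$mirna, dem_results$feature)]
  y <- deg_results$log2FC[match(edges$target, deg_results$feature)]
  if (anyNA(x) || anyNA(y)) stop("edge references feature without DE result")
  data.frame(mirna = edges$mirna, target = edges$target, x = x, y = y,
             regulation = edges$regulation, stringsAsFactors = FALSE)
}

#' Recompute headline catalogue totals from their components
#'
#' Small reporting helpers that derive dataset-level totals from their
#' printed components instead of restating them: total miRNA count from
#' the known (primary + secondary reference set) and novel counts,
#' degradome pair totals from the known/novel split, and network pair
#' totals from the anti/positive split of a built network.
#'
#' @param family_sizes named integer vector of family member counts.
#' @return `family_total`: the summed member count.
#' @export
family_total <- function(family_sizes) sum(family_sizes)

#' @rdname family_total
#' @param n_known_primary,n_known_secondary,n_novel component counts.
#' @export
catalog_total <- function(n_known_primary, n_known_secondary, n_novel) {
  n_known_primary + n_known_secondary + n_novel
}

#' @rdname family_total
#' @param n_known_pairs,n_novel_pairs degradome pair counts by miRNA status.
#' @export
pair_total <- function(n_known_pairs, n_novel_pairs) {
  n_known_pairs + n_novel_pairs
}

#' @rdname family_total
#' @param edges a `regulatory_edges` data.frame.
#' @return `network_totals`: named vector `anti`, `positive`, `total`.
#' @export
network_totals <- function(edges) {
  anti <- sum(edges$regulation == "anti")
  pos <- sum(edges$regulation == "positive")
  c(anti = anti, positive = pos, total = anti + pos)
}
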