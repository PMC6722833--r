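#' Transcripts-per-million normalization for small RNAs
#'
#' `TPM = mapped read count / total reads x 10^6`, the standard abundance
#' unit for length-homogeneous small-RNA counts.
#'
#' @param mapped_count mapped read count(s) for the feature.
#' @param total_reads library total (> 0).
#' @return TPM value(s).
#' @export
tpm <- function(mapped_count, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be > 0")
  if (any(mapped_count < 0) || any(mapped_count > total_reads)) {
    stop("mapped_count must be in [0, total_reads]")
  }
  mapped_count / total_reads * 1e6
}

#' Median-of-ratios size factors
#'
#' For each sample, the median across features of the ratio of its count to
#' the geometric mean of that feature's counts over all samples (features
#' with a zero anywhere are excluded from the reference, as usual).
#'
#' @param counts non-negative integer matrix, features x samples.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) return(rep(1, ncol(counts)))
  sf <- apply(counts[use, , drop = FALSE], 2L, function(cnt) {
    exp(stats::median(log(cnt) - log_geo[use]))
  })
  # normalize to geometric mean 1 so a c-fold depth change in one sample
  # moves only that sample's factor (by c) and no other
  sf / exp(mean(log(sf)))
}

#' Negative-binomial differential expression between two conditions
#'
#' Per feature: counts are normalized by median-of-ratios size factors;
#' log2 fold change is computed as
#' `log2((mean_HR + pc) / (mean_LR + pc))` on normalized counts
#' (pseudocount `pc = 0.5` avoids infinite fold changes at zeros); a
#' negative-binomial Wald test of the condition effect is run with a
#' per-feature method-of-moments dispersion estimate
#' (`variance = mu + alpha mu^2`) floored at `dispersion_floor`; p-values
#' are Benjamini-Hochberg adjusted across all tested features. A feature is
#' called `up` when `log2FC >= lfc_threshold` and `FDR <= fdr_threshold`,
#' `down` for the mirror case, otherwise `ns`. The second condition level
#' given in `condition` order (`HR` by default usage) is the numerator.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param condition factor/character of length `ncol(counts)` with exactly
#'   two levels; the **second** level is the numerator of the fold change.
#' @param lfc_threshold,fdr_threshold differential-call thresholds.
#' @param dispersion_floor lower bound on the dispersion alpha.
#' @param pseudocount added to condition means for the fold change.
#' @param total_reads optional per-sample library totals for TPM columns
#'   (defaults to column sums of `counts`).
#' @return data.frame of class `expression_results`: `feature`, per-sample
#'   normalized counts and TPM are in attributes `normalized` and `tpm`;
#'   columns `baseMean_<ref>`, `baseMean_<num>`, `log2FC`, `pvalue`, `fdr`,
#'   `call`.
#' @export
differential_expression <- function(counts, condition,
                                    lfc_threshold = 1,
                                    fdr_threshold = 0.05,
                                    dispersion_floor = 0.01,
                                    pseudocount = 0.5,
                                    total_reads = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  condition <- if (is.factor(condition)) droplevels(condition)
               else factor(condition, levels = unique(condition))
  if (nlevels(condition) != 2L) stop("exactly two condition levels required")
  if (min(table(condition)) < 2L) stop("need >= 2 replicates per condition")
  lev <- levels(condition)
  ref <- lev[1L]; num <- lev[2L]

  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  if (is.null(total_reads)) total_reads <- colSums(counts)
  tpm_mat <- sweep(counts, 2L, total_reads, "/") * 1e6

  i_ref <- condition == ref
  i_num <- condition == num
  mean_ref <- rowMeans(norm[, i_ref, drop = FALSE])
  mean_num <- rowMeans(norm[, i_num, drop = FALSE])
  log2fc <- log2((mean_num + pseudocount) / (mean_ref + pseudocount))

  # method-of-moments dispersion on normalized counts, pooled over the two
  # conditions. Per-feature moment estimates from a handful of replicates
  # are noisy downward, which inflates Wald statistics, so each feature's
  # dispersion is additionally floored at the across-feature median (a
  # feature cannot claim less overdispersion than the typical feature)
  # and at the absolute floor.
  var_ref <- apply(norm[, i_ref, drop = FALSE], 1L, stats::var)
  var_num <- apply(norm[, i_num, drop = FALSE], 1L, stats::var)
  alpha_of <- function(m, v) ifelse(m > 0, (v - m) / m^2, NA_real_)
  alpha <- rowMeans(cbind(alpha_of(mean_ref, var_ref),
                          alpha_of(mean_num, var_num)), na.rm = TRUE)
  alpha_central <- stats::median(alpha[is.finite(alpha) & alpha > 0])
  if (!is.finite(alpha_central)) alpha_central <- dispersion_floor
  alpha[!is.finite(alpha)] <- alpha_central
  alpha <- pmax(alpha, alpha_central, dispersion_floor)

  off <- log(sf)
  pvals <- vapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    if (all(y == 0)) return(1)
    fit <- tryCatch(
      suppressWarnings(stats::glm(
        y ~ condition + offset(off),
        family = MASS::negative.binomial(theta = 1 / alpha[i]))),
      error = function(e) NULL)
    if (is.null(fit)) return(1)
    # dispersion = 1: the NB variance is already in the family; the
    # default summary would rescale SEs by a Pearson quasi-dispersion
    cf <- stats::coef(summary(fit, dispersion = 1))
    if (nrow(cf) < 2L || !is.finite(cf[2L, 3L])) return(1)
    2 * stats::pnorm(-abs(cf[2L, 3L]))
  }, numeric(1))
  all_zero <- rowSums(counts) == 0
  log2fc[all_zero] <- 0
  pvals[all_zero] <- 1

  fdr <- stats::p.adjust(pvals, method = "BH")
  call <- rep("ns", nrow(counts))
  call[log2fc >= lfc_threshold & fdr <= fdr_threshold] <- "up"
  call[log2fc <= -lfc_threshold & fdr <= fdr_threshold] <- "down"

  out <- data.frame(
    feature = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    stringsAsFactors = FALSE)
  out[[paste0("baseMean_", ref)]] <- mean_ref
  out[[paste0("baseMean_", num)]] <- mean_num
  out$log2FC <- log2fc
  out$pvalue <- pvals
  out$fdr <- fdr
  out$call <- call
  attr(out, "normalized") <- norm
  attr(out, "tpm") <- tpm_mat
  attr(out, "size_factors") <- sf
  attr(out, "levels") <- c(reference = ref, numerator = num)
  class(out) <- c("expression_results", "data.frame")
  out
}

#' @export
print.expression_results <- function(x, ...) {
  lv <- attr(x, "levels")
  cat(sprintf("<expression_results> %d features (%s vs %s): %d up, %d down\n",
              nrow(x), lv["numerator"], lv["reference"],
              sum(x$call == "up"), sum(x$call == "down")))
  print.data.frame(utils::head(as.data.frame(x), 8L))
  invisible(x)
}

#' Row-wise Z-score normalization
#'
#' `(x - row mean) / row sd` with the n-1 denominator; constant rows map to
#' all zeros. Used to prepare expression matrices for heatmap display.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need >= 2 samples per row")
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}
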