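#' Flag first-percentile outlier SNPs
#'
#' Flags the ceiling(quantile * M) SNPs with the smallest association
#' p-values out of M scored SNPs. Ties at the cutoff are broken by smaller
#' p-value and then by `snp_id` order, so exactly ceiling(quantile * M)
#' SNPs are flagged.
#'
#' @param assoc a `snp_association` table (needs `snp_id` and `p`).
#' @param quantile outlier fraction, default 0.01 (first percentile).
#' @return logical vector named by snp_id, in the input row order.
#' @export
flag_outlier_snps <- function(assoc, quantile = 0.01) {
  m <- nrow(assoc)
  if (m == 0) stop("empty association table")
  n_flag <- ceiling(quantile * m)
  o <- order(assoc$p, assoc$snp_id)
  flags <- logical(m)
  flags[o[seq_len(n_flag)]] <- TRUE
  stats::setNames(flags, assoc$snp_id)
}

# per-bin counts of scored SNPs and flagged outliers
.bin_counts <- function(bins, flags) {
  map <- bins$snp_map
  idx <- match(map$snp_id, names(flags))
  scored <- !is.na(idx)
  tot <- table(map$bin_id[scored])
  out <- table(map$bin_id[scored][flags[idx[scored]]])
  ids <- names(tot)
  data.frame(bin_id = ids, n_snps = as.integer(tot),
             n_outliers = as.integer(ifelse(is.na(match(ids, names(out))),
                                            0L, out[ids])))
}

#' Expected per-gene outlier rate
#'
#' The expected proportion of outlier SNPs per bin, computed as the mean of
#' n_outliers / n_snps over eligible bins: those with at least five scored
#' SNPs and at least one outlier.
#'
#' @param bins a `gene_bins` object from [assign_bins()].
#' @param flags named logical outlier flags from [flag_outlier_snps()].
#' @param min_snps,min_outliers eligibility thresholds (defaults 5 and 1).
#' @return scalar expected rate p-bar.
#' @export
expected_outlier_rate <- function(bins, flags, min_snps = 5, min_outliers = 1) {
  ct <- .bin_counts(bins, flags)
  el <- ct$n_snps >= min_snps & ct$n_outliers >= min_outliers
  if (!any(el))
    stop("no eligible bins (>= ", min_snps, " SNPs and >= ", min_outliers,
         " outlier); fall back to the global outlier fraction if appropriate")
  mean(ct$n_outliers[el] / ct$n_snps[el])
}

#' Binomial candidate threshold
#'
#' Smallest integer t such that the cumulative Binomial(n_snps, p_bar)
#' probability P(X <= t) is at least `q`. A bin is a top candidate only if
#' its outlier count strictly exceeds this threshold.
#'
#' @param n_snps number of scored SNPs in the bin.
#' @param p_bar expected outlier rate from [expected_outlier_rate()].
#' @param q binomial quantile, default 0.999.
#' @return integer threshold (vectorized over `n_snps`).
#' @export
binomial_threshold <- function(n_snps, p_bar, q = 0.999) {
  stopifnot(p_bar >= 0, p_bar <= 1)
  as.integer(stats::qbinom(q, n_snps, p_bar))
}

#' Gene-based top-candidate scan
#'
#' For every bin: the number of scored SNPs, the number of outlier SNPs,
#' the binomial 0.999-quantile threshold, the upper-tail binomial gene
#' p-value P(X >= n_outliers) (1 when n_outliers = 0), and the candidate
#' flag (n_outliers strictly above the threshold).
#'
#' @inheritParams expected_outlier_rate
#' @param p_bar expected outlier rate, typically from
#'   [expected_outlier_rate()].
#' @param q binomial quantile for the candidate rule, default 0.999.
#' @return data.frame of class `gene_scan_result`: `bin_id`, `kind`,
#'   `n_snps`, `n_outliers`, `threshold`, `gene_p`, `candidate`.
#' @export
scan_genes <- function(bins, flags, p_bar, q = 0.999) {
  ct <- .bin_counts(bins, flags)
  ct$threshold <- binomial_threshold(ct$n_snps, p_bar, q)
  ct$gene_p <- ifelse(ct$n_outliers == 0, 1,
                      stats::pbinom(ct$n_outliers - 1, ct$n_snps, p_bar,
                                    lower.tail = FALSE))
  ct$candidate <- ct$n_outliers > ct$threshold
  ct <- merge(ct, bins$bins[, c("bin_id", "kind")], by = "bin_id", sort = FALSE)
  ct <- ct[, c("bin_id", "kind", "n_snps", "n_outliers", "threshold",
               "gene_p", "candidate")]
  class(ct) <- c("gene_scan_result", "data.frame")
  ct
}

#' Run a full top-candidate scan from an association table
#'
#' Convenience wrapper: flag first-percentile outliers, estimate the
#' expected rate, and scan all bins.
#'
#' @inheritParams expected_outlier_rate
#' @param assoc a `snp_association` table.
#' @param quantile outlier fraction for [flag_outlier_snps()].
#' @param q binomial quantile for [scan_genes()].
#' @return a `gene_scan_result` (see [scan_genes()]); attribute `p_bar`
#'   holds the expected rate used.
#' @export
top_candidate_scan <- function(bins, assoc, quantile = 0.01, q = 0.999) {
  flags <- flag_outlier_snps(assoc, quantile)
  p_bar <- expected_outlier_rate(bins, flags)
  res <- scan_genes(bins, flags, p_bar, q)
  attr(res, "p_bar") <- p_bar
  res
}
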