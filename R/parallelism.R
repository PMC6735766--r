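#' Build the control SNP panel for the null-W test
#'
#' Seeded uniform sample (without replacement) of SNP ids drawn from bins
#' that were not flagged as top candidates. If fewer than `size`
#' noncandidate SNPs exist, all are returned with a warning.
#'
#' @param bins a `gene_bins` object.
#' @param assoc association table whose SNPs are eligible (only scored SNPs
#'   enter the panel).
#' @param candidate_ids bin ids flagged as candidates (excluded).
#' @param size panel size, default 10000.
#' @param seed integer seed.
#' @param score score column used to decide which SNPs carry a usable score
#'   (SNPs with missing scores, e.g. monomorphic in the analysed subset,
#'   are ineligible).
#' @return character vector of SNP ids.
#' @export
build_control_panel <- function(bins, assoc, candidate_ids, size = 10000,
                                seed = 1, score = "r2") {
  map <- bins$snp_map
  scored <- assoc$snp_id[is.finite(assoc[[score]])]
  pool <- map$snp_id[!(map$bin_id %in% candidate_ids) &
                       map$snp_id %in% scored]
  if (length(pool) == 0) stop("no noncandidate SNPs available")
  if (length(pool) < size) {
    warning("only ", length(pool), " noncandidate SNPs available; using all")
    return(pool)
  }
  withr::with_seed(seed, sample(pool, size))
}

#' Rank-sum W and Z for one gene against a control panel
#'
#' W is the two-sample Mann-Whitney U counting pairs where the gene score
#' exceeds a control score, with half credit for ties (midranks).
#' Z = (2W - n1 n2) / sqrt(n1 n2 (n1 + n2 + 1) / 3), where n1 is the control
#' panel size and n2 the gene's SNP count; positive Z means the gene's
#' scores are stochastically larger than the panel's.
#'
#' @param gene_scores association scores (e.g. r2) of the gene's SNPs.
#' @param control_scores scores of the control panel.
#' @return named numeric `c(W, Z, n1, n2)`.
#' @export
rank_sum_z <- function(gene_scores, control_scores) {
  n2 <- length(gene_scores); n1 <- length(control_scores)
  if (n1 == 0 || n2 == 0) stop("empty score list")
  r <- rank(c(control_scores, gene_scores))
  W <- sum(r[n1 + seq_len(n2)]) - n2 * (n2 + 1) / 2
  Z <- (2 * W - n1 * n2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 3)
  c(W = W, Z = Z, n1 = n1, n2 = n2)
}

# W of gene scores vs a sorted control vector, excluding the `excl` values
# (already known to be in the control); exact midrank handling.
.w_vs_sorted <- function(gene_scores, sorted_panel, excl = numeric(0)) {
  le <- findInterval(gene_scores, sorted_panel)
  lt <- findInterval(gene_scores, sorted_panel, left.open = TRUE)
  W <- sum(lt) + 0.5 * sum(le - lt)
  if (length(excl)) {
    W <- W - sum(outer(gene_scores, excl, ">")) -
      0.5 * sum(outer(gene_scores, excl, "=="))
  }
  W
}

#' Null distribution of Z scores from noncandidate bins
#'
#' One rank-sum Z per noncandidate bin, comparing the bin's SNP scores with
#' the control panel. A bin's own SNPs are excluded from the panel side of
#' its test so a bin never competes against itself. Bins with no scored
#' SNPs are skipped (count reported in attribute `n_skipped`).
#'
#' @param bins a `gene_bins` object.
#' @param assoc association table supplying the per-SNP scores.
#' @param panel control SNP ids from [build_control_panel()].
#' @param candidate_ids bin ids to exclude (the candidates).
#' @param score column of `assoc` used as the score, default `"r2"`.
#' @return data.frame `bin_id`, `n1`, `n2`, `W`, `Z`.
#' @export
null_z_distribution <- function(bins, assoc, panel, candidate_ids,
                                score = "r2") {
  assoc <- assoc[is.finite(assoc[[score]]), , drop = FALSE]
  sc <- stats::setNames(assoc[[score]], assoc$snp_id)
  map <- bins$snp_map[bins$snp_map$snp_id %in% assoc$snp_id, , drop = FALSE]
  nonc <- map[!(map$bin_id %in% candidate_ids), , drop = FALSE]
  if (nrow(nonc) == 0) stop("no noncandidate bins with scored SNPs")
  in_panel <- stats::setNames(map$snp_id %in% panel, map$snp_id)
  sp <- sort(unname(sc[panel]))
  n1_full <- length(panel)
  by_bin <- split(nonc$snp_id, nonc$bin_id)
  res <- lapply(names(by_bin), function(b) {
    ids <- by_bin[[b]]
    g <- unname(sc[ids])
    ex <- unname(sc[ids[in_panel[ids]]])
    n1 <- n1_full - length(ex)
    if (n1 == 0) return(NULL)
    W <- .w_vs_sorted(g, sp, ex)
    n2 <- length(g)
    Z <- (2 * W - n1 * n2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 3)
    data.frame(bin_id = b, n1 = n1, n2 = n2, W = W, Z = Z)
  })
  out <- do.call(rbind, res)
  attr(out, "n_skipped") <- length(setdiff(unique(bins$snp_map$bin_id),
                                           c(unique(map$bin_id))))
  out
}

#' Null-W test of parallel adaptation
#'
#' Tests whether candidate genes from one transect also show elevated
#' association scores in the other transect. Each candidate gene's Z (its
#' SNP scores in transect B against transect B's control panel) is referred
#' to the empirical null distribution of Z from transect B's noncandidate
#' bins: p = #(null Z > observed Z) / #null, floored at 1 / #null. P-values
#' are Benjamini-Hochberg adjusted across the tested candidates; genes with
#' q <= `alpha` are parallel outliers.
#'
#' @param candidate_ids bin ids of the candidates found in transect A.
#' @param bins transect B's `gene_bins`.
#' @param assoc_b transect B's association table.
#' @param panel_b transect B's control panel SNP ids.
#' @param null_z data.frame from [null_z_distribution()] on transect B.
#' @param alpha FDR level, default 0.05.
#' @param score score column, default `"r2"`.
#' @return data.frame of class `nullw_result`: `gene_id`, `n1`, `n2`, `W`,
#'   `Z`, `p`, `q`, `parallel`; candidates without scored SNPs in B are
#'   skipped (attribute `n_skipped`).
#' @export
nullw_test <- function(candidate_ids, bins, assoc_b, panel_b, null_z,
                       alpha = 0.05, score = "r2") {
  if (is.null(null_z) || nrow(null_z) == 0) stop("empty null distribution")
  assoc_b <- assoc_b[is.finite(assoc_b[[score]]), , drop = FALSE]
  sc <- stats::setNames(assoc_b[[score]], assoc_b$snp_id)
  map <- bins$snp_map[bins$snp_map$snp_id %in% assoc_b$snp_id, , drop = FALSE]
  sp <- sort(unname(sc[panel_b]))
  n1_full <- length(panel_b)
  in_panel <- stats::setNames(map$snp_id %in% panel_b, map$snp_id)
  n_null <- nrow(null_z)
  rows <- lapply(candidate_ids, function(b) {
    ids <- map$snp_id[map$bin_id == b]
    if (length(ids) == 0) return(NULL)
    g <- unname(sc[ids])
    ex <- unname(sc[ids[in_panel[ids]]])
    n1 <- n1_full - length(ex)
    if (n1 == 0) return(NULL)
    W <- .w_vs_sorted(g, sp, ex)
    n2 <- length(g)
    Z <- (2 * W - n1 * n2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 3)
    p <- max(sum(null_z$Z > Z) / n_null, 1 / n_null)
    data.frame(gene_id = b, n1 = n1, n2 = n2, W = W, Z = Z, p = p)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no candidate gene has scored SNPs in transect B")
  out$q <- bh_adjust(out$p)
  out$parallel <- out$q <= alpha
  attr(out, "n_skipped") <- skipped
  class(out) <- c("nullw_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; q-values are returned in the input order.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) stats::p.adjust(p_values, method = "BH")

#' Hypergeometric test of candidate-set overlap
#'
#' Upper-tail probability of observing at least `k` genes in common between
#' a set of `K` and a set of `n` candidates drawn from a universe of `N`
#' bins: p = P(X >= k), X ~ Hypergeometric(N, K, n).
#'
#' @param N universe size (number of bins).
#' @param K size of the first candidate set.
#' @param n size of the second candidate set.
#' @param k observed overlap.
#' @return list of class `overlap_test`: `N`, `K`, `n`, `k`, `p`.
#' @export
hypergeom_overlap <- function(N, K, n, k) {
  if (k > min(K, n) || K > N || n > N || any(c(N, K, n, k) < 0))
    stop("inconsistent counts: need k <= min(K, n) <= N")
  p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, k = k, p = p), class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap: %d of (%d, %d) sets in universe %d; P(X >= k) = %.3g\n",
              x$k, x$K, x$n, x$N, x$p))
  invisible(x)
}
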