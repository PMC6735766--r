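# small fixtures built in code, shared across test files

# a tiny deterministic variant table
toy_vt <- function(n = 20, m = 12, seed = 42, chrom = NULL) {
  d <- withr::with_seed(seed,
    matrix(sample(0:2, n * m, replace = TRUE), n, m,
           dimnames = list(sprintf("s%02d", 1:n), sprintf("snp%03d", 1:m))))
  if (is.null(chrom)) chrom <- rep("chr1", m)
  variant_table(d, chrom, seq(1000, by = 1000, length.out = m))
}

# a quick small simulated study for integration-flavoured unit tests
small_study <- function(seed = 11, ...) {
  simulate_study(sim_config(n_genes = 60, snps_per_gene = 8,
                            n_intergenic_snps = 120,
                            n_causal_genes_lat = 5, n_causal_genes_alt = 5,
                            n_causal_shared = 2, causal_snps_per_gene = 5,
                            seed = seed, ...))
}

# a gene_bins object built directly from a bin_id -> snp count spec
fake_bins <- function(counts) {
  ids <- names(counts)
  snp_map <- data.frame(
    snp_id = unlist(lapply(ids, function(b)
      sprintf("%s_snp%03d", b, seq_len(counts[[b]])))),
    bin_id = rep(ids, unlist(counts)))
  structure(list(bins = data.frame(bin_id = ids, kind = "genic",
                                   chrom = "chr1", start = 1, end = 2,
                                   n_snps = unlist(counts)),
                 snp_map = snp_map), class = "gene_bins")
}

flags_for <- function(bins, n_out) {
  # flag the first n_out[i] SNPs of bin i
  f <- logical(nrow(bins$snp_map))
  names(f) <- bins$snp_map$snp_id
  for (b in names(n_out)) {
    ids <- bins$snp_map$snp_id[bins$snp_map$bin_id == b]
    if (n_out[[b]] > 0) f[ids[seq_len(n_out[[b]])]] <- TRUE
  }
  f
}

# brute-force all-pairs rank-sum oracle (reference implementation)
brute_rank_sum <- function(gene, control) {
  W <- sum(outer(gene, control, ">")) + 0.5 * sum(outer(gene, control, "=="))
  n1 <- length(control); n2 <- length(gene)
  Z <- (2 * W - n1 * n2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 3)
  c(W = W, Z = Z)
}

# exact binomial upper tail by direct summation
brute_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(x) choose(n, x) * p^x * (1 - p)^(n - x), numeric(1)))
}

# exact hypergeometric upper tail by enumeration
brute_hyper_upper <- function(N, K, n, k) {
  if (k <= 0) return(1)
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
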