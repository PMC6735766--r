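test_that("rank-sum W and Z reproduce hand and brute-force values", {
  r <- rank_sum_z(c(0.25, 0.35), c(0.1, 0.2, 0.3))
  expect_equal(unname(r["W"]), 5)
  expect_equal(unname(r["Z"]), (10 - 6) / sqrt(12), tolerance = 1e-12)
  # null center and extremes
  r0 <- rank_sum_z(c(1, 4), c(2, 3))  # W = 2 = n1 n2 / 2
  expect_equal(unname(r0["Z"]), 0)
  re <- rank_sum_z(c(0.1, 0.2), c(0.5, 0.6, 0.7))
  expect_equal(unname(re["W"]), 0)
  expect_equal(unname(re["Z"]), -6 / sqrt(3 * 2 * 6 / 3), tolerance = 1e-12)
  expect_error(rank_sum_z(numeric(0), 1:3), "empty")
})

test_that("rank_sum_z agrees with the all-pairs oracle on random instances", {
  set.seed(30)
  for (i in 1:200) {
    n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
    # ties are common with rounded scores
    g <- round(runif(n2), 1); ctl <- round(runif(n1), 1)
    got <- rank_sum_z(g, ctl)
    ref <- brute_rank_sum(g, ctl)
    expect_identical(unname(got["W"]), unname(ref["W"]))
    expect_equal(unname(got["Z"]), unname(ref["Z"]), tolerance = 1e-12)
  }
})

test_that("control panels are seeded, candidate-free, and capped", {
  st <- small_study(seed = 41)
  vt <- filter_variants(st$variants)
  bins <- assign_bins(vt, st$genes)
  assoc <- data.frame(snp_id = vt$snp_id, r2 = runif(n_snps(vt)))
  cand <- bins$bins$bin_id[1:5]
  p1 <- build_control_panel(bins, assoc, cand, size = 100, seed = 3)
  p2 <- build_control_panel(bins, assoc, cand, size = 100, seed = 3)
  expect_identical(p1, p2)
  expect_length(p1, 100)
  cand_snps <- bins$snp_map$snp_id[bins$snp_map$bin_id %in% cand]
  expect_length(intersect(p1, cand_snps), 0)
  expect_warning(
    pall <- build_control_panel(bins, assoc, cand, size = 1e6, seed = 3),
    "using all")
  expect_setequal(pall, setdiff(assoc$snp_id, cand_snps))
})

test_that("null Z distribution is centered and scaled under exchangeability", {
  set.seed(31)
  sizes <- rgeom(2000, 1 / 10) + 1
  bins <- structure(list(
    bins = data.frame(bin_id = sprintf("b%04d", 1:2000), kind = "genic",
                      chrom = "chr1", start = 1, end = 2, n_snps = sizes),
    snp_map = data.frame(
      snp_id = sprintf("s%06d", seq_len(sum(sizes))),
      bin_id = rep(sprintf("b%04d", 1:2000), sizes))), class = "gene_bins")
  assoc <- data.frame(snp_id = bins$snp_map$snp_id, r2 = runif(sum(sizes)))
  panel <- build_control_panel(bins, assoc, character(0), 5000, seed = 7)
  nz <- null_z_distribution(bins, assoc, panel, character(0))
  expect_equal(nrow(nz), 2000)
  expect_lt(abs(mean(nz$Z)), 0.1)
  expect_gt(sd(nz$Z), 0.8)
  expect_lt(sd(nz$Z), 1.2)
  # deterministic given panel and scores
  nz2 <- null_z_distribution(bins, assoc, panel, character(0))
  expect_identical(nz, nz2)
  # panel-overlap exclusion matches a direct rank_sum_z on the reduced panel
  b <- nz$bin_id[which.max(nz$n2)]
  ids <- bins$snp_map$snp_id[bins$snp_map$bin_id == b]
  g <- assoc$r2[match(ids, assoc$snp_id)]
  ctl <- assoc$r2[match(setdiff(panel, ids), assoc$snp_id)]
  ref <- rank_sum_z(g, ctl)
  expect_equal(nz$W[nz$bin_id == b], unname(ref["W"]))
  expect_equal(nz$Z[nz$bin_id == b], unname(ref["Z"]), tolerance = 1e-12)
  # a bin fully inside the panel still yields a defined Z
  small <- bins$snp_map$bin_id[match(panel[1], bins$snp_map$snp_id)]
  expect_true(small %in% nz$bin_id)
  expect_true(is.finite(nz$Z[nz$bin_id == small]))
})

test_that("empirical null-W p-values are floored and super-uniform", {
  set.seed(32)
  null_z <- data.frame(bin_id = sprintf("n%04d", 1:2000), n1 = 100, n2 = 10,
                       W = 0, Z = rnorm(2000))
  # candidate with Z above every null value hits the floor 1/2000
  bins <- structure(list(
    bins = data.frame(bin_id = "g1", kind = "genic", chrom = "chr1",
                      start = 1, end = 2, n_snps = 5),
    snp_map = data.frame(snp_id = sprintf("g1_s%d", 1:5), bin_id = "g1")),
    class = "gene_bins")
  assoc <- data.frame(snp_id = c(sprintf("g1_s%d", 1:5), sprintf("c%03d", 1:200)),
                      r2 = c(rep(0.99, 5), runif(200, 0, 0.5)))
  bins$snp_map <- rbind(bins$snp_map,
                        data.frame(snp_id = sprintf("c%03d", 1:200),
                                   bin_id = rep(sprintf("nc%02d", 1:20), each = 10)))
  bins$bins <- rbind(bins$bins,
                     data.frame(bin_id = sprintf("nc%02d", 1:20), kind = "genic",
                                chrom = "chr1", start = 1, end = 2, n_snps = 10))
  panel <- sprintf("c%03d", 1:200)
  res <- nullw_test("g1", bins, assoc, panel, null_z)
  expect_equal(res$p, 1 / 2000)
  expect_true(res$parallel)
  # under exchangeable scores the empirical p is approximately uniform
  obs_z <- rnorm(500)
  p_emp <- vapply(obs_z, function(z)
    max(mean(null_z$Z > z), 1 / 2000), numeric(1))
  expect_gt(suppressWarnings(ks.test(p_emp, "punif")$p.value), 0.01)
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  p <- withr::with_seed(33, runif(50))
  q <- bh_adjust(p)
  o <- order(p)
  q_oracle <- rev(cummin(rev(p[o] * 50 / seq_len(50))))
  expect_equal(q[o], pmin(q_oracle, 1))
  # order invariance
  perm <- withr::with_seed(34, sample(50))
  expect_equal(bh_adjust(p[perm]), q[perm])
})

test_that("hypergeometric overlap matches enumeration and is symmetric", {
  ht <- hypergeom_overlap(10, 5, 5, 5)
  expect_equal(ht$p, 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_overlap(10, 5, 5, 5)$p,
               brute_hyper_upper(10, 5, 5, 5), tolerance = 1e-12)
  expect_equal(hypergeom_overlap(500, 40, 25, 4)$p,
               brute_hyper_upper(500, 40, 25, 4), tolerance = 1e-12)
  expect_equal(hypergeom_overlap(500, 40, 25, 4)$p,
               hypergeom_overlap(500, 25, 40, 4)$p, tolerance = 1e-14)
  expect_equal(hypergeom_overlap(100, 10, 10, 0)$p, 1)
  expect_error(hypergeom_overlap(10, 5, 5, 6), "inconsistent")
  # binomial limit at large N, fixed K/N
  N <- 1e6; K <- 2e5; n <- 30; k <- 12
  expect_equal(hypergeom_overlap(N, K, n, k)$p,
               pbinom(k - 1, n, K / N, lower.tail = FALSE), tolerance = 0.01)
})
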