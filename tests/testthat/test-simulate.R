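test_that("config invariants are enforced", {
  expect_error(sim_config(fst = 0), "fst")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(n_causal_shared = 30, n_causal_genes_lat = 10,
                          n_causal_genes_alt = 20), "shared")
  expect_error(sim_config(n_blocks = 0), "counts")
})

test_that("identical seeds give bit-identical studies", {
  a <- small_study(seed = 5)
  b <- small_study(seed = 5)
  expect_identical(a$variants$dosage, b$variants$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$climate, b$climate)
  c <- small_study(seed = 6)
  expect_false(identical(a$variants$dosage, c$variants$dosage))
})

test_that("truth is internally consistent", {
  st <- small_study(seed = 9)
  tr <- st$truth
  expect_true(all(tr$shared_genes %in% tr$causal_genes$lat))
  expect_true(all(tr$shared_genes %in% tr$causal_genes$alt))
  map_gene <- function(ids) {
    # every causal SNP must fall inside a causal gene body
    idx <- match(ids, st$variants$snp_id)
    pos <- st$variants$pos[idx]; ch <- st$variants$chrom[idx]
    vapply(seq_along(ids), function(i) {
      g <- st$genes[st$genes$chrom == ch[i] & st$genes$start <= pos[i] &
                      st$genes$end >= pos[i], "gene_id"]
      length(g) == 1
    }, logical(1))
  }
  expect_true(all(map_gene(tr$causal_snps$lat$snp_id)))
  expect_true(all(map_gene(tr$causal_snps$alt$snp_id)))
})

test_that("heterozygosity decreases as fst increases", {
  het <- vapply(c(0.05, 0.2, 0.5), function(f) {
    mean(vapply(1:3, function(s) {
      st <- simulate_study(sim_config(n_genes = 40, snps_per_gene = 6,
                                      n_intergenic_snps = 50, fst = f,
                                      n_causal_genes_lat = 2,
                                      n_causal_genes_alt = 2,
                                      n_causal_shared = 1, seed = s))
      mean(st$variants$dosage == 1)
    }, numeric(1)))
  }, numeric(1))
  expect_true(het[1] > het[2] && het[2] > het[3])
})

test_that("causal SNP frequencies are clinal relative to neutral SNPs", {
  st <- small_study(seed = 21)
  prov <- st$truth$provenance_positions
  lat_prov <- prov$provenance[prov$transect == "lat"]
  cl <- st$samples$clone[st$samples$transect == "lat"]
  d <- st$variants$dosage[cl, , drop = FALSE]
  pf <- rowsum(d, st$samples$provenance[match(cl, st$samples$clone)])
  pf <- pf / (2 * as.vector(table(st$samples$provenance[match(cl, st$samples$clone)])[rownames(pf)]))
  lats <- prov$latitude[match(rownames(pf), prov$provenance)]
  rho <- abs(apply(pf, 2, function(p) suppressWarnings(cor(p, lats, method = "spearman"))))
  causal <- st$variants$snp_id %in% st$truth$causal_snps$lat$snp_id
  cutoff <- quantile(rho[!causal], 0.95, na.rm = TRUE)
  expect_gt(mean(rho[causal] > cutoff, na.rm = TRUE), 0.8)
})

test_that("noise-free limit reproduces the genetic values exactly", {
  cfg <- sim_config(n_genes = 30, snps_per_gene = 5, n_intergenic_snps = 40,
                    n_causal_genes_lat = 3, n_causal_genes_alt = 3,
                    n_causal_shared = 1, h2_clone = 1, climate_effect = 0,
                    seed = 2)
  st <- simulate_study(cfg)
  cs <- st$truth$causal_snps$lat
  cl <- st$samples$clone[st$samples$transect == "lat"]
  g <- st$variants$dosage[cl, cs$snp_id, drop = FALSE] %*% cs$effect
  expect_equal(unname(st$truth$true_clone_values[cl]), as.vector(g))
  # and observations differ from clone value only by mean + block effect
  ph <- st$phenotypes
  one <- ph[ph$clone == cl[1] & ph$garden == "VA", ]
  expect_equal(stats::sd(one$value - st$truth$true_clone_values[cl[1]]),
               stats::sd(one$value - mean(one$value)), tolerance = 1e-10)
})

test_that("realized clone repeatability tracks h2_clone", {
  for (h2 in c(0.4, 0.8)) {
    st <- simulate_study(sim_config(n_genes = 50, snps_per_gene = 6,
                                    n_intergenic_snps = 60, h2_clone = h2,
                                    n_causal_genes_lat = 5,
                                    n_causal_genes_alt = 5,
                                    n_causal_shared = 2, seed = 31))
    ph <- st$phenotypes[st$phenotypes$garden == "VA", ]
    fit <- fit_blups(st$phenotypes, "height", "VA")
    v <- fit$varcomp
    rep_hat <- v["sigma2_clone"] / (v["sigma2_clone"] + v["sigma2_resid"])
    expect_lt(abs(rep_hat - h2), 0.15)
  }
})

test_that("written study round-trips through the readers", {
  st <- small_study(seed = 14)
  d <- withr::local_tempdir()
  paths <- write_study(st, d)
  expect_true(all(file.exists(paths)))
  vt2 <- read_genotypes(paths[["vcf"]])
  expect_equal(vt2$dosage[rownames(st$variants$dosage), st$variants$snp_id],
               st$variants$dosage, ignore_attr = TRUE)
  g2 <- read_annotation(paths[["gff"]])
  expect_equal(g2$start, st$genes$start[order(st$genes$chrom, st$genes$start)])
  ph2 <- read.delim(paths[["phenotypes"]])
  expect_equal(ph2$value, st$phenotypes$value, tolerance = 1e-10)
})

test_that("empty gene set writes a header-only GFF3", {
  d <- withr::local_tempdir()
  p <- file.path(d, "empty.gff3")
  write_gff3(data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer()), p)
  expect_identical(readLines(p), "##gff-version 3")
  expect_equal(nrow(read_annotation(p)), 0)
})

test_that("intergenic SNPs are placed more than 2 kb from every gene", {
  st <- small_study(seed = 8)
  genic <- rep(FALSE, n_snps(st$variants))
  for (i in seq_len(nrow(st$genes))) {
    g <- st$genes[i, ]
    genic <- genic | (st$variants$chrom == g$chrom &
                        st$variants$pos >= g$start - 2000 &
                        st$variants$pos <= g$end + 2000)
  }
  bins <- assign_bins(st$variants, st$genes)
  kinds <- bins$bins$kind[match(bins$snp_map$bin_id, bins$bins$bin_id)]
  expect_true(all(kinds[!genic] == "intergenic_cluster"))
  expect_true(all(kinds[genic] == "genic"))
})

test_that("near-zero fst with no causal loci yields calibrated GWAS", {
  prov_var <- function(f, seed) {
    st <- simulate_study(sim_config(n_genes = 60, snps_per_gene = 8,
                                    n_intergenic_snps = 60, fst = f,
                                    n_causal_genes_lat = 1, n_causal_genes_alt = 1,
                                    n_causal_shared = 1, causal_snps_per_gene = 1,
                                    effect_size_sd = 0, climate_effect = 0,
                                    seed = seed))
    cl <- st$samples$clone[st$samples$transect == "lat"]
    pf <- rowsum(st$variants$dosage[cl, ],
                 st$samples$provenance[match(cl, st$samples$clone)]) / 8
    mean(apply(pf, 2, var))
  }
  # at F -> 0 the residual provenance variance is pure binomial sampling
  # noise; structure-driven variance at F = 0.3 dwarfs it
  expect_lt(prov_var(0.001, 17), 0.4 * prov_var(0.3, 17))
  st <- simulate_study(sim_config(n_genes = 250, snps_per_gene = 20,
                                  n_intergenic_snps = 200, fst = 0.001,
                                  n_causal_genes_lat = 1, n_causal_genes_alt = 1,
                                  n_causal_shared = 1, causal_snps_per_gene = 1,
                                  effect_size_sd = 0, climate_effect = 0,
                                  seed = 17))
  cl <- st$samples$clone[st$samples$transect == "lat"]
  vt <- filter_variants(subset_variants(st$variants, cl))
  bl <- fit_blups(st$phenotypes[st$phenotypes$clone %in% cl, ], "height", "VA")
  phen <- unname(bl$blup[match(rownames(vt$dosage), names(bl$blup))])
  lam <- lambda_gc(glm_scan(vt, phen)$p)
  expect_lt(abs(lam - 1), 0.1)
})
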