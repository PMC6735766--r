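test_that("kinship matrix follows the centered-relationship formula", {
  # single SNP, p = 0.5, dosages {0, 2}: W = {-1, 1}, 2*sum(p(1-p)) = 0.5
  vt <- variant_table(matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "s1")),
                      "chr1", 100)
  K <- kinship_matrix(vt)
  expect_equal(K, matrix(c(2, -2, -2, 2), 2, dimnames = list(c("a", "b"), c("a", "b"))))
  # duplicated sample: off-diagonal equals diagonal
  vt2 <- toy_vt(n = 10, m = 50, seed = 1)
  d <- rbind(vt2$dosage, dup = vt2$dosage[1, ])
  K2 <- kinship_matrix(variant_table(d, vt2$chrom, vt2$pos))
  expect_equal(K2["dup", "s01"], K2["s01", "s01"])
  # PSD and symmetric
  expect_equal(K2, t(K2))
  expect_gt(min(eigen(K2, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # unrelated samples: off-diagonal mean near zero
  vt3 <- toy_vt(n = 40, m = 400, seed = 2)
  K3 <- kinship_matrix(vt3)
  expect_lt(abs(mean(K3[lower.tri(K3)])), 0.05)
})

test_that("glm_scan reproduces hand OLS results", {
  vt <- variant_table(matrix(c(0, 1, 1, 2), 4, 1, dimnames = list(NULL, "s1")),
                      "chr1", 10)
  res <- glm_scan(vt, c(1, 2, 3, 4))
  expect_equal(res$r2, 0.9, tolerance = 1e-12)  # r = 3/sqrt(10)
  # phenotype exactly equal to dosage
  res2 <- glm_scan(vt, c(0, 1, 1, 2))
  expect_equal(res2$r2, 1, tolerance = 1e-12)
  expect_lt(res2$p, 1e-12)
  # matches lm() with a covariate
  set.seed(3)
  vt3 <- toy_vt(n = 40, m = 8, seed = 3)
  y <- rnorm(40); cov1 <- cbind(x = rnorm(40))
  res3 <- glm_scan(vt3, y, cov1)
  for (j in c(1, 5)) {
    fit <- lm(y ~ vt3$dosage[, j] + cov1)
    expect_equal(res3$p[j], summary(fit)$coefficients[2, 4], tolerance = 1e-10)
    expect_equal(res3$beta[j], coef(fit)[2], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("r2 is invariant to affine phenotype transforms and coding flips", {
  vt <- toy_vt(n = 30, m = 10, seed = 4)
  y <- withr::with_seed(5, rnorm(30))
  a <- glm_scan(vt, y)
  b <- glm_scan(vt, 3 * y - 7)
  expect_equal(a$r2, b$r2, tolerance = 1e-12)
  flip <- variant_table(2 - vt$dosage, vt$chrom, vt$pos)
  c_ <- glm_scan(flip, y)
  expect_equal(a$r2, c_$r2, tolerance = 1e-12)
})

test_that("null p-values are uniform for independent dosages", {
  set.seed(6)
  vt <- toy_vt(n = 300, m = 800, seed = 6)
  y <- rnorm(300)
  res <- glm_scan(vt, y)
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("mlm_scan reduces to glm_scan when K is the identity", {
  vt <- toy_vt(n = 50, m = 30, seed = 7)
  y <- withr::with_seed(8, rnorm(50))
  cov1 <- withr::with_seed(9, cbind(a = rnorm(50)))
  g <- glm_scan(vt, y, cov1)
  m <- mlm_scan(vt, y, cov1, diag(50))
  expect_equal(m$p, g$p, tolerance = 1e-6)
  expect_equal(m$r2, g$r2, tolerance = 1e-6)
})

test_that("mlm_scan recovers the variance ratio and deflates inflation", {
  set.seed(10)
  n <- 300
  # two populations with diverged allele frequencies
  m <- 600
  pA <- runif(m, 0.1, 0.9)
  pB <- pmin(0.95, pmax(0.05, pA + runif(m, -0.35, 0.35)))
  d <- rbind(matrix(rbinom(n / 2 * m, 2, rep(pA, each = n / 2)), n / 2),
             matrix(rbinom(n / 2 * m, 2, rep(pB, each = n / 2)), n / 2))
  dimnames(d) <- list(sprintf("i%03d", 1:n), sprintf("s%04d", 1:m))
  vt <- filter_variants(variant_table(d, rep("chr1", m), seq_len(m) * 10))
  K <- kinship_matrix(vt)
  # structured phenotype: population effect, no causal SNP
  y <- rep(c(0, 1.2), each = n / 2) + rnorm(n)
  lam_glm <- lambda_gc(glm_scan(vt, y)$p)
  res_mlm <- mlm_scan(vt, y, NULL, K)
  expect_gt(lam_glm, lambda_gc(res_mlm$p))
  # polygenic phenotype: estimated variance ratio in a sane range
  u <- as.vector(d %*% rnorm(m, 0, sqrt(1 / m)))
  y2 <- u + rnorm(n, 0, sd(u))
  invisible(mlm_scan(vt, y2, NULL, K))
  delta <- attr(mlm_scan(vt, y2, NULL, K), "delta")
  expect_gt(delta, 0.3)
  expect_lt(delta, 3)
})

test_that("lambda_gc matches its definition and calibrates on uniforms", {
  expect_equal(lambda_gc(rep(0.5, 200)), 1, tolerance = 1e-6)
  p <- withr::with_seed(11, runif(1e5))
  expect_gt(lambda_gc(p), 0.98)
  expect_lt(lambda_gc(p), 1.02)
  # inflated chi-square: lambda tracks the scale factor
  x <- withr::with_seed(12, 1.5 * rchisq(5e4, 1))
  expect_equal(lambda_gc(pchisq(x, 1, lower.tail = FALSE)), 1.5,
               tolerance = 0.03)
  expect_error(lambda_gc(numeric(0)), "no p-values")
})

test_that("model selection walks the parsimony order", {
  sel <- select_model(c(simple = 1.6, PC2 = 1.3, PC5 = 1.15, `PC2+K` = 1.02))
  expect_equal(sel$model, "PC5")
  sel2 <- select_model(c(simple = 1.1, PC2 = 1.0, PC5 = 1.05, K = 1.01))
  expect_equal(sel2$model, "simple")
  expect_warning(sel3 <- select_model(c(simple = 1.8, PC2 = 1.5, `PC2+K` = 1.31)),
                 "nearest")
  expect_equal(sel3$model, "PC2+K")
  expect_false(sel3$in_window)
})

test_that("spearman scan reproduces hand rank correlations", {
  vt <- variant_table(matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "s1")),
                      "chr1", 5)
  res <- spearman_climate_scan(vt, c(3, 1, 2))
  expect_equal(res$rho, -0.5, tolerance = 1e-12)  # sum d^2 = 6
  # strictly monotone dosage in climate
  vt2 <- variant_table(matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "s1")),
                       "chr1", 5)
  res2 <- spearman_climate_scan(vt2, c(10, 20, 40))
  expect_equal(res2$rho, 1, tolerance = 1e-12)
  expect_equal(res2$r2, 1, tolerance = 1e-12)
  expect_error(spearman_climate_scan(vt2, rep(1, 3)), "constant")
})

test_that("spearman scan matches cor.test with ties and permutation null", {
  vt <- toy_vt(n = 60, m = 40, seed = 13)
  y <- withr::with_seed(14, rnorm(60) + rep(c(0, 0.5), 30))
  res <- spearman_climate_scan(vt, y)
  ref <- apply(vt$dosage, 2, function(g)
    suppressWarnings(cor(g, y, method = "spearman")))
  expect_equal(res$rho, unname(ref), tolerance = 1e-12)
  # permuted labels give a null-distributed scan
  perm <- withr::with_seed(15, sample(y))
  r_perm <- spearman_climate_scan(vt, perm)$r2
  vt_null <- toy_vt(n = 60, m = 40, seed = 16)
  r_null <- spearman_climate_scan(vt_null, y)$r2
  expect_gt(suppressWarnings(stats::ks.test(r_perm, r_null)$p.value), 0.01)
})
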