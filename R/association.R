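#' Centered genomic relationship (kinship) matrix
#'
#' VanRaden-type estimator: K = W W' / (2 * sum p(1-p)) with
#' W = dosage - 2p, p the sample alt-allele frequency of each SNP.
#' Monomorphic SNPs contribute nothing and are dropped.
#'
#' @param vt a filled [variant_table()].
#' @return symmetric positive-semidefinite samples x samples matrix.
#' @export
kinship_matrix <- function(vt) {
  p <- colMeans(vt$dosage) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic")
  W <- sweep(vt$dosage[, poly, drop = FALSE], 2, 2 * p[poly])
  K <- tcrossprod(W) / (2 * sum(p[poly] * (1 - p[poly])))
  (K + t(K)) / 2
}

# residualize y (vector or matrix columns) on covariate matrix C (with intercept)
.resid_on <- function(x, qrC) qr.resid(qrC, x)

#' Per-SNP linear-model association scan
#'
#' Ordinary least squares of the phenotype on each SNP's dosage plus
#' covariates. Reports the dosage coefficient, its two-sided t-test p-value,
#' and r2 = squared partial correlation of dosage and phenotype given the
#' covariates.
#'
#' @param vt a filled [variant_table()]; samples must match `phenotype`.
#' @param phenotype numeric vector, one value per sample (names optional but
#'   checked against sample ids when present).
#' @param covariates optional numeric matrix of covariates (samples x q),
#'   e.g. PC scores; an intercept is always included.
#' @return data.frame of class `snp_association`: `snp_id`, `chrom`, `pos`,
#'   `beta`, `statistic`, `p`, `r2`.
#' @export
glm_scan <- function(vt, phenotype, covariates = NULL) {
  n <- n_samples(vt)
  stopifnot(length(phenotype) == n)
  if (!is.null(names(phenotype)) && !is.null(rownames(vt$dosage)))
    stopifnot(identical(names(phenotype), rownames(vt$dosage)))
  C <- cbind(`(Intercept)` = rep(1, n), covariates)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("covariates are rank deficient")
  yr <- .resid_on(phenotype, qrC)
  Gr <- .resid_on(vt$dosage, qrC)
  df <- n - ncol(C) - 1
  ss_g <- colSums(Gr^2)
  ss_y <- sum(yr^2)
  cp <- as.vector(crossprod(Gr, yr))
  r <- cp / sqrt(ss_g * ss_y)
  r[ss_g <= 0 | ss_y <= 0] <- NA_real_
  beta <- cp / ss_g
  tval <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  structure(data.frame(snp_id = vt$snp_id, chrom = vt$chrom, pos = vt$pos,
                       beta = beta, statistic = tval, p = p, r2 = r^2),
            class = c("snp_association", "data.frame"))
}

# REML profile log-likelihood for the one-random-effect model after rotation
# by the eigenvectors of K; delta = sigma2_e / sigma2_g
.reml_ll <- function(log_delta, d, Xs, ys) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  sw <- sqrt(w)
  Xw <- Xs * sw
  yw <- ys * sw
  fit <- qr(Xw)
  rss <- sum(qr.resid(fit, yw)^2)
  nq <- length(ys) - ncol(Xs)
  XtX <- crossprod(Xw)
  XtX0 <- crossprod(Xs)
  -0.5 * (nq * log(rss / nq) + nq - sum(log(w)) +
            determinant(XtX, logarithm = TRUE)$modulus -
            determinant(XtX0, logarithm = TRUE)$modulus)
}

#' Per-SNP mixed-model association scan
#'
#' Single-random-effect mixed model y = Xb + u + e with Var(u) =
#' sigma2_g K, solved by a one-time spectral decomposition of K. The
#' variance ratio is estimated by REML on the null (no-SNP) model and held
#' fixed across SNPs; each SNP is then tested by generalized least squares
#' in the rotated coordinates. Output columns match [glm_scan()].
#'
#' @inheritParams glm_scan
#' @param K kinship matrix from [kinship_matrix()].
#' @return data.frame of class `snp_association`; attribute `delta` holds
#'   the estimated sigma2_e / sigma2_g ratio.
#' @export
mlm_scan <- function(vt, phenotype, covariates = NULL, K) {
  n <- n_samples(vt)
  stopifnot(length(phenotype) == n, all(dim(K) == n))
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values)))
    stop("K is not positive semidefinite")
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  C <- cbind(`(Intercept)` = rep(1, n), covariates)
  ys <- crossprod(U, phenotype)[, 1]
  Xs <- crossprod(U, C)
  opt <- stats::optimize(.reml_ll, c(-10, 10), d = d, Xs = Xs, ys = ys,
                         maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  sw <- sqrt(1 / (d + delta))
  yw <- ys * sw
  Xw <- Xs * sw
  Gw <- crossprod(U, vt$dosage) * sw
  qrX <- qr(Xw)
  yr <- qr.resid(qrX, yw)
  Gr <- qr.resid(qrX, Gw)
  df <- n - ncol(C) - 1
  ss_g <- colSums(Gr^2); ss_y <- sum(yr^2)
  cp <- as.vector(crossprod(Gr, yr))
  r <- cp / sqrt(ss_g * ss_y)
  r[ss_g <= 0 | ss_y <= 0] <- NA_real_
  beta <- cp / ss_g
  tval <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- pmax(2 * stats::pt(-abs(tval), df), .Machine$double.xmin)
  out <- structure(data.frame(snp_id = vt$snp_id, chrom = vt$chrom,
                              pos = vt$pos, beta = beta, statistic = tval,
                              p = p, r2 = r^2),
                   class = c("snp_association", "data.frame"))
  attr(out, "delta") <- delta
  out
}

#' Genomic inflation factor
#'
#' lambda_GC = median of the chi-square(1) quantile transform of the
#' p-values, divided by the chi-square(1) median 0.4549364.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return scalar lambda.
#' @export
lambda_gc <- function(p_values) {
  p <- p_values[is.finite(p_values)]
  if (length(p) == 0) stop("no p-values")
  if (length(p) < 100)
    warning("lambda_GC estimated from fewer than 100 p-values")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / 0.4549364
}

#' Select the structure-correction model by genomic inflation
#'
#' Among candidate models whose lambda_GC falls inside the acceptance
#' window, returns the most parsimonious one in the order
#' simple < PC2 < PC5 < PC10 < K < PC2+K. If no model qualifies, the model
#' with lambda nearest the window is returned with a warning.
#'
#' @param lambdas named numeric vector of lambda_GC per candidate model.
#' @param window acceptance interval, default `c(0.98, 1.22)`.
#' @param parsimony_order model names from most to least parsimonious;
#'   models absent from `lambdas` are skipped.
#' @return list: `model` (name), `lambda`, `in_window` (logical).
#' @export
select_model <- function(lambdas, window = c(0.98, 1.22),
                         parsimony_order = c("simple", "PC2", "PC5", "PC10",
                                             "K", "PC2+K")) {
  if (length(lambdas) == 0) stop("no candidate models")
  ord <- c(intersect(parsimony_order, names(lambdas)),
           setdiff(names(lambdas), parsimony_order))
  lam <- lambdas[ord]
  ok <- lam >= window[1] & lam <= window[2]
  if (any(ok)) {
    i <- which(ok)[1]
    return(list(model = names(lam)[i], lambda = unname(lam[i]), in_window = TRUE))
  }
  dist <- pmax(window[1] - lam, lam - window[2], 0)
  i <- which.min(dist)
  warning("no model has lambda_GC inside [", window[1], ", ", window[2],
          "]; returning nearest (", names(lam)[i], ")")
  list(model = names(lam)[i], lambda = unname(lam[i]), in_window = FALSE)
}

#' Per-SNP Spearman genotype-environment scan
#'
#' Spearman rank correlation (midranks for ties) between each SNP's dosage
#' and a climate value per sample (the provenance value propagated to its
#' clones). Reports rho-squared as `r2` and the asymptotic two-sided
#' t-approximation p-value.
#'
#' @param vt a filled [variant_table()].
#' @param climate_values numeric vector, one value per sample.
#' @return data.frame of class `snp_association`: `snp_id`, `chrom`, `pos`,
#'   `rho`, `statistic`, `p`, `r2`.
#' @export
spearman_climate_scan <- function(vt, climate_values) {
  n <- n_samples(vt)
  stopifnot(length(climate_values) == n)
  if (stats::sd(climate_values) == 0) stop("climate variable is constant")
  ry <- rank(climate_values)
  ry <- ry - mean(ry)
  D <- vt$dosage
  if (all(D %in% c(0, 1, 2))) {
    # midranks of a 0/1/2 column follow from the three counts, which lets
    # the whole rank transform run as matrix arithmetic
    two <- D == 2
    n2 <- colSums(two); n1 <- colSums(D) - 2 * n2; n0 <- n - n1 - n2
    r0 <- (n0 + 1) / 2; r1 <- n0 + (n1 + 1) / 2; r2 <- n0 + n1 + (n2 + 1) / 2
    mr <- (n + 1) / 2
    # per-genotype-class sums of the centered climate ranks: s1 + 2*s2 and
    # s2 come from two crossprods, s0 follows because the ranks sum to zero
    a <- as.vector(crossprod(D, ry)); s2 <- as.vector(crossprod(two, ry))
    s1 <- a - 2 * s2; s0 <- -(s1 + s2)
    cp <- s0 * (r0 - mr) + s1 * (r1 - mr) + s2 * (r2 - mr)
    ss_g <- n0 * (r0 - mr)^2 + n1 * (r1 - mr)^2 + n2 * (r2 - mr)^2
  } else {
    RG <- scale(apply(D, 2, rank), center = TRUE, scale = FALSE)
    ss_g <- colSums(RG^2)
    cp <- as.vector(crossprod(RG, ry))
  }
  rho <- cp / sqrt(ss_g * sum(ry^2))
  rho[ss_g <= 0] <- NA_real_
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- pmax(2 * stats::pt(-abs(tval), n - 2), .Machine$double.xmin)
  structure(data.frame(snp_id = vt$snp_id, chrom = vt$chrom, pos = vt$pos,
                       rho = rho, statistic = tval, p = p, r2 = rho^2),
            class = c("snp_association", "data.frame"))
}
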