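#' Greedy selection of weakly correlated climate predictors
#'
#' Walks the variables in priority order and keeps a variable only if its
#' maximum absolute Pearson correlation with the already-kept set is below
#' `r_max`.
#'
#' @param climate data.frame or matrix of candidate variables (samples or
#'   provenances x variables).
#' @param r_max correlation ceiling, default 0.75.
#' @param priority variable names in preference order; defaults to column
#'   order.
#' @return character vector of kept variable names.
#' @export
select_predictors <- function(climate, r_max = 0.75, priority = NULL) {
  X <- as.matrix(climate)
  if (ncol(X) == 0) stop("empty climate table")
  if (is.null(priority)) priority <- colnames(X)
  priority <- intersect(priority, colnames(X))
  kept <- character(0)
  for (v in priority) {
    if (stats::sd(X[, v]) == 0) next
    if (length(kept) == 0 ||
        max(abs(stats::cor(X[, v], X[, kept, drop = FALSE]))) < r_max)
      kept <- c(kept, v)
  }
  kept
}

#' Redundancy analysis of genotypes on climate predictors
#'
#' Constrained ordination computed from first principles: the per-SNP
#' centered dosage matrix Y is regressed on the standardized predictor
#' matrix X, and the fitted values are decomposed by SVD. Eigenvalues are
#' the squared singular values of fitted / sqrt(n - 1); locus scores are
#' the unit-norm right singular vectors; sample scores are the left
#' singular vectors scaled by the singular values.
#'
#' @param vt a filled [variant_table()], or a numeric samples x SNPs matrix.
#' @param predictors numeric samples x p matrix of climate predictors
#'   (standardized internally).
#' @return list of class `rda_model`: `eigenvalues`, `sample_scores`,
#'   `locus_scores`, `predictor_loadings` (correlation of each predictor
#'   with each axis's sample scores), `constrained_fraction`, `predictors`
#'   (the standardized matrix), `snp_ids`.
#' @export
fit_rda <- function(vt, predictors) {
  Y <- if (inherits(vt, "variant_table")) vt$dosage else as.matrix(vt)
  X <- scale(as.matrix(predictors))
  n <- nrow(Y)
  stopifnot(nrow(X) == n, ncol(X) < n)
  kx <- kappa(crossprod(X), exact = TRUE)
  if (!is.finite(kx) || kx > 1e10) stop("collinear predictors (condition number > 1e10)")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  qrX <- qr(X)
  fitted <- qr.fitted(qrX, Yc)
  naxes <- qrX$rank
  sv <- svd(fitted / sqrt(n - 1), nu = naxes, nv = naxes)
  d <- sv$d[seq_len(naxes)]
  for (i in seq_len(naxes)) {  # sign convention: largest |locus score| positive
    top <- which.max(abs(sv$v[, i]))
    if (sv$v[top, i] < 0) { sv$v[, i] <- -sv$v[, i]; sv$u[, i] <- -sv$u[, i] }
  }
  ax <- paste0("RDA", seq_len(naxes))
  samp <- sv$u %*% diag(d, naxes, naxes)
  dimnames(samp) <- list(rownames(Y), ax)
  locus <- sv$v
  dimnames(locus) <- list(colnames(Y), ax)
  total <- sum(Yc^2) / (n - 1)
  loadings <- suppressWarnings(stats::cor(X, samp))
  structure(list(eigenvalues = d^2,
                 sample_scores = samp,
                 locus_scores = locus,
                 predictor_loadings = loadings,
                 constrained_fraction = sum(d^2) / total,
                 predictors = X,
                 snp_ids = colnames(Y)),
            class = "rda_model")
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf("rda_model: %d axes, %.1f%% of genotypic variance constrained\n",
              length(x$eigenvalues), 100 * x$constrained_fraction))
  cat("  eigenvalues:", signif(x$eigenvalues, 3), "\n")
  invisible(x)
}

#' Locus-score outliers on the leading ordination axes
#'
#' For each of the first `n_axes` axes, flags SNPs whose locus score lies
#' more than `sd_mult` standard deviations from the axis mean, and assigns
#' each flagged SNP to the predictor with which its dosage is most strongly
#' correlated (by absolute Pearson correlation). A SNP extreme on several
#' axes is reported once per axis.
#'
#' @param model an `rda_model` from [fit_rda()].
#' @param dosage samples x SNPs dosage matrix used for the fit (for the
#'   predictor assignment), or a `variant_table`.
#' @param n_axes number of leading axes to scan, default 3.
#' @param sd_mult outlier multiplier, default 3.
#' @return data.frame of class `rda_outliers`: `snp_id`, `axis`, `score`,
#'   `predictor`, `r`.
#' @export
rda_outliers <- function(model, dosage, n_axes = 3, sd_mult = 3) {
  if (n_axes > ncol(model$locus_scores))
    stop("n_axes exceeds the number of fitted axes")
  D <- if (inherits(dosage, "variant_table")) dosage$dosage else as.matrix(dosage)
  rows <- list()
  for (i in seq_len(n_axes)) {
    s <- model$locus_scores[, i]
    mu <- mean(s); sdv <- stats::sd(s)
    hit <- which(abs(s - mu) > sd_mult * sdv)
    if (length(hit) == 0) next
    r_mat <- suppressWarnings(stats::cor(D[, hit, drop = FALSE], model$predictors))
    j <- apply(abs(r_mat), 1, which.max)
    rows[[i]] <- data.frame(snp_id = model$snp_ids[hit], axis = i,
                            score = unname(s[hit]),
                            predictor = colnames(model$predictors)[j],
                            r = r_mat[cbind(seq_along(hit), j)])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(), axis = integer(), score = numeric(),
               predictor = character(), r = numeric())
  rownames(out) <- NULL
  class(out) <- c("rda_outliers", "data.frame")
  out
}
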