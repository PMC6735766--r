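#' Construct a variant table
#'
#' Container for biallelic SNP genotypes coded as alt-allele dosages (0/1/2,
#' `NA` for missing). Per-SNP minor allele frequency and missingness are
#' computed on construction.
#'
#' @param dosage numeric matrix, samples x SNPs; values 0, 1, 2 or `NA`.
#'   Column names are SNP ids, row names sample ids.
#' @param chrom character vector of chromosome names, one per SNP.
#' @param pos integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param ref,alt allele characters (single bases or symbolic), one per SNP.
#' @return An object of class `variant_table`: a list with elements
#'   `snp_id`, `chrom`, `pos`, `ref`, `alt`, `dosage`, `maf`, `missingness`.
#' @export
variant_table <- function(dosage, chrom, pos, ref = NULL, alt = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- paste0("snp", seq_len(m))
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("s", seq_len(nrow(dosage)))
  stopifnot(length(chrom) == m, length(pos) == m)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("T", m)
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    stop("dosages must lie in [0, 2]")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  p_alt <- colMeans(dosage, na.rm = TRUE) / 2
  p_alt[is.nan(p_alt)] <- NA_real_
  structure(list(
    snp_id = colnames(dosage),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    dosage = dosage,
    maf = pmin(p_alt, 1 - p_alt),
    missingness = colMeans(is.na(dosage))
  ), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), length(x$snp_id), length(unique(x$chrom))))
  cat(sprintf("  median MAF %.3f, median missingness %.3f\n",
              stats::median(x$maf, na.rm = TRUE), stats::median(x$missingness)))
  invisible(x)
}

#' Number of samples / SNPs in a variant table
#' @param vt a `variant_table`
#' @export
n_samples <- function(vt) nrow(vt$dosage)

#' @rdname n_samples
#' @export
n_snps <- function(vt) length(vt$snp_id)

#' Subset a variant table
#'
#' @param vt a `variant_table`
#' @param samples sample ids or indices to keep (default all)
#' @param snps SNP ids or indices to keep (default all)
#' @return a `variant_table` with MAF/missingness recomputed on the subset.
#' @export
subset_variants <- function(vt, samples = NULL, snps = NULL) {
  d <- vt$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  keep <- if (is.null(snps)) seq_along(vt$snp_id) else {
    if (is.character(snps)) match(snps, vt$snp_id) else snps
  }
  variant_table(d[, keep, drop = FALSE], vt$chrom[keep], vt$pos[keep],
                vt$ref[keep], vt$alt[keep])
}

#' Read genotypes from a VCF file
#'
#' Reads a VCFv4.2 file with GT fields and codes genotypes as alt-allele
#' dosages. Records that are not biallelic SNPs, and half-calls such as
#' `./1`, are rejected; the number of rejected records/calls is reported as a
#' warning and stored in attributes `n_excluded` and `n_halfcalls`.
#'
#' @param vcf_path path to a VCF file (plain or bgzipped).
#' @return a [variant_table()].
#' @export
read_genotypes <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (ncol(v@gt) < 2) stop("VCF has zero sample columns: ", vcf_path)
  fix <- v@fix
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  n_excluded <- sum(!biallelic)
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  # strip phasing, then map the three diploid genotypes
  gt <- gsub("|", "/", gt, fixed = TRUE)
  codes <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2, "./." = NA_real_)
  dos <- matrix(codes[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  known <- gt %in% names(codes) | is.na(gt)
  n_half <- sum(!known)
  dos[!known] <- NA_real_
  if (n_excluded + n_half > 0)
    warning(sprintf("excluded %d non-biallelic record(s), %d half/odd call(s) set missing",
                    n_excluded, n_half))
  ids <- fix[, "ID"]
  if (all(is.na(ids)) || any(ids == "." | is.na(ids)))
    ids <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  dos <- t(dos)  # samples x SNPs
  colnames(dos) <- ids
  vt <- variant_table(dos, fix[, "CHROM"], as.integer(fix[, "POS"]),
                      fix[, "REF"], fix[, "ALT"])
  attr(vt, "n_excluded") <- n_excluded
  attr(vt, "n_halfcalls") <- n_half
  vt
}

#' Filter variants on missingness and minor allele frequency
#'
#' Retains SNPs with missingness strictly below `max_missing` and MAF
#' strictly above `min_maf`; remaining missing dosages are replaced by the
#' per-SNP mean dosage (mean-dosage fill).
#'
#' @param vt a `variant_table`
#' @param max_missing maximum tolerated missingness fraction (exclusive).
#' @param min_maf minimum MAF (exclusive).
#' @return a filtered `variant_table` with no missing dosages; attributes
#'   `n_removed_missing` and `n_removed_maf` carry removal counts.
#' @export
filter_variants <- function(vt, max_missing = 0.25, min_maf = 0.05) {
  ok_miss <- vt$missingness < max_missing
  ok_maf <- !is.na(vt$maf) & vt$maf > min_maf
  keep <- which(ok_miss & ok_maf)
  d <- vt$dosage[, keep, drop = FALSE]
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  out <- variant_table(d, vt$chrom[keep], vt$pos[keep], vt$ref[keep], vt$alt[keep])
  attr(out, "n_removed_missing") <- sum(!ok_miss)
  attr(out, "n_removed_maf") <- sum(ok_miss & !ok_maf)
  out
}
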