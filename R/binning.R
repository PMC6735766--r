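#' Read a gene annotation from GFF3
#'
#' Imports gene features from a GFF3 file and returns a plain table of gene
#' intervals (1-based inclusive).
#'
#' @param gff_path path to a GFF3 file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_annotation <- function(gff_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer()))
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) ids <- paste0("gene", seq_along(gr))
  df <- data.frame(gene_id = as.character(ids),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr))
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Assign SNPs to gene bins and intergenic clusters
#'
#' Each SNP is assigned to exactly one bin. A SNP inside a gene body or
#' within `flank` bp of it belongs to that gene's bin; if several genes'
#' flanked intervals cover the SNP it goes to the gene with the nearest body
#' boundary (ties broken by lower gene start). All remaining SNPs fall into
#' intergenic clusters: each maximal gene-free interval (relative to the
#' flanked gene intervals) is tiled with consecutive `cluster_size`-bp
#' windows starting at the interval start, the partial last window kept.
#' Bins containing no SNP are omitted.
#'
#' @param vt a [variant_table()]
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), as from [read_annotation()].
#' @param flank flank width in bp added to both sides of each gene (strand
#'   is ignored).
#' @param cluster_size intergenic window width in bp.
#' @return an object of class `gene_bins`: list with `bins` (data.frame
#'   `bin_id`, `kind`, `chrom`, `start`, `end`, `n_snps`) and `snp_map`
#'   (data.frame `snp_id`, `bin_id`).
#' @export
assign_bins <- function(vt, genes, flank = 2000, cluster_size = 5000) {
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  snp_chroms <- unique(vt$chrom)
  missing_ch <- setdiff(snp_chroms, unique(genes$chrom))
  if (nrow(genes) > 0 && length(missing_ch) > 0)
    warning("no annotation on chromosome(s) ", paste(missing_ch, collapse = ", "),
            "; their SNPs go to intergenic clusters")

  map_bin <- character(length(vt$snp_id))
  bin_rows <- list()

  for (ch in snp_chroms) {
    si <- which(vt$chrom == ch)
    pos <- vt$pos[si]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    assigned <- rep(NA_character_, length(si))

    if (nrow(g) > 0) {
      ext <- IRanges::IRanges(pmax(1L, g$start - flank), g$end + flank)
      hits <- IRanges::findOverlaps(IRanges::IRanges(pos, pos), ext)
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      if (length(qh)) {
        # distance of SNP to the gene BODY (0 if inside)
        d <- pmax(0L, g$start[sh] - pos[qh], pos[qh] - g$end[sh])
        o <- order(qh, d, g$start[sh])
        qh <- qh[o]; sh <- sh[o]
        first <- !duplicated(qh)
        assigned[qh[first]] <- g$gene_id[sh[first]]
      }
    }

    genic <- !is.na(assigned)
    map_bin[si[genic]] <- assigned[genic]
    if (any(genic)) {
      tab <- table(assigned[genic])
      gi <- match(names(tab), g$gene_id)
      bin_rows[[length(bin_rows) + 1L]] <- data.frame(
        bin_id = names(tab), kind = "genic", chrom = ch,
        start = pmax(1L, g$start[gi] - flank), end = g$end[gi] + flank,
        n_snps = as.integer(tab))
    }

    if (any(!genic)) {
      lims <- range(c(pos, if (nrow(g) > 0) c(g$start, g$end)))
      full <- IRanges::IRanges(1L, max(lims) + flank + cluster_size)
      free <- if (nrow(g) > 0) {
        ext <- IRanges::reduce(IRanges::IRanges(pmax(1L, g$start - flank), g$end + flank))
        IRanges::setdiff(full, ext)
      } else full
      fs <- IRanges::start(free); fe <- IRanges::end(free)
      ipos <- pos[!genic]
      iv <- findInterval(ipos, fs)            # which free interval
      stopifnot(all(iv >= 1), all(ipos <= fe[iv]))
      win <- (ipos - fs[iv]) %/% cluster_size # 0-based window within interval
      ws <- fs[iv] + win * cluster_size
      we <- pmin(ws + cluster_size - 1L, fe[iv])
      bid <- sprintf("cluster_%s_%d", ch, ws)
      map_bin[si[!genic]] <- bid
      u <- !duplicated(bid)
      tab <- table(bid)
      bin_rows[[length(bin_rows) + 1L]] <- data.frame(
        bin_id = bid[u], kind = "intergenic_cluster", chrom = ch,
        start = ws[u], end = we[u],
        n_snps = as.integer(tab[bid[u]]))
    }
  }

  bins <- do.call(rbind, bin_rows)
  rownames(bins) <- NULL
  structure(list(
    bins = bins[order(bins$chrom, bins$start), , drop = FALSE],
    snp_map = data.frame(snp_id = vt$snp_id, bin_id = map_bin)
  ), class = "gene_bins")
}

#' @export
print.gene_bins <- function(x, ...) {
  cat(sprintf("gene_bins: %d bins (%d genic, %d intergenic) holding %d SNPs\n",
              nrow(x$bins), sum(x$bins$kind == "genic"),
              sum(x$bins$kind != "genic"), nrow(x$snp_map)))
  invisible(x)
}

#' Greedy LD-pruned SNP sample
#'
#' Scans SNPs in a seeded random order and keeps a SNP only if its squared
#' Pearson dosage correlation with every already-kept SNP on the same
#' chromosome lying within 100 SNPs (in genomic position order) is below
#' `r2_max`. Stops once `target_n` SNPs are kept.
#'
#' @param vt a filled [variant_table()] (no missing dosages).
#' @param r2_max squared-correlation ceiling.
#' @param target_n number of SNPs wanted.
#' @param seed integer seed for the scan order.
#' @param window comparison window in SNPs (genomic order), default 100.
#' @return character vector of kept SNP ids (genomic order).
#' @export
ld_prune_sample <- function(vt, r2_max = 0.2, target_n = 10000, seed = 1,
                            window = 100) {
  m <- n_snps(vt)
  if (m < 2) stop("need at least 2 SNPs")
  # genomic index within chromosome
  gidx <- stats::ave(seq_len(m), vt$chrom, FUN = seq_along)
  d <- vt$dosage
  sds <- apply(d, 2, stats::sd)
  ord <- withr::with_seed(seed, sample.int(m))
  kept <- integer(0)
  kept_by_chrom <- split(integer(0), NULL)
  for (j in ord) {
    if (sds[j] == 0) next
    ch <- vt$chrom[j]
    near <- kept[vt$chrom[kept] == ch & abs(gidx[kept] - gidx[j]) <= window]
    ok <- TRUE
    if (length(near)) {
      r <- suppressWarnings(stats::cor(d[, j], d[, near, drop = FALSE]))
      ok <- all(r^2 < r2_max, na.rm = TRUE)
    }
    if (ok) {
      kept <- c(kept, j)
      if (length(kept) >= target_n) break
    }
  }
  vt$snp_id[sort(kept)]
}

#' Principal component analysis of genotypes
#'
#' Centers dosages per SNP (no scaling) and computes sample scores by
#' singular value decomposition. Component signs are fixed so that each
#' component's largest-magnitude SNP loading is positive.
#'
#' @param vt a filled [variant_table()].
#' @param snp_ids SNPs to use (default all).
#' @param k number of components.
#' @return list of class `pca_result`: `scores` (samples x k),
#'   `var_explained` (length-k fractions of total variance), `snp_ids`.
#' @export
pca_genotypes <- function(vt, snp_ids = NULL, k = 10) {
  if (is.null(snp_ids)) snp_ids <- vt$snp_id
  X <- vt$dosage[, snp_ids, drop = FALSE]
  X <- scale(X, center = TRUE, scale = FALSE)
  n <- nrow(X)
  if (k > min(n - 1, ncol(X))) stop("k exceeds min(samples - 1, #SNPs)")
  sv <- svd(X, nu = k, nv = k)
  for (i in seq_len(k)) {
    top <- which.max(abs(sv$v[, i]))
    if (sv$v[top, i] < 0) { sv$v[, i] <- -sv$v[, i]; sv$u[, i] <- -sv$u[, i] }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(rownames(vt$dosage), paste0("PC", seq_len(k)))
  structure(list(scores = scores,
                 var_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 snp_ids = snp_ids), class = "pca_result")
}
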