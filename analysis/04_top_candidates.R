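#!/usr/bin/env Rscript
# Step 4: gene-based top-candidate scans. For every association scan, SNPs
# in the first percentile of p-values are flagged as outliers; per bin the
# outlier count is compared with the 0.999 quantile of its binomial
# expectation (expected rate = mean outlier proportion over bins with >= 5
# SNPs and >= 1 outlier), and gene-wise binomial p-values are assigned.
# Outputs: results/analysis/topcand_<transect>_<phenotype>.tsv and a
# candidate-count summary.

suppressPackageStartupMessages(library(clinescan))

snp_map <- read.delim("results/analysis/snp_bins.tsv")
bin_tab <- read.delim("results/analysis/bins.tsv")
bins <- structure(list(bins = bin_tab, snp_map = snp_map),
                  class = "gene_bins")

scans <- list.files("results/analysis", pattern = "^scan_", full.names = TRUE)
summary_rows <- list()
for (f in scans) {
  tag <- sub("^scan_", "", sub("\\.tsv$", "", basename(f)))
  assoc <- read.delim(f)
  res <- top_candidate_scan(bins, assoc)
  write.table(res, file.path("results/analysis", paste0("topcand_", tag, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary_rows[[tag]] <- data.frame(
    scan = tag, p_bar = attr(res, "p_bar"),
    n_candidates = sum(res$candidate),
    n_genic = sum(res$candidate & res$kind == "genic"))
}
smry <- do.call(rbind, summary_rows)
write.table(smry, "results/analysis/topcand_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(smry[order(-smry$n_candidates), ], row.names = FALSE)
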