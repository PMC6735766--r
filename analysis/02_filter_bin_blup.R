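#!/usr/bin/env Rscript
# Step 2: read the study back from its interchange formats, apply the
# variant filters (missingness < 25%, MAF > 0.05), assign SNPs to gene bins
# (gene body +/- 2 kb) and 5-kb intergenic clusters, and estimate per-clone
# BLUPs for each trait x garden from the randomized-block design.
# Outputs: results/analysis/bins.tsv, results/analysis/blups.tsv.

suppressPackageStartupMessages(library(clinescan))

sdir <- "results/analysis/study"
vt <- read_genotypes(file.path(sdir, "genotypes.vcf"))
genes <- read_annotation(file.path(sdir, "genes.gff3"))
ph <- read.delim(file.path(sdir, "phenotypes.tsv"))

vt <- filter_variants(vt)
cat(sprintf("retained %d SNPs (%d removed by missingness, %d by MAF)\n",
            n_snps(vt), attr(vt, "n_removed_missing"),
            attr(vt, "n_removed_maf")))

bins <- assign_bins(vt, genes)
print(bins)
write.table(bins$bins, "results/analysis/bins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(bins$snp_map, "results/analysis/snp_bins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rows <- list()
for (gd in unique(ph$garden)) for (tr in unique(ph$trait)) {
  fit <- fit_blups(ph, tr, gd)
  print(fit)
  rows[[paste(tr, gd)]] <- data.frame(clone = names(fit$blup), garden = gd,
                                      trait = tr, blup = unname(fit$blup))
}
write.table(do.call(rbind, rows), "results/analysis/blups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/analysis/{bins,snp_bins,blups}.tsv\n")
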