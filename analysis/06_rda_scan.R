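#!/usr/bin/env Rscript
# Step 6: multilocus genotype-environment association by redundancy
# analysis. Climate predictors are pruned to a weakly correlated subset
# (pairwise |r| < 0.75, priority order = table order); the centered dosage
# matrix is regressed on the standardized predictors and the fitted values
# decomposed by SVD. SNPs whose locus score on any of the first three axes
# lies beyond mean +/- 3 SD are outliers, assigned to their most correlated
# predictor. Enrichment of the generator's planted clinal SNPs is reported.
# Outputs: results/analysis/rda_*_<transect>.tsv.

suppressPackageStartupMessages(library(clinescan))

sdir <- "results/analysis/study"
vt <- filter_variants(read_genotypes(file.path(sdir, "genotypes.vcf")))
samples <- read.delim(file.path(sdir, "samples.tsv"))
climate <- read.delim(file.path(sdir, "climate.tsv"))
truth <- read.delim(file.path(sdir, "truth_causal_snps.tsv"))

clim_vars <- setdiff(colnames(climate),
                     c("provenance", "latitude", "longitude", "elevation"))
kept <- select_predictors(climate[, clim_vars], r_max = 0.75)
cat("retained predictors:", paste(kept, collapse = ", "), "\n")

for (tr in c("lat", "alt")) {
  cl <- samples$clone[samples$transect == tr]
  vtt <- subset_variants(vt, cl)
  pidx <- match(samples$provenance[match(cl, samples$clone)],
                climate$provenance)
  X <- as.matrix(climate[pidx, kept])
  X <- X[, apply(X, 2, sd) > 0, drop = FALSE]
  mod <- fit_rda(vtt, X)
  print(mod)
  out <- rda_outliers(mod, vtt, n_axes = min(3, length(mod$eigenvalues)))
  causal <- vtt$snp_id %in% truth$snp_id[truth$transect == tr]
  hit <- vtt$snp_id %in% out$snp_id
  ft <- fisher.test(table(causal, hit))
  cat(sprintf("%s: %d outlier records; clinal-SNP enrichment OR %.1f (p %.2g)\n",
              tr, nrow(out), ft$estimate, ft$p.value))
  write.table(out, sprintf("results/analysis/rda_outliers_%s.tsv", tr),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(axis = seq_along(mod$eigenvalues),
                         eigenvalue = mod$eigenvalues),
              sprintf("results/analysis/rda_eigenvalues_%s.tsv", tr),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
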