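#!/usr/bin/env Rscript
# Step 1: generate the synthetic two-transect common-garden study.
#
# The generator emulates the design of a range-wide poplar provenance trial:
# 68 latitudinal provenances (4 clones each) and 13 altitudinal provenances
# (13 clones each), genotyped at SNPs housed in annotated genes plus
# intergenic SNPs, phenotyped as 4 ramets x 4 blocks in two common gardens
# (VA, BC), with 21 correlated climate variables per provenance.
# Outputs: VCF + GFF3 + TSVs under results/analysis/study/.

suppressPackageStartupMessages(library(clinescan))

out <- "results/analysis/study"
# causal SNPs are kept sparse relative to the first-percentile flag budget
# (~135 flags vs ~60 causal SNPs) so the expected outlier rate reflects the
# genomic background, as it does at full exome scale
cfg <- sim_config(n_genes = 800, snps_per_gene = 15, n_intergenic_snps = 1500,
                  n_causal_genes_lat = 6, n_causal_genes_alt = 6,
                  n_causal_shared = 3, seed = 42)
st <- simulate_study(cfg)
print(st)
paths <- write_study(st, out)

cat(sprintf("causal genes: %d lat / %d alt (%d shared)\n",
            length(st$truth$causal_genes$lat),
            length(st$truth$causal_genes$alt),
            length(st$truth$shared_genes)))
cat("wrote:\n"); print(unname(paths))
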