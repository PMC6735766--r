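# Canonical climate variable names (ClimateWNA-style annual + derived set)
# with their loadings on the provenance cold/continentality gradient. Signs
# and magnitudes chosen so temperature- and season-length-type variables
# fall and continentality/snow-type variables rise towards cold provenances,
# giving the correlated structure climate scans assume.
.climate_loadings <- c(
  MAT = -1.0, MWMT = -0.8, MCMT = -1.1, TD = 0.9, MAP = 0.5, MSP = 0.3,
  AHM = -0.6, SHM = -0.5, DD_0 = 1.0, DD5 = -0.9, DD_18 = 0.95, DD18 = -0.7,
  NFFD = -0.9, FFP = -0.85, bFFP = 0.8, eFFP = -0.8, PAS = 0.9, EMT = -1.0,
  EXT = -0.6, Eref = -0.7, CMD = -0.4)

#' Configuration for a synthetic two-transect study
#'
#' Defines the design of a simulated common-garden local-adaptation study:
#' clones sampled from provenances along a latitudinal and an altitudinal
#' transect, genotyped at SNPs housed in annotated genes plus intergenic
#' SNPs, phenotyped as replicated ramets in randomized blocks in two
#' gardens, with provenance climate described by 21 correlated variables.
#'
#' @param n_provenances_lat,n_provenances_alt provenance counts per transect.
#' @param clones_per_provenance clones sampled per provenance; length-2
#'   vector `(lat, alt)` or a single count used for both.
#' @param n_gardens,n_blocks,ramets_per_clone common-garden design; each
#'   ramet of a clone is planted in its own block.
#' @param n_genes number of annotated genes.
#' @param snps_per_gene mean SNPs per gene (Poisson, floored at 1).
#' @param n_intergenic_snps SNPs placed at least 2 kb from any gene.
#' @param fst Balding-Nichols differentiation parameter in (0, 1).
#' @param n_causal_genes_lat,n_causal_genes_alt,n_causal_shared causal gene
#'   counts per transect and shared between them (`n_causal_shared` genes
#'   are counted inside both transect totals).
#' @param causal_snps_per_gene causal (clinal) SNPs planted per causal gene,
#'   capped at the gene's SNP count. The default of 10 emulates the elevated
#'   within-gene LD of a selected haplotype, where most SNPs in the gene
#'   track the adaptive cline rather than a single causal site.
#' @param cline_slope allele-frequency change of causal SNPs per unit of the
#'   standardized gradient (latitude or elevation scaled to [-1, 1]).
#' @param effect_size_sd standard deviation of per-SNP trait effects.
#' @param climate_effect coefficient of the provenance gradient in the clone
#'   value (provenance-of-origin climate term; confounds trait with
#'   structure).
#' @param h2_clone clone-level repeatability in (0, 1]: fraction of
#'   within-garden phenotypic variance attributable to clones.
#' @param climate_noise_sd per-variable noise sd of climate variables
#'   (gradient loadings have magnitude about 1).
#' @param missing_rate fraction of genotype calls set missing.
#' @param seed integer seed; identical seeds give bit-identical studies.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_provenances_lat = 68, n_provenances_alt = 13,
                       clones_per_provenance = c(4, 13),
                       n_gardens = 2, n_blocks = 4, ramets_per_clone = 4,
                       n_genes = 300, snps_per_gene = 15,
                       n_intergenic_snps = 1000, fst = 0.15,
                       n_causal_genes_lat = 20, n_causal_genes_alt = 20,
                       n_causal_shared = 10, causal_snps_per_gene = 10,
                       cline_slope = 0.35, effect_size_sd = 0.3,
                       climate_effect = 0.3, h2_clone = 0.6,
                       climate_noise_sd = 0.3, missing_rate = 0, seed = 1) {
  cfg <- as.list(environment())
  if (length(cfg$clones_per_provenance) == 1)
    cfg$clones_per_provenance <- rep(cfg$clones_per_provenance, 2)
  counts <- c(n_provenances_lat, n_provenances_alt, cfg$clones_per_provenance,
              n_gardens, n_blocks, ramets_per_clone, n_genes, snps_per_gene)
  if (any(counts <= 0)) stop("all design counts must be > 0")
  if (fst <= 0 || fst >= 1) stop("fst must lie in (0, 1)")
  if (h2_clone <= 0 || h2_clone > 1) stop("h2_clone must lie in (0, 1]")
  if (n_causal_shared > min(n_causal_genes_lat, n_causal_genes_alt))
    stop("n_causal_shared exceeds a transect's causal gene count")
  if (n_causal_genes_lat + n_causal_genes_alt - n_causal_shared > n_genes)
    stop("causal genes exceed n_genes")
  class(cfg) <- "sim_config"
  cfg
}

# gene/SNP coordinate layout: genes in tandem with >= 2*flank + free space
# between them so intergenic SNPs can sit > 2 kb from every gene
.sim_layout <- function(cfg) {
  n_chrom <- max(1L, ceiling(cfg$n_genes / 500))
  per <- ceiling(cfg$n_genes / n_chrom)
  chrom <- rep(sprintf("chr%02d", seq_len(n_chrom)), each = per)[seq_len(cfg$n_genes)]
  glen <- sample(1000:4000, cfg$n_genes, replace = TRUE)
  gap <- 12000L  # leaves a ~8 kb gene-free core between flanked genes
  start <- unlist(lapply(split(glen, factor(chrom, levels = unique(chrom))), function(l) {
    cumsum(c(5000L, utils::head(l, -1) + gap))
  }), use.names = FALSE)
  genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
                      chrom = chrom, start = start, end = start + glen - 1L)
  # genic SNPs inside gene bodies
  nsnp <- pmax(1L, stats::rpois(cfg$n_genes, cfg$snps_per_gene))
  gsnp <- data.frame(
    chrom = rep(genes$chrom, nsnp),
    pos = unlist(mapply(function(s, e, k) sort(sample(s:e, min(k, e - s + 1))),
                        genes$start, genes$end, nsnp, SIMPLIFY = FALSE)),
    gene = rep(genes$gene_id, nsnp))
  # intergenic SNPs: centred in inter-gene gaps, > 2 kb from both neighbours
  igap <- do.call(rbind, lapply(split(genes, genes$chrom), function(g) {
    lo <- g$end[-nrow(g)] + 2500L; hi <- g$start[-1] - 2500L
    data.frame(chrom = g$chrom[1], lo = lo, hi = hi)
  }))
  pick <- sample(nrow(igap), cfg$n_intergenic_snps, replace = TRUE)
  isnp <- data.frame(
    chrom = igap$chrom[pick],
    pos = igap$lo[pick] +
      floor(stats::runif(cfg$n_intergenic_snps) * (igap$hi[pick] - igap$lo[pick] + 1)),
    gene = NA_character_)
  snps <- rbind(gsnp, isnp)
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  dup <- duplicated(paste(snps$chrom, snps$pos))
  snps <- snps[!dup, , drop = FALSE]
  snps$snp_id <- sprintf("snp%06d", seq_len(nrow(snps)))
  list(genes = genes, snps = snps)
}

#' Simulate a two-transect local-adaptation study
#'
#' Generates genotypes, gene annotation, replicated common-garden phenotype
#' observations, provenance climate, and the causal ground truth. Neutral
#' provenance allele frequencies follow a Balding-Nichols model: ancestral
#' frequency p ~ Uniform(0.05, 0.95), provenance frequency
#' ~ Beta(p(1-F)/F, (1-p)(1-F)/F). Causal SNPs instead follow a linear
#' cline in latitude (latitudinal transect) or elevation (altitudinal
#' transect). Genotypes are Binomial(2, p) draws. A phenotype observation is
#' grand mean + block effect + clone value + residual; the clone value is
#' the dosage-weighted sum of causal effects plus a provenance climate term,
#' and the residual scale is set so the clone-level repeatability equals
#' `h2_clone`.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_study` with elements `variants`
#'   ([variant_table()]), `genes` (annotation data.frame), `phenotypes`
#'   (data.frame clone/garden/block/ramet/trait/value), `climate`
#'   (provenance climate data.frame), `samples` (clone metadata), `truth`
#'   (causal SNPs/genes, provenance positions, true clone values), `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, .simulate_study_impl(cfg))
}

.simulate_study_impl <- function(cfg) {
  lay <- .sim_layout(cfg)
  snps <- lay$snps; genes <- lay$genes
  m <- nrow(snps)

  # provenances
  np_lat <- cfg$n_provenances_lat; np_alt <- cfg$n_provenances_alt
  prov <- data.frame(
    provenance = c(sprintf("L%03d", seq_len(np_lat)), sprintf("A%03d", seq_len(np_alt))),
    transect = rep(c("lat", "alt"), c(np_lat, np_alt)),
    latitude = c(seq(34, 60, length.out = np_lat),
                 49.8 + stats::runif(np_alt, -0.3, 0.3)),
    longitude = -122 + stats::rnorm(np_lat + np_alt, 0, 1.5),
    elevation = c(round(stats::runif(np_lat, 20, 400)),
                  round(seq(100, 1500, length.out = np_alt))))
  npv <- nrow(prov)
  # standardized gradient in [-1, 1] within each transect
  grad <- numeric(npv)
  il <- prov$transect == "lat"; ia <- !il
  rng <- function(x) if (diff(range(x)) == 0) rep(0, length(x)) else
    2 * (x - min(x)) / diff(range(x)) - 1
  grad[il] <- rng(prov$latitude[il])
  grad[ia] <- rng(prov$elevation[ia])
  prov$gradient <- grad

  # causal gene / SNP assignment
  genic_genes <- unique(snps$gene[!is.na(snps$gene)])
  n_lat <- cfg$n_causal_genes_lat; n_alt <- cfg$n_causal_genes_alt
  n_sh <- cfg$n_causal_shared
  pick <- sample(genic_genes, n_lat + n_alt - n_sh)
  shared <- pick[seq_len(n_sh)]
  lat_genes <- pick[seq_len(n_lat)]
  alt_genes <- c(shared, pick[seq(n_lat + 1, length.out = n_alt - n_sh)])
  pick_snps <- function(gs) unlist(lapply(gs, function(g) {
    ids <- snps$snp_id[!is.na(snps$gene) & snps$gene == g]
    sample(ids, min(cfg$causal_snps_per_gene, length(ids)))
  }), use.names = FALSE)
  lat_snps <- pick_snps(lat_genes)
  # shared genes reuse the SAME causal SNPs in both transects
  shared_snp_ids <- unlist(lapply(shared, function(g)
    lat_snps[snps$gene[match(lat_snps, snps$snp_id)] == g]), use.names = FALSE)
  alt_only <- setdiff(alt_genes, shared)
  alt_snps <- c(shared_snp_ids, pick_snps(alt_only))

  # Balding-Nichols provenance frequencies
  p0 <- stats::runif(m, 0.05, 0.95)
  f <- cfg$fst
  a <- p0 * (1 - f) / f; b <- (1 - p0) * (1 - f) / f
  pf <- matrix(stats::rbeta(npv * m, rep(a, each = npv), rep(b, each = npv)),
               nrow = npv, ncol = m)
  # clinal overwrite for causal SNPs (within their own transect only)
  clip <- function(x) pmin(0.98, pmax(0.02, x))
  jl <- match(lat_snps, snps$snp_id)
  pf[il, jl] <- clip(rep(p0[jl], each = sum(il)) +
                       cfg$cline_slope * outer(grad[il], rep(1, length(jl))))
  ja <- match(alt_snps, snps$snp_id)
  pf[ia, ja] <- clip(rep(p0[ja], each = sum(ia)) +
                       cfg$cline_slope * outer(grad[ia], rep(1, length(ja))))

  # clones and genotypes
  cpp <- rep(cfg$clones_per_provenance[1], npv)
  cpp[ia] <- cfg$clones_per_provenance[2]
  samples <- data.frame(
    clone = sprintf("cl%04d", seq_len(sum(cpp))),
    provenance = rep(prov$provenance, cpp),
    transect = rep(prov$transect, cpp))
  n <- nrow(samples)
  pidx <- rep(seq_len(npv), cpp)
  dos <- matrix(stats::rbinom(n * m, 2L, pf[pidx, ]), nrow = n, ncol = m,
                dimnames = list(samples$clone, snps$snp_id))
  if (cfg$missing_rate > 0) {
    nm <- round(cfg$missing_rate * length(dos))
    dos[sample(length(dos), nm)] <- NA_real_
  }

  # effects and clone values (per transect)
  eff_lat <- stats::rnorm(length(lat_snps), 0, cfg$effect_size_sd)
  eff_alt <- stats::rnorm(length(alt_snps), 0, cfg$effect_size_sd)
  g_clone <- prov$gradient[pidx]
  val <- numeric(n)
  d0 <- dos; d0[is.na(d0)] <- 0  # truth uses the drawn genotypes
  ilc <- samples$transect == "lat"
  val[ilc] <- d0[ilc, jl, drop = FALSE] %*% eff_lat + cfg$climate_effect * g_clone[ilc]
  val[!ilc] <- d0[!ilc, ja, drop = FALSE] %*% eff_alt + cfg$climate_effect * g_clone[!ilc]

  v_g <- stats::var(val)
  base <- if (v_g == 0) 1 else v_g
  dev_sd <- sqrt(base * (1 - cfg$h2_clone))
  val <- val + stats::rnorm(n, 0, dev_sd)
  v_c <- if (cfg$h2_clone == 1) v_g else stats::var(val)
  eps_sd <- sqrt(v_c * (1 - cfg$h2_clone) / cfg$h2_clone)

  # common-garden observations: ramet i of a clone sits in block i
  gardens <- c("VA", "BC")[seq_len(cfg$n_gardens)]
  obs <- expand.grid(clone = samples$clone, garden = gardens,
                     ramet = seq_len(cfg$ramets_per_clone),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  obs$block <- ((obs$ramet - 1) %% cfg$n_blocks) + 1L
  blk <- stats::rnorm(cfg$n_gardens * cfg$n_blocks, 0, sqrt(0.25 * max(v_c, base)))
  dim(blk) <- c(cfg$n_gardens, cfg$n_blocks)
  obs$trait <- "height"
  obs$value <- 10 + blk[cbind(match(obs$garden, gardens), obs$block)] +
    val[match(obs$clone, samples$clone)] +
    stats::rnorm(nrow(obs), 0, eps_sd)
  obs <- obs[order(obs$garden, obs$clone, obs$ramet),
             c("clone", "garden", "block", "ramet", "trait", "value")]
  rownames(obs) <- NULL

  # climate: loadings on the cold gradient; lat transect centred colder
  cold <- numeric(npv)
  cold[il] <- rng(prov$latitude[il]); cold[ia] <- rng(prov$elevation[ia])
  cv <- sapply(names(.climate_loadings), function(v)
    .climate_loadings[[v]] * cold + stats::rnorm(npv, 0, cfg$climate_noise_sd))
  climate <- cbind(prov[, c("provenance", "latitude", "longitude", "elevation")],
                   as.data.frame(cv))

  truth <- list(
    causal_snps = list(lat = data.frame(snp_id = lat_snps, effect = eff_lat),
                       alt = data.frame(snp_id = alt_snps, effect = eff_alt)),
    causal_genes = list(lat = lat_genes, alt = alt_genes),
    shared_genes = shared,
    provenance_positions = prov,
    true_clone_values = stats::setNames(val, samples$clone))

  structure(list(
    variants = variant_table(dos, snps$chrom, snps$pos),
    genes = genes, phenotypes = obs, climate = climate,
    samples = samples, truth = truth, config = cfg
  ), class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("sim_study: %d clones (%d lat / %d alt), %d SNPs, %d genes\n",
              nrow(x$samples), sum(x$samples$transect == "lat"),
              sum(x$samples$transect == "alt"), n_snps(x$variants),
              nrow(x$genes)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits genotypes as plain VCFv4.2, annotation as GFF3, and phenotypes,
#' climate, sample metadata, and causal truth as TSV. The files round-trip
#' losslessly through [read_genotypes()] and [read_annotation()].
#'
#' @param study a `sim_study` from [simulate_study()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a named vector of file paths.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             gff = file.path(out_dir, "genes.gff3"),
             phenotypes = file.path(out_dir, "phenotypes.tsv"),
             climate = file.path(out_dir, "climate.tsv"),
             samples = file.path(out_dir, "samples.tsv"),
             truth_snps = file.path(out_dir, "truth_causal_snps.tsv"))
  write_vcf(study$variants, paths["vcf"])
  write_gff3(study$genes, paths["gff"])
  tsv <- function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  tsv(study$phenotypes, paths["phenotypes"])
  tsv(study$climate, paths["climate"])
  tsv(study$samples, paths["samples"])
  cs <- rbind(cbind(transect = "lat", study$truth$causal_snps$lat),
              cbind(transect = "alt", study$truth$causal_snps$alt))
  tsv(cs, paths["truth_snps"])
  invisible(paths)
}

#' Write a variant table as VCFv4.2
#'
#' @param vt a [variant_table()].
#' @param path output path (plain text).
#' @export
write_vcf <- function(vt, path) {
  gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  g <- matrix(gt[as.character(t(vt$dosage))], nrow = n_snps(vt))
  g[is.na(g)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(vt$dosage)), collapse = "\t"))
  body <- paste(vt$chrom, vt$pos, vt$snp_id, vt$ref, vt$alt, ".", "PASS",
                ".", "GT", apply(g, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
}

#' Write a gene annotation as GFF3
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  if (nrow(genes) > 0)
    lines <- c(lines, paste(genes$chrom, "clinescan", "gene", genes$start,
                            genes$end, ".", "+", ".",
                            paste0("ID=", genes$gene_id), sep = "\t"))
  writeLines(lines, path)
}
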