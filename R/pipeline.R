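#' Configuration for a full two-transect analysis run
#'
#' Either `sim` (a [sim_config()]) or `inputs` (paths to a VCF, a GFF3, a
#' phenotype TSV, a climate TSV and a sample-metadata TSV) must be given.
#'
#' @param sim a [sim_config()] to generate the study, or `NULL`.
#' @param inputs named list of paths (`vcf`, `gff`, `phenotypes`, `climate`,
#'   `samples`), or `NULL`.
#' @param out_dir output directory for TSV results and the run log.
#' @param max_missing,min_maf variant filters (see [filter_variants()]).
#' @param flank,cluster_size binning parameters (see [assign_bins()]).
#' @param pc_counts numbers of principal components tried as covariates.
#' @param lambda_window lambda_GC acceptance window for model selection.
#' @param outlier_quantile per-SNP outlier fraction for the gene scan.
#' @param binom_q binomial quantile of the top-candidate rule.
#' @param panel_size control panel size for the null-W test.
#' @param alpha FDR level for parallel outliers.
#' @param ld_r2,ld_target LD pruning parameters for the structure PCA.
#' @param rda_axes,rda_sd,rda_rmax RDA scan parameters.
#' @param run_mlm whether kinship-based models enter model selection
#'   (mixed-model scans dominate runtime on large SNP sets).
#' @param seed master seed; every stochastic step derives from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), inputs = NULL,
                            out_dir = tempfile("clinescan_run_"),
                            max_missing = 0.25, min_maf = 0.05,
                            flank = 2000, cluster_size = 5000,
                            pc_counts = c(2, 5, 10),
                            lambda_window = c(0.98, 1.22),
                            outlier_quantile = 0.01, binom_q = 0.999,
                            panel_size = 10000, alpha = 0.05,
                            ld_r2 = 0.2, ld_target = 10000,
                            rda_axes = 3, rda_sd = 3, rda_rmax = 0.75,
                            run_mlm = TRUE, seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$sim) && is.null(cfg$inputs))
    stop("either a simulation config or input paths are required")
  if (!is.null(cfg$inputs)) {
    need <- c("vcf", "gff", "phenotypes", "climate", "samples")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss)) stop("missing input path(s): ", paste(miss, collapse = ", "))
    absent <- unlist(cfg$inputs[need])[!file.exists(unlist(cfg$inputs[need]))]
    if (length(absent)) stop("input file(s) not found: ",
                             paste(absent, collapse = ", "))
  }
  stopifnot(cfg$outlier_quantile > 0, cfg$outlier_quantile < 1,
            cfg$binom_q > 0, cfg$binom_q < 1, cfg$alpha > 0, cfg$alpha <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

# association scans under all candidate structure models for one phenotype;
# returns the selected model's scan plus the per-model lambdas
.scan_with_model_selection <- function(vt, phen, pcs, K, cfg) {
  scans <- list(simple = glm_scan(vt, phen))
  for (k in cfg$pc_counts)
    scans[[paste0("PC", k)]] <- glm_scan(vt, phen, pcs[, seq_len(k), drop = FALSE])
  if (cfg$run_mlm && !is.null(K)) {
    scans[["K"]] <- mlm_scan(vt, phen, NULL, K)
    scans[["PC2+K"]] <- mlm_scan(vt, phen, pcs[, 1:2, drop = FALSE], K)
  }
  lambdas <- vapply(scans, function(s) lambda_gc(s$p), numeric(1))
  sel <- select_model(lambdas, cfg$lambda_window)
  list(assoc = scans[[sel$model]], model = sel$model, lambda = sel$lambda,
       in_window = sel$in_window, lambdas = lambdas)
}

#' Run the full two-transect local-adaptation analysis
#'
#' Executes simulate (or read) -> filter -> bin -> BLUP -> structure PCA and
#' kinship -> model-selected GWAS per trait -> Spearman climate scans ->
#' gene-based top-candidate scans -> null-W parallelism tests in both
#' directions -> RDA outlier scans -> hypergeometric overlap tests, and
#' writes every result as TSV under `cfg$out_dir` together with a run log
#' recording the effective parameters and seed.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with the main result objects: `study`, `bins`,
#'   `scans` (per transect, per phenotype/climate variable), `candidates`,
#'   `nullw`, `overlaps`, `rda`, `paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(d, file.path(cfg$out_dir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  log_lines <- c(sprintf("clinescan %s", as.character(utils::packageVersion("clinescan"))),
                 sprintf("seed: %d", cfg$seed))

  # ---- inputs ----
  if (!is.null(cfg$sim)) {
    study <- simulate_study(cfg$sim)
    genes <- study$genes
    vt <- study$variants
    phenotypes <- study$phenotypes
    climate <- study$climate
    samples <- study$samples
    log_lines <- c(log_lines, "input: simulated study",
                   sprintf("  sim seed: %d", cfg$sim$seed))
  } else {
    vt <- read_genotypes(cfg$inputs$vcf)
    genes <- read_annotation(cfg$inputs$gff)
    phenotypes <- utils::read.delim(cfg$inputs$phenotypes)
    climate <- utils::read.delim(cfg$inputs$climate)
    samples <- utils::read.delim(cfg$inputs$samples)
    study <- list(variants = vt, genes = genes, phenotypes = phenotypes,
                  climate = climate, samples = samples)
    log_lines <- c(log_lines, sprintf("input: %s", cfg$inputs$vcf))
  }

  # ---- filter + bin ----
  vt <- filter_variants(vt, cfg$max_missing, cfg$min_maf)
  bins <- assign_bins(vt, genes, cfg$flank, cfg$cluster_size)
  n_bins <- nrow(bins$bins)
  log_lines <- c(log_lines,
                 sprintf("filtered SNPs: %d (removed %d missingness, %d MAF)",
                         n_snps(vt), attr(vt, "n_removed_missing"),
                         attr(vt, "n_removed_maf")),
                 sprintf("bins: %d", n_bins))
  tsv(bins$bins, "bins.tsv")

  climate_vars <- setdiff(colnames(climate),
                          c("provenance", "latitude", "longitude", "elevation"))
  transects <- intersect(c("lat", "alt"), unique(samples$transect))
  scans <- list(); candidates <- list(); model_log <- list()

  for (tr in transects) {
    cl <- samples$clone[samples$transect == tr]
    vtt <- subset_variants(vt, cl)
    # structure: LD-pruned PCA and kinship
    pruned <- ld_prune_sample(vtt, cfg$ld_r2, cfg$ld_target,
                              seed = cfg$seed + 11)
    pcs <- pca_genotypes(vtt, pruned, k = max(cfg$pc_counts))$scores
    K <- if (cfg$run_mlm) kinship_matrix(vtt) else NULL
    tsv(data.frame(clone = rownames(pcs), pcs),
        sprintf("pca_scores_%s.tsv", tr))

    # phenotype scans: BLUPs per trait x garden
    ph <- phenotypes[phenotypes$clone %in% cl, , drop = FALSE]
    for (trait in unique(ph$trait)) for (gd in unique(ph$garden)) {
      bl <- fit_blups(ph, trait, gd)
      phen <- bl$blup[match(cl, names(bl$blup))]
      keep <- which(!is.na(phen))
      sel <- .scan_with_model_selection(subset_variants(vtt, keep),
                                        unname(phen[keep]),
                                        pcs[keep, , drop = FALSE],
                                        if (is.null(K)) NULL else K[keep, keep],
                                        cfg)
      tag <- sprintf("%s_%s", trait, gd)
      scans[[tr]][[tag]] <- sel$assoc
      model_log[[length(model_log) + 1L]] <-
        data.frame(transect = tr, phenotype = tag, model = sel$model,
                   lambda = sel$lambda, in_window = sel$in_window)
      candidates[[tr]][[tag]] <- top_candidate_scan(bins, sel$assoc,
                                                    cfg$outlier_quantile,
                                                    cfg$binom_q)
    }

    # climate scans: provenance value propagated to clones
    pidx <- match(samples$provenance[match(cl, samples$clone)],
                  climate$provenance)
    for (cv in climate_vars) {
      vals <- climate[[cv]][pidx]
      sc <- spearman_climate_scan(vtt, vals)
      scans[[tr]][[cv]] <- sc
      candidates[[tr]][[cv]] <- top_candidate_scan(bins, sc,
                                                   cfg$outlier_quantile,
                                                   cfg$binom_q)
    }

    for (nm in names(candidates[[tr]]))
      tsv(candidates[[tr]][[nm]], sprintf("topcand_%s_%s.tsv", tr, nm))
  }
  tsv(do.call(rbind, model_log), "selected_models.tsv")

  # ---- null-W parallelism, both directions ----
  nullw <- list()
  if (length(transects) == 2) {
    for (dir_ab in list(c("lat", "alt"), c("alt", "lat"))) {
      a <- dir_ab[1]; b <- dir_ab[2]
      for (nm in intersect(names(candidates[[a]]), names(scans[[b]]))) {
        cand_a <- candidates[[a]][[nm]]
        cand_ids <- cand_a$bin_id[cand_a$candidate]
        if (length(cand_ids) == 0) next
        cand_b_ids <- candidates[[b]][[nm]]$bin_id[candidates[[b]][[nm]]$candidate]
        panel <- build_control_panel(bins, scans[[b]][[nm]], cand_b_ids,
                                     cfg$panel_size, seed = cfg$seed + 23)
        nz <- null_z_distribution(bins, scans[[b]][[nm]], panel, cand_b_ids)
        res <- nullw_test(cand_ids, bins, scans[[b]][[nm]], panel, nz,
                          cfg$alpha)
        key <- sprintf("%s_to_%s_%s", a, b, nm)
        nullw[[key]] <- res
        tsv(res, sprintf("nullw_%s.tsv", key))
      }
    }
  }

  # ---- direct-overlap hypergeometric tests ----
  overlaps <- NULL
  if (length(transects) == 2) {
    common <- intersect(names(candidates$lat), names(candidates$alt))
    overlaps <- do.call(rbind, lapply(common, function(nm) {
      ca <- candidates$lat[[nm]]; cb <- candidates$alt[[nm]]
      A <- ca$bin_id[ca$candidate]; B <- cb$bin_id[cb$candidate]
      k <- length(intersect(A, B))
      ht <- hypergeom_overlap(n_bins, length(A), length(B), k)
      data.frame(phenotype = nm, n_lat = length(A), n_alt = length(B),
                 overlap = k, p = ht$p)
    }))
    tsv(overlaps, "overlap_tests.tsv")
  }

  # ---- RDA per transect ----
  rda <- list()
  pred_vars <- select_predictors(
    climate[, climate_vars, drop = FALSE], cfg$rda_rmax)
  for (tr in transects) {
    cl <- samples$clone[samples$transect == tr]
    vtt <- subset_variants(vt, cl)
    pidx <- match(samples$provenance[match(cl, samples$clone)],
                  climate$provenance)
    Xp <- as.matrix(climate[pidx, pred_vars, drop = FALSE])
    Xp <- Xp[, apply(Xp, 2, stats::sd) > 0, drop = FALSE]
    model <- fit_rda(vtt, Xp)
    out <- rda_outliers(model, vtt, min(cfg$rda_axes, length(model$eigenvalues)),
                        cfg$rda_sd)
    rda[[tr]] <- list(model = model, outliers = out)
    tsv(out, sprintf("rda_outliers_%s.tsv", tr))
    tsv(data.frame(axis = seq_along(model$eigenvalues),
                   eigenvalue = model$eigenvalues),
        sprintf("rda_eigenvalues_%s.tsv", tr))
  }
  log_lines <- c(log_lines,
                 sprintf("rda predictors: %s", paste(pred_vars, collapse = ", ")),
                 sprintf("finished: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))

  invisible(list(study = study, variants = vt, bins = bins, scans = scans,
                 candidates = candidates, nullw = nullw, overlaps = overlaps,
                 rda = rda, models = do.call(rbind, model_log),
                 out_dir = cfg$out_dir))
}

#' Single-variable climate parallelism analysis
#'
#' Focused driver for power and calibration studies: filters and bins a
#' simulated study, runs the Spearman scan of one climate variable in each
#' transect, performs the gene-based top-candidate scan, and applies the
#' null-W test in the requested directions. Much lighter than
#' [run_pipeline()] when only one association score is needed.
#'
#' @param study a `sim_study` from [simulate_study()].
#' @param variable climate variable name, default `"MAT"`.
#' @param outlier_quantile,binom_q,panel_size,alpha scan and test
#'   parameters as in [pipeline_config()].
#' @param seed seed for the control panel draw.
#' @param directions list of `c(from, to)` transect pairs to test.
#' @return list: `bins`, per-transect `scans` and `candidates`, and `nullw`
#'   (one `nullw_result` per direction, named `"lat_to_alt"` etc.; `NULL`
#'   when a direction has no candidates).
#' @export
climate_nullw_analysis <- function(study, variable = "MAT",
                                   outlier_quantile = 0.01, binom_q = 0.999,
                                   panel_size = 10000, alpha = 0.05, seed = 1,
                                   directions = list(c("lat", "alt"),
                                                     c("alt", "lat"))) {
  vt <- filter_variants(study$variants)
  bins <- assign_bins(vt, study$genes)
  scans <- list(); cands <- list()
  for (tr in c("lat", "alt")) {
    cl <- study$samples$clone[study$samples$transect == tr]
    vtt <- subset_variants(vt, cl)
    pidx <- match(study$samples$provenance[match(cl, study$samples$clone)],
                  study$climate$provenance)
    scans[[tr]] <- spearman_climate_scan(vtt, study$climate[[variable]][pidx])
    cands[[tr]] <- top_candidate_scan(bins, scans[[tr]], outlier_quantile,
                                      binom_q)
  }
  nullw <- list()
  for (ab in directions) {
    a <- ab[1]; b <- ab[2]
    ids <- cands[[a]]$bin_id[cands[[a]]$candidate]
    key <- sprintf("%s_to_%s", a, b)
    if (length(ids) == 0) { nullw[key] <- list(NULL); next }
    cb <- cands[[b]]$bin_id[cands[[b]]$candidate]
    panel <- build_control_panel(bins, scans[[b]], cb, panel_size,
                                 seed = seed)
    nz <- null_z_distribution(bins, scans[[b]], panel, cb)
    nullw[[key]] <- nullw_test(ids, bins, scans[[b]], panel, nz, alpha)
  }
  list(bins = bins, scans = scans, candidates = cands, nullw = nullw)
}
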