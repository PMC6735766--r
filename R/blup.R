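#' Clone BLUPs from a randomized-block common-garden design
#'
#' Fits the mixed model y = mu + block + clone + error with block and clone
#' as independent random effects, by REML, and returns the empirical BLUPs
#' of the clone effects. Gardens are analysed separately; the BLUPs are the
#' phenotypes used by the association scans.
#'
#' @param obs phenotype observations: data.frame with columns `clone`,
#'   `garden`, `block`, `ramet`, `trait`, `value`.
#' @param trait trait name to fit.
#' @param garden garden id to fit.
#' @return list of class `blup_table`: `blup` (named numeric, clone BLUPs),
#'   `varcomp` (sigma2_block, sigma2_clone, sigma2_resid), `grand_mean`,
#'   `trait`, `garden`, `n_obs`.
#' @export
fit_blups <- function(obs, trait, garden) {
  d <- obs[obs$trait == trait & obs$garden == garden, , drop = FALSE]
  d <- d[is.finite(d$value), , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for ", trait, " in garden ", garden)
  if (length(unique(d$clone)) < 2 || length(unique(d$block)) < 2)
    stop("degenerate design: need at least 2 clones and 2 blocks")
  d$clone <- factor(d$clone)
  d$block <- factor(d$block)
  fit <- lme4::lmer(value ~ 1 + (1 | block) + (1 | clone), data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get <- function(g) { i <- match(g, vc$grp); if (is.na(i)) 0 else vc$vcov[i] }
  re <- lme4::ranef(fit)$clone
  blup <- stats::setNames(re[["(Intercept)"]], rownames(re))
  structure(list(
    blup = blup,
    varcomp = c(sigma2_block = get("block"), sigma2_clone = get("clone"),
                sigma2_resid = get("Residual")),
    grand_mean = unname(lme4::fixef(fit)[1]),
    trait = trait, garden = garden, n_obs = nrow(d)
  ), class = "blup_table")
}

#' @export
print.blup_table <- function(x, ...) {
  cat(sprintf("blup_table: %s in %s, %d clones (%d obs)\n", x$trait, x$garden,
              length(x$blup), x$n_obs))
  v <- x$varcomp
  cat(sprintf("  sigma2 block %.3g, clone %.3g, resid %.3g; grand mean %.3g\n",
              v[1], v[2], v[3], x$grand_mean))
  invisible(x)
}
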