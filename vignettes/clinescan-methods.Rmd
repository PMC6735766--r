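---
title: "Gene-based scans for local adaptation and parallelism: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based scans for local adaptation and parallelism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clinescan` analyses two-transect common-garden studies of local
adaptation: clones sampled along a latitudinal and an altitudinal gradient,
genotyped at exome-scale SNPs, phenotyped in replicated randomized-block
gardens, and matched to provenance climate. This vignette documents the
statistical models, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical and design decisions
behind the implementation.

## Phenotypes: clone BLUPs

Each trait in each garden is modelled as
$$y_{ijk} = \mu + b_i + c_j + \varepsilon_{ijk},$$
with random block effects $b_i$, random clone effects $c_j$, and
i.i.d. residuals. `fit_blups()` fits this by REML via `lme4::lmer` and
returns the empirical BLUPs of $c_j$, which serve as the GWAS phenotypes.
Gardens are fitted separately (producing e.g. `height_VA` and `height_BC`
phenotypes); we do not pool gardens because garden-specific error variances
and block structures make within-garden shrinkage the cleaner estimate.
BLUPs are shrinkage estimates: their variance never exceeds that of raw
clone means, and in a balanced noise-free design they are proportional to
centered clone means — both properties are tested.

## Association scans and structure correction

`glm_scan()` regresses the phenotype on each SNP's dosage plus covariates
by OLS and reports the dosage coefficient, its two-sided t-test p-value,
and $r^2$, the squared partial correlation of dosage and phenotype given
the covariates. The partial correlation is computed by residualizing both
phenotype and dosages on the covariates (Frisch–Waugh), which vectorizes
across all SNPs.

`mlm_scan()` adds a polygenic random effect with covariance
$\sigma^2_g K$, where $K$ is the centered (VanRaden-type) genomic
relationship matrix $W W^\top / (2\sum_m p_m(1-p_m))$, $W$ the
mean-centered dosage matrix. The model is solved in the eigenbasis of $K$;
the variance ratio $\delta = \sigma^2_e/\sigma^2_g$ is estimated once by
REML on the null (no-SNP) model and held fixed across SNPs — the standard
EMMAX-style approximation, trading exactness per SNP for a three-orders-of-
magnitude speedup. With $K = I$ the mixed scan reduces to the OLS scan
(tested to 1e-6).

Structure correction is chosen by the genomic inflation factor
$\lambda_{GC}$ = median of the $\chi^2_1$-transformed p-values divided by
0.4549364 (the $\chi^2_1$ median; we fix the constant rather than calling
`qchisq(0.5, 1)` each time so the definition is explicit). Candidate models
are ranked simple < PC2 < PC5 < PC10 < K < PC2+K, and the most parsimonious
model with $\lambda_{GC} \in [0.98, 1.22]$ wins; if none qualifies the
nearest model is returned with a warning. The window endpoints are the
conventional compromise between residual confounding (upper bound) and
overcorrection (lower bound) for polygenic traits with dense, linked SNPs.

Genotype–environment association uses per-SNP Spearman rank correlation
(`spearman_climate_scan()`), with the provenance climate value propagated
to its clones, midranks for ties, $\rho^2$ as the score, and the asymptotic
t-approximation for the two-sided p-value. Because filled dosages are
discrete {0, 1, 2}, the rank transform is computed in closed form from the
three genotype counts, making a 40,000-SNP scan a handful of matrix
products. A Bayesian allele-frequency–environment model would be an
alternative scan on the same gene-based machinery; the rank correlation was
chosen as a dependency-free, deterministic statistic whose squared value
plays the same role downstream.

## The top-candidate test

SNPs are assigned to bins by `assign_bins()`: a SNP inside a gene body or
within 2 kb of it belongs to that gene; a SNP covered by two flanked genes
goes to the nearer gene body (ties to the lower start coordinate — the
choice is arbitrary but deterministic); all remaining SNPs fall into 5-kb
windows tiled from the start of each maximal gene-free interval. Strand is
ignored: the flank is symmetric.

For one scan, `flag_outlier_snps()` marks exactly $\lceil 0.01 M \rceil$
SNPs (ties broken by p then SNP id), `expected_outlier_rate()` computes
$\bar p$ as the mean outlier proportion over bins with at least five SNPs
and at least one outlier, and `scan_genes()` classifies a bin with $n$ SNPs
and $k$ outliers as a top candidate when $k$ strictly exceeds the 0.999
quantile of $\mathrm{Binomial}(n, \bar p)$ ("exceeded" in the rule's
wording reads as a strict inequality). Gene-wise p-values are the binomial
upper tail $P(X \ge k)$, defined as 1 when $k = 0$.

Two properties of $\bar p$ matter in practice and are verified by the test
suite. First, conditioning the eligible set on "at least one outlier"
inflates $\bar p$ well above the nominal flag rate (about fourfold for
geometric bin sizes with mean 30), which makes the 0.999 rule strongly
conservative: under random flags essentially no bin is classified as a
candidate. Second, the same inflation means a gene needs a *cluster* of
outliers — roughly $k \gtrsim 0.999$-quantile of Binomial(n, ~0.04) — to be
flagged; isolated hits never qualify, which is the point of the gene-based
design, but it also means a fixed small number of outlier SNPs cannot be
recovered in large bins regardless of signal placement. The expected rate
is computed per scan (per trait, per transect), matching the per-trait
framing of the procedure; pooling across traits would couple scans that
are otherwise independent.

## The null-W test of parallel adaptation

For candidates from transect A, the test asks whether the same genes score
high in transect B without requiring them to pass B's candidate threshold.
`rank_sum_z()` computes the two-sample Mann–Whitney statistic $W$ (gene
SNP scores vs a control panel, midranks for ties) and
$$Z = \frac{2W - n_1 n_2}{\sqrt{n_1 n_2 (n_1 + n_2 + 1)/3}},$$
with $n_1$ the panel size and $n_2$ the gene's SNP count. These are the
mean and (four times the) variance of the two-sample U statistic, so the
two-sample U interpretation is adopted throughout; the brute-force
all-pairs oracle in the test suite pins the orientation (positive $Z$ ⇔
gene scores stochastically larger).

The control panel is a seeded draw of 10,000 SNPs from noncandidate bins
(`build_control_panel()`); one panel per transect per score type. The null
distribution is one $Z$ per noncandidate bin
(`null_z_distribution()`), and each candidate's empirical p-value is the
fraction of null $Z$ strictly exceeding its own, floored at one over the
null size so BH adjustment never sees a zero. Two decisions the procedure's
description leaves open: (i) when a tested bin's own SNPs are in the panel
they are excluded from the panel side of that bin's test, avoiding
self-comparison bias; (ii) SNPs with undefined scores (e.g. monomorphic
within one transect after filtering on the pooled sample) are excluded from
gene, panel, and null sides alike — they carry no rank information. Genes
with BH-adjusted $q \le 0.05$ are parallel outliers.

## Redundancy analysis

`fit_rda()` implements constrained ordination from first principles: center
the dosage matrix $Y$ per SNP, standardize the predictors $X$ (mixed
units), project $\hat Y = X(X^\top X)^{-1} X^\top Y$, and decompose
$\hat Y / \sqrt{n-1}$ by SVD. Eigenvalues are squared singular values,
sample scores are left singular vectors scaled by singular values, and
locus scores are unit-norm right singular vectors. Ordination packages
offer several locus-score scalings; the unit-norm convention is used here
because the downstream outlier rule — flag SNPs whose locus score on each
of the first three axes lies beyond the axis mean ± 3 SD — is invariant to
any per-axis rescaling. The implementation is cross-checked against
`vegan::rda` eigenvalues in the test suite, and against naive
eigendecomposition of $\hat Y^\top \hat Y/(n-1)$ to 1e-8. Predictors are
first pruned greedily to pairwise $|r| < 0.75$ in a user-controlled
priority order (`select_predictors()`); the retained set is configurable
rather than hard-coded because any fixed list is specific to one climate
table. Collinear predictor matrices (condition number > 1e10) are
rejected. Each flagged SNP is assigned to the predictor with the largest
absolute dosage correlation.

## The synthetic-data generator

`simulate_study()` generates the study the analysis assumes, with known
truth:

* **Population structure.** Balding–Nichols: ancestral frequency
  $p \sim U(0.05, 0.95)$ per SNP; provenance frequency
  $\sim \mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$ with a common $F$ (default
  0.15). This is the simplest model producing realistic allele-frequency
  covariance, enough to inflate uncorrected GWAS and to exercise the
  structure-correction path.
* **Causal architecture.** Causal genes per transect (default 20, of which
  10 shared between transects) carry `causal_snps_per_gene` clinal SNPs
  (default 10) whose provenance frequencies follow a linear cline in
  latitude or elevation (slope 0.35 per unit of the standardized gradient).
  Ten of ~15 SNPs per causal gene tracking the cline emulates the elevated
  within-gene LD of a selected haplotype; with only one or two clinal SNPs
  per gene, no gene could ever exceed the binomial threshold given the
  inflated $\bar p$ discussed above, and the gene-based test would have
  nothing to find by construction.
* **Design.** 68 latitudinal provenances × 4 clones and 13 altitudinal
  provenances × 13 clones (≈ 440 clones split ≈ 270/170 between transects,
  mirroring a realistic two-transect provenance trial), 2 gardens × 4
  blocks × 4 ramets, each ramet in its own block.
* **Phenotype.** Clone value = Σ(dosage × effect) + a provenance climate
  term + a clone-level normal deviate; the deviate and the observation
  residual are scaled so the clone-level repeatability equals `h2_clone`
  (default 0.6, a typical value for growth and phenology in tree
  provenance trials). At `h2_clone = 1` both noise terms vanish and clone
  values equal the genetic values exactly.
* **Climate.** 21 variables named after the standard ClimateWNA annual and
  derived set, each an affine function of the provenance cold/
  continentality gradient plus independent noise (default SD 0.3 against
  loadings of magnitude ≈ 1). Only the correlation structure matters for
  the scans, so no attempt is made to reproduce real climate surfaces.

What the generator does *not* emulate: linkage disequilibrium beyond the
within-gene correlation induced by shared clinal frequencies (no haplotype
or recombination model), sequencing artefacts, unbalanced provenance
sampling, garden × genotype interaction, or spatial field heterogeneity
beyond blocks. Passing tests therefore demonstrate that the machinery is
correct and calibrated under the stated statistical structure, not that it
is robust to every property of real exome data.

## Problem sizes and determinism

The test suite runs the parallelism recovery at 2,000 genes / ~40,000 SNPs
over 20 seeds (plus 8 zero-sharing seeds for the FDR check), calibration at
42,970 bins, and structure-correction behaviour at ~5,000 SNPs over 20
seeds — sizes chosen so each property is measured on hundreds of
gene-level events while a full run stays desk-scale. All randomness flows
through explicit seeds (`withr::with_seed`); identical seeds give
bit-identical studies, panels, and pipelines, which the tests assert by
byte-comparing output tables.

## Known limitations

* The EMMAX-style fixed variance ratio slightly misestimates per-SNP tests
  when a SNP explains a large variance fraction; for top-candidate
  purposes only the p-value *ranking* matters.
* Mean-dosage fill for missing genotypes preserves marginal association
  tests but attenuates LD-based quantities; the LD pruning step operates on
  filled dosages.
* The empirical null-W p-value has resolution 1/(number of noncandidate
  bins); with few bins the BH step is coarse.
* `run_pipeline()` scans every trait × garden and every climate variable it
  finds; on very large SNP sets the kinship-based models dominate runtime
  and can be disabled (`run_mlm = FALSE`).
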