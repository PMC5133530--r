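---
title: "Variance-component QTL mapping in pedigrees with pedscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-component QTL mapping in pedigrees with pedscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedscan)
```

## The model

`pedscan` maps quantitative trait loci in family data with the classical
multivariate variance-component model.  For a pedigree of $n$ individuals
with a $T$-variate trait $Y \in \mathbb{R}^{n \times T}$, the trait-major
vectorization $\mathrm{vec}(Y)$ is modelled as multivariate normal with
mean $A\beta$ and covariance

$$
\Sigma \;=\; 2\,\Sigma_a \otimes \Phi \;+\; \Sigma_d \otimes \Delta_7
\;+\; \Sigma_h \otimes H \;+\; \Sigma_e \otimes I ,
$$

where $\Phi$ is the kinship matrix (additive polygenic effects),
$\Delta_7$ the condensed identity coefficient matrix for dominance,
$H$ the household indicator matrix (shared environment), and $I$ the
identity (individual environment and measurement error).  The
$T \times T$ matrices $\Sigma_a, \Sigma_d, \Sigma_h, \Sigma_e$ are the
free variance components; $\Sigma_e$ must be positive definite and is
always active.  Pedigrees are independent, so the loglikelihood is a sum
of per-pedigree multivariate-normal log-densities; we include the
$-(m/2)\ln 2\pi$ constant so values are directly comparable with any
generic normal log-density (software that omits the constant will report
values offset by exactly $(m/2)\ln 2\pi$ for $m$ observations).

A SNP is tested as a fixed effect: the design $A$ gains $T$ columns
holding the individual's minor-allele count, one per trait, and the $T$
coefficients are tested jointly.  The score test needs no iteration
under the alternative — it reuses the null fit's residuals and
inverse-covariance factors — and the top hits (10 by default) are
re-examined with a full likelihood-ratio refit.

## Kinship options

Four sources for the additive structure are supported:

* `theoretical` — recursive computation from the pedigree: founders are
  non-inbred and mutually unrelated, $\phi_{kk} = (1+\phi_{fm})/2$ and
  $\phi_{kj} = (\phi_{fj}+\phi_{mj})/2$ in parents-before-children
  order.  Exact rationals up to floating representation.
* `grm` / `grm_within` — the per-SNP standardized genetic relationship
  matrix on the kinship scale, globally or masked to zero across
  pedigrees.  Pairwise-complete SNPs handle missing dosages without
  imputation bias; allele frequencies come from all individuals.
* `mom` — the allele-matching method-of-moments estimator.

Empirical estimates can be slightly indefinite (method-of-moments in
particular), so the fitter projects them onto the PSD cone by eigenvalue
clipping before they enter $\Sigma$; the estimators themselves are
reported unmodified.  $\Delta_7$ is implemented for non-inbred pedigrees
only — each non-founder's parents must have kinship zero, which is
checked, not assumed — via
$\Delta_7(i,j) = \phi_{ac}\phi_{bd} + \phi_{ad}\phi_{bc}$ for parental
pairs $(a,b)$ and $(c,d)$.  General Jacquard coefficients for inbred
pedigrees are deliberately out of scope.

## Mean model, constraints, missing data

`pedvc()` takes a formula (`cbind(SBP, DBP) ~ sex + age + sex:age`) and
builds one design column per covariate per trait.  Longitudinal designs
often constrain a covariate's effect to be equal across time points;
`constraints =` names design columns whose per-trait copies are collapsed
into a single summed column per trait group, giving one shared
coefficient — exactly the equality constraint of the covariance model,
and the free-coefficient count drops by (group size − 1) per constrained
column.

Missing data are handled likelihood-exactly:

* a missing **covariate** removes the individual (all trait rows), and
  the removal is logged in `fit$dropped`;
* a missing **trait entry** removes only that coordinate — the
  multivariate normal is marginalized by deleting the corresponding
  rows/columns of $\mathrm{vec}(Y)$, $A$ and $\Sigma$;
* missing **dosages** are mean-imputed to $2\hat p$ for association
  testing only (a deliberate bias/variance trade-off that keeps per-SNP
  testing a vector product); kinship estimation instead uses
  pairwise-complete SNPs and never imputes.

## Fitting: algorithm and numerics

$\beta$ is profiled out by generalized least squares at every variance
iterate.  The component matrices are parametrized by their Cholesky
factors, so the search space is the PSD cone without inequality
constraints; boundary estimates (a component collapsing to zero) are
returned with a `boundary` flag rather than an error.  The profile
likelihood is maximized by BFGS with line search (accepted steps never
decrease the likelihood), restarted until an additional restart improves
the loglikelihood by less than $10^{-8}$ (relative) and moves no
parameter by more than $10^{-6}$, then polished by L-BFGS-B at
near-machine tolerance with $10^{-6}$ finite-difference gradient steps —
the polish is what lets closed-form identities (OLS on unrelateds, the
Armitage trend statistic) hold to $10^{-8}$ in tests.  Initialization is
deterministic: $\Sigma_e$ starts at the covariance of per-trait OLS
residuals, $\Sigma_a$ at half of it, other components at a small multiple
of the identity.

Two degeneracies are detected explicitly: a covariance that is not
positive definite raises an error naming the pedigree, and data in which
the additive structure equals the identity in every block (a cohort of
unrelateds with no pedigree structure) makes $\Sigma_a$ and $\Sigma_e$
non-identifiable — the fit warns and records `identifiable = FALSE`
instead of silently returning one of the infinitely many optima.

Standard errors for the mean coefficients come from the GLS information;
uncertainty for all parameters jointly comes from a central
finite-difference Hessian of the full loglikelihood.  `confint()` uses
log-scale Wald intervals for variance diagonals — variance estimators
are right-skewed, and symmetric intervals visibly under-cover them in
our own calibration runs — and symmetric intervals elsewhere.

## Association testing

With the null fit cached per pedigree ($\Sigma^{-1}r$, $\Sigma^{-1}A$,
$(A^{t}\Sigma^{-1}A)^{-1}$), the score statistic for SNP design block
$X_s$ is $S = U^{t}V^{-1}U$ with $U = X_s^{t}\Sigma^{-1}r$ and
$V = X_s^{t}PX_s$, variance parameters held at the null MLE, referred to
$\chi^2_T$.  A singular $V$ (constant dosage, collinearity with the
intercept) is flagged `undefined` and the SNP skipped, judged on the
scale of the unprojected information.  The likelihood-ratio refinement
re-maximizes everything, warm-started at the null estimates; its
statistic is clipped at zero (tolerance $10^{-6}$) and non-convergence
keeps the score result with a flag.  Ties in top-hit selection break by
genome order.

Scan-level diagnostics follow standard practice: $\lambda_{GC}$ is the
median score statistic over the $\chi^2_T$ median (computed on score
statistics, not the refined LRT values), the Bonferroni threshold is
$\alpha/m$ over the SNPs actually tested, and the FDR cutoff is plain
Benjamini–Hochberg.  The minor-allele-frequency filter's threshold and
comparator are both configurable (strict `<` and non-strict `<=` rules
both occur in practice); by default MAF-failing SNPs are flagged and
skipped by the scan but retained for kinship estimation, which uses the
full panel.  The Hardy–Weinberg exact test runs on founder genotype
counts and is report-only by default, since an extreme HWE p-value is a
diagnostic for genotyping error rather than an automatic exclusion; a
hard threshold is available.  Whether the 98% call-rate rule is strict
is ambiguous in common descriptions; we exclude strictly below the
threshold.  Call-rate filtering alternates SNP and individual passes to
a fixed point, which makes `run_qc()` idempotent; the first pass follows
the documented order (SNPs, then individuals on surviving SNPs), which
is the order that determines survivor counts.

## The simulator

`sim_study()` generates the study conditions the package is tested
under: non-inbred multi-generation pedigrees (founder couple; each
non-terminal child marries a new founder; nuclear family = household),
independent gene-dropped SNPs (founder alleles i.i.d. Bernoulli(MAF),
children inherit one uniformly chosen allele per parent per locus), and
traits drawn exactly from the model covariance above, with causal SNPs
entering the mean — matching how SNPs are tested.  A planted effect
$\beta$ at frequency $p$ contributes $2p(1-p)\beta^2$ of trait variance.
One global random stream per seed is consumed in the documented order
pedigree → genotypes → traits, so runs are fully reproducible.

What the simulator does **not** emulate: linkage disequilibrium
(independent loci only), ascertainment, longitudinal autocorrelation
beyond what $\Sigma_e \otimes I$ encodes, genotyping-error processes,
and population structure beyond the pedigrees themselves.  Passing
calibration and power checks on these studies therefore demonstrates
correctness of the machinery, not robustness to LD or confounding in
real cohorts.

## Study sizes used by the checks

The packaged checks run on deliberately scaled-down studies chosen once:

* *Calibration*: 2,000 null score tests from four bivariate studies of
  20 pedigrees × 26 members (the three-generation template with
  sibship 4 yields 26-person pedigrees), 500 SNPs each; empirical size
  at $\alpha = 0.05$, Kolmogorov–Smirnov uniformity, and
  $\lambda_{GC} \in [0.95, 1.05]$.
* *Power*: bivariate trait, 34 pedigrees (n = 884), planted SNP at MAF
  0.03 affecting both traits, per-trait variance shares 1%, 2% and 4%,
  rejection at the Bonferroni level of a 500-SNP scan.  In family data
  of this size the 2% point sits mid-curve (~0.6); the sweep's top point
  saturates near the 0.82–0.89 range that family-data power studies of
  this design report, while cohorts of ~2,000 unrelateds would saturate
  at 1.  The sweep checks strict monotonicity and saturation.
* *Parameter recovery*: bivariate, 40 pedigrees × 26, 100 replicates;
  every mean coefficient and variance-component entry must fall inside
  its 95% interval at least 90% of the time.
* *Empirical-kinship consistency*: RMSE against the theoretical kinship
  matrix over $10^3$, $10^4$, $5\times10^4$ gene-dropped SNPs on ten
  3-generation pedigrees (~170 individuals).  The RMSE floor is set by
  in-sample allele-frequency estimation — order mean-kinship/$n$ — not
  by SNP count, so the convergence study uses enough pedigrees that SNP
  noise dominates; with only a handful of pedigrees the floor (~0.05 at
  $n \approx 50$) would mask convergence.
* *Exactness*: Hardy–Weinberg p-values agree with combinatorial
  enumeration to $10^{-12}$ for all genotype configurations with
  $N \le 200$; kinship/dominance coefficients agree with gene-dropping
  Monte Carlo ($10^5$ replicates, 3 SE) and exact transmission
  enumeration; the loglikelihood agrees with a dense multivariate-normal
  oracle to $10^{-8}$, including marginalization over missing entries.

## Worked example

```{r example, eval = FALSE}
spec <- sim_spec(n_pedigrees = 20, sibship = 4, n_snps = 200,
                 trait_names = c("SBP", "DBP"),
                 Sigma_a = matrix(c(1, .3, .3, 1), 2),
                 Sigma_e = matrix(c(1, .2, .2, 1), 2),
                 causal = data.frame(snp = 7, trait = c(1, 2), beta = 0.6))
sim <- sim_study(spec, seed = 1)

qc  <- run_qc(sim$geno, sim$pedigree, maf_min = 0.03)
fit <- pedvc(cbind(SBP, DBP) ~ age + sex, sim_data_frame(sim),
             sim$pedigree, kinship = "theoretical")
summary(fit)
scan <- gwas_scan(fit, qc$geno, top_k = 10, maf_min = 0.03)
scan
plot(scan)
pedigree_outlier_report(fit)$pedigrees[1:5, ]
```

## Known limitations

* Maximum likelihood only (no REML); variance components are biased
  downward by the usual $O(k/n)$ fixed-effect correction.
* No X-linked kinship, no robust heavy-tailed likelihood, no
  rare-variant set tests, no conditional multi-SNP models.
* $\Delta_7$ requires non-inbred pedigrees (checked).
* The score test holds variance parameters at the null MLE inside the
  information; the exact-information alternative is not implemented.
* Per-pedigree blocking is the only sparsity exploited; cohorts of tens
  of thousands of unrelateds would need low-rank updates this package
  does not provide.
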