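---
title: "Family-based mixed-model association for longitudinal lipids and treatment response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based mixed-model association for longitudinal lipids and treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famgwas)
```

## The problem

Lipid phenotypes such as triglycerides (TG) and HDL cholesterol are measured
repeatedly in family studies of lipid-lowering treatment: typically two
visits before and two visits after drug administration. Individuals within a
family are correlated through shared polygenic background, the two traits
are correlated both genetically and environmentally, and repeated visits of
the same trait are serially correlated. `famgwas` implements two
variance-component mixed models that use all of this structure for
association testing in families, together with the surrounding pipeline
(kinship, quality control, transformation, imputation, regions, reporting)
and a simulator that draws data exactly from both models so that every
estimator and test in the package can be validated against known truth.

## Model 1: bivariate longitudinal model and the 2-df LRT

For $n$ individuals the stacked response holds both traits at four visits.
With trait-major ordering (TG visits 1–4, then HDL visits 1–4), each trait
obeys

$$Y^{(t)} = X^{(t)}\beta^{(t)} + Z u^{(t)} + \varepsilon^{(t)},$$

where the fixed design contains the four visit means and optionally one SNP
dosage effect shared across visits, $u^{(t)}$ is a polygenic effect with
$\mathrm{Var}(u^{(t)}) = \sigma^2_{u,t} K$ for the pedigree kinship matrix
$K$ (stored as kinship $\Phi$, self = 0.5 for non-inbred individuals; the
model uses $K$ exactly as given), and the residual of each trait has a
common variance $\sigma^2_{e,t}$ across visits with a Markov-product
temporal correlation: $\mathrm{corr}(v_i, v_j) = \prod_{k=i}^{j-1}\rho_k$,
three free parameters per trait. Across traits, the polygenic effects are
correlated with genetic correlation $\rho_g$ and the residuals with
environmental correlation $\rho_\varepsilon$, the latter entering through
symmetric matrix square roots,
$\rho_\varepsilon \Sigma_1^{1/2}\Sigma_2^{1/2}$, which keeps the joint
residual block a valid covariance (a Cholesky root would break its
symmetry). Altogether
$$\mathrm{Var}(Y) = C_1 \otimes I_n + C_2 \otimes K$$
with $8\times 8$ per-individual blocks: $C_1$ the bivariate residual block
and $C_2 = \Sigma_u \otimes J_4$ ($J_4$ all ones, because the polygenic
effect is constant across visits).

Twelve variance parameters govern the model. They are estimated by maximum
likelihood — not REML — because the SNP test compares models that differ in
fixed effects, where REML likelihoods are not comparable. The per-SNP test
is a likelihood-ratio test with 2 degrees of freedom (the SNP enters both
traits), referred to $\chi^2_2$.

### Numerics

Two exact factorizations make the likelihood cheap:

* $C_1$ factorizes as
  $\mathrm{blkdiag}(R_1,R_2)\,(M_{\rho_\varepsilon}\!\otimes\!I_4)\,
  \mathrm{blkdiag}(R_1,R_2)$ with $R_t$ the symmetric root of trait $t$'s
  residual block and $M_\rho$ the $2\times2$ equicorrelation matrix with
  eigenvalues $1\pm\rho_\varepsilon$. Consequently $C_1$ is positive
  definite for every parameter value with all correlations inside
  $(-1,1)$, and a whitening transform $T$ with $TC_1T' = I$ and
  $TC_2T' = \mathrm{diag}(\delta)$ costs two $4\times4$ and one $8\times8$
  eigendecompositions.
* Rotating individuals onto the eigenbasis of $K$ (computed family block by
  family block, once per data set) turns $\mathrm{Var}(Y)$ into $8n$
  independent scalar variances $1+\lambda_i\delta_j$. The fixed effects are
  profiled out by GLS in this doubly rotated basis, where the normal
  equations collapse to $8\times8$ algebra.

Optimization runs quasi-Newton (`L-BFGS-B`) on log-variances and
atanh-correlations with a cached forward-difference gradient and, by
default, three deterministic restarts (moment-based, shrunk, inflated
starts). Convergence uses the optimizer's relative-reduction criterion
(`factr = 1e7`); there is no randomness anywhere in fitting, so scans are
reproducible without seeds. The genome-wide scan fits the null once (it has
no SNP term) and offers two per-SNP modes: `full_refit` re-estimates all
variance components per SNP warm-started from the null, while `fixed_vc`
holds them at the null estimates and refits only the fixed effects. In this
Gaussian model mean and covariance parameters are information-orthogonal,
so both modes share the $\chi^2_2$ reference; `fixed_vc` is never
anti-conservative relative to `full_refit` (its statistic is bounded above
by the full one) and is the mode we use for large Monte-Carlo loops.

## Model 2: Henderson mixed model for treatment response

The drug-response phenotype is the change in doubly-logged TG from
pre-treatment to post-treatment visits (post minus pre, so a negative value
means the drug lowered TG; the direction is configurable and documented in
the output). The model is

$$y = X\beta + Zu + \varepsilon, \qquad u \sim N(0, \sigma^2_g K), \quad
\varepsilon \sim N(0, \sigma^2_e R),$$

with covariates (intercept, age, smoking) plus one SNP column — or the $p$
LD-pruned SNP columns of a genomic region — in $X$. Estimation is REML via
the standard two-component EM iteration (E-step: conditional moments of $u$
and $\varepsilon$ given $y$ through the REML projection; M-step:
closed-form updates), which is monotone in the REML log-likelihood at every
step — the fit records the trace and the tests assert it. Fixed effects and
BLUPs solve Henderson's mixed-model equations; the block solve is provided
verbatim (`solve_mme`) and agrees exactly with the GLS and BLUP closed
forms. A one-time whitening of $(ZKZ', R)$ reduces each EM iteration to
$O(nq^2)$.

The test of $H_0: M\beta = 0$ is
$$F = \frac{(M\hat\beta)'[M(X'\hat V^{-1}X)^{-1}M']^{-1}(M\hat\beta)}{p}
\sim F(p,\; n-q),$$
with $\mathrm{Var}(\hat\beta) = (X'\hat V^{-1}X)^{-1}$ (the inverse of the
fixed-effect information; the non-inverted form sometimes written for
$\mathrm{Var}(\hat\beta)$ is a typographical slip — the quadratic form
above is the one that makes the statistic pivotal). The denominator degrees
of freedom are literally $n-q$; no Satterthwaite or Kenward–Roger
adjustment is applied, which is anti-conservative for very small $n$ and
documented as such. With $\sigma^2_g = 0$, $R = I$ and the REML residual
variance, the test reduces exactly to the classical partial F-test.

### Design choices where the model family is genuinely open

* **Residual matrix `R`.** A non-diagonal positive-definite `R` is part of
  the model family, but family covariance already enters through
  $\sigma^2_g ZKZ'$; a second unconstrained family covariance is not
  identifiable. The default is therefore `R = I`, with
  `residual_exchangeable()` (within-family equicorrelation at a fixed
  $\rho$) or any user-supplied PD matrix as alternatives.
* **Random design `Z`.** The default is the identity on individuals — the
  polygenic reading of a "family" random effect, since
  $\mathrm{Var}(u) = \sigma^2_g K$ fixes the covariance either way. A
  family-indicator `Z` (with `K` the identity on families) is supported.
* **Per-SNP variance components.** The scan re-estimates
  $(\sigma^2_g,\sigma^2_e)$ per SNP by default; `refit = FALSE` estimates
  them once under the covariate-only model and holds them fixed, which is
  much faster and nearly identical away from strong signals.

## Preprocessing rules

* **Transform.** $y = \log\log x$ (natural logs by default; the base is
  configurable since nothing forces a choice, and natural log is the
  statistics default). Defined for raw values $> 1$; raw lipid levels in
  mg/dL are far above that.
* **SNP QC.** In order: SNPs with missing genotypes are removed (a
  missingness-fraction threshold generalizes this; the default of 0 removes
  any missing call), monomorphic SNPs are removed, and SNPs with exactly
  two observed genotype classes lose the site when the rarer class is below
  5%. Sites showing all three genotype classes are deliberately not subject
  to the 5% rule — a rare homozygote class alone does not remove a site —
  and a conventional MAF filter exists but defaults off.
* **Phenotype imputation.** Missing trait-visit cells are imputed under the
  no-SNP polygenic null with a *fixed* heritability (default
  `h2 = 0.5`, deliberately user-visible since it is an external constant,
  not an estimate): each missing cell receives its conditional normal mean
  given the observed cells of that trait-visit column. Imputation is per
  column (marginal), the simplest reading of a single constant
  heritability; joint imputation across the eight columns is out of scope.
* **Response construction.** Pre- and post-treatment means are taken over
  available visits — replacing a single missing visit by its pair partner
  is identical to averaging what is available — and individuals missing an
  entire pre or post pair are excluded and reported.

## Regions and LD pruning

Testing units are genic intervals and the intergenic gaps between
consecutive genes, keeping only units that contain genotyped SNPs; a SNP
under two overlapping genes belongs to both. SNPs upstream of the first or
downstream of the last gene of a chromosome go to terminal
`intergenic_telomeric` units (flag-controlled, on by default) so that every
genotyped SNP is covered. Within each region, greedy left-to-right pruning
keeps a SNP iff its squared dosage correlation with every kept SNP is
$\le 0.5$ (strictly greater removes; position order is the deterministic
tie-break). $r^2$ is composite LD on dosages — family genotypes are
unphased.

## The simulator

`sim_pedigree` builds nuclear or three-generation families;
`sim_genotypes` drops founder alleles at a chosen MAF under Hardy–Weinberg
and transmits them Mendelianly, so relative-pair genotype covariances track
kinship. `sim_longitudinal` draws phenotypes *exactly* from Model 1 via the
structured sampler and exports raw scale by default
($x = e^{e^y}$), so the full pipeline — transform, impute, fit — is
exercised end to end. `sim_response` draws exactly from Model 2. Defaults
emulate a moderate-heritability lipid study on the doubly-logged scale:
polygenic and residual variances 0.4/0.6 per trait (heritability 0.4, in
the range reported for lipids), $\rho_g = 0.4$, $\rho_\varepsilon = 0.3$,
adjacent-visit correlations (0.7, 0.6, 0.5), TG visit means around 1.53
dropping to 1.50 after treatment, HDL around 1.36, age uniform on 20–70,
smoking Bernoulli(0.3). What the simulator does *not* emulate: linkage
disequilibrium between SNPs (sites are independent), ascertainment,
genotyping error, non-normal tails, or informative missingness — passing
tests demonstrate correctness of the estimators under the stated models,
not robustness to violations of them.

## Validation problem sizes

The test suite validates, among others: kinship against Wright's
path-counting oracle on 500 random pedigrees; the rotated likelihood
against dense multivariate-normal evaluation to 1e-10; Henderson solutions
against dense GLS/BLUP closed forms to 1e-8 on 200 random instances; exact
reduction to the partial F-test; type-I error of the F-test (1,000 null
replicates at $n=300$, EM-REML refit each time) and of the LRT (1,000 null
replicates at $n=200$, null components re-estimated per replicate with the
single moment-based start, SNP effects profiled at those components) within
[0.035, 0.065] at $\alpha = 0.05$; EM-REML recovery of
$(\sigma^2_g,\sigma^2_e) = (1.0, 0.5)$ at $n=500$ over 200 replicates;
recovery of all 12 bivariate parameters at $n=400$ over 100 replicates; and
power curves over planted effects $\{0, 0.1, 0.25, 0.5\}$ (500 replicates
per point for the F-test at $n=300$, 250 per point for the LRT at $n=200$).
These sizes are the package's own validation choices: large enough for the
stated Monte-Carlo bands, small enough to run routinely on one CPU.

## A worked example

```{r example, eval = FALSE}
seeds <- derive_seeds(1)
ped <- sim_pedigree(60, "nuclear", k_children = 2, seed = seeds[["pedigree"]])
K <- compute_kinship(ped)
G <- qc_filter(sim_genotypes(ped, 40, seed = seeds[["genotypes"]]))$genotypes
causal <- G$map$snp_id[10]
raw <- sim_longitudinal(ped, G = G,
                        causal = list(snp_id = causal,
                                      beta_tg = 0.4, beta_hdl = 0.3),
                        missing_rate = 0.05,
                        seed = seeds[["longitudinal"]], K = K)
pheno <- impute_null_model(loglog_transform(raw), K, h2 = 0.5)
scan <- gwas_longitudinal(pheno_matrix(pheno), G, K, mode = "full_refit")
scan$unit_id <- scan$snp_id
head(top_table(assoc_table(scan), 5))

resp <- build_response(pheno)
```

## Known limitations

Four visits and two traits are structural (the temporal display is
hard-coded to the 2-pre/2-post layout); unequal visit spacing, more visits,
covariates inside the longitudinal fixed design (available behind a flag
but off by default), score tests, dominance, multi-component variance
models and Satterthwaite-type degrees of freedom are out of scope. Single
imputation ignores imputation uncertainty. The $\chi^2_2$ and $F$
references are asymptotic; at small $n$ the literal $n-q$ denominator df
is anti-conservative.
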