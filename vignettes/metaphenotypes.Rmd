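---
title: "Metaphenotypes: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaphenotypes: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the parameters that matter,
what the simulator does and does not emulate, and the choices we made
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The decomposition model

A study measures m correlated quantitative traits on n individuals. We
write the (column-standardized) trait matrix as

$$X = M\,W + E,$$

where the k rows of $W$ are weights of each trait on a component and the
columns of $M$ are component scores — the *metaphenotypes*. Two
estimators of $W$ are provided.

**PCA** (`pca()`) takes the top-k eigenvectors of the sample covariance of
the standardized traits; components capture maximal shared variance and
are ordered by eigenvalue.

**fastICA** (`fastica()`) whitens the data to k dimensions by PCA and then
seeks the orthogonal rotation maximizing non-Gaussianity of the scores,
measured by the negentropy approximation $E[G(w^\top z)]$ with
$G'(u)=\tanh(u)$ (log-cosh, the reference default) or
$G'(u)=u e^{-u^2/2}$. The fixed-point update with *symmetric* (parallel)
decorrelation is used rather than deflation, so no component is privileged
by estimation order; a canonical order is imposed afterwards (section 3).
Identifiability requires at most one Gaussian source; with purely Gaussian
data the iteration legitimately fails, and `fastica()` retries from five
perturbed seeds before raising a diagnostic error.

Because ICA is a rotation of the whitened PCA space, at equal k both
methods span the same subspace: their reconstructions `M %*% W` are
identical, which the test suite asserts. The difference is interpretive —
PCA concentrates shared variance, ICA separates statistically independent
sources, which is the configuration in which a pleiotropic genetic signal
(one variant feeding many traits) isolates into a single component.

**Standardization.** Traits are z-scored (population, ddof = 0) before
decomposition. The traits this targets — e.g. 27 coagulation assays — have
incompatible units; covariance PCA would be dominated by whichever assay
happens to have the largest numeric variance. A zero-variance trait is an
error, not silently dropped.

**Choosing k** (`choose_k_cv()`). The number of informative components is
selected by element-wise (Wold-style) cross-validation: cells are
partitioned at random into folds; each fold is deleted, reconstructed by a
rank-k EM-PCA (iterated SVD imputation) fitted on the remaining cells, and
the squared prediction error accumulated into a PRESS curve whose argmin
is k. The literature the pipeline descends from cites only "a criterion
based on cross-validation approximations"; element-wise PRESS is our
concrete stand-in and is flagged as such. Row-wise CV was rejected because
it cannot score reconstruction of truly unseen cells.

## 2. Imputation by Bayesian PCA

`fit_bpca()` fits $y_i = \mu + W x_i + \varepsilon_i$, $x_i \sim N(0,I_q)$,
isotropic residual, by EM in which only the factor scores are latent:
missing cells simply drop out of the observed-data likelihood, so the EM
is exact (no missing-data augmentation, no approximation of cross
terms). Each loading column carries an automatic-relevance (ARD) Gaussian
prior whose precision is re-estimated each iteration
($\alpha_j = (m-2)/\lVert w_j \rVert^2$, the MAP update under a scale
prior), so superfluous columns shrink toward zero and q may default to
m − 1 without overfitting. The penalized negative log-likelihood is
recorded per iteration and is non-increasing by construction (every E/M
coordinate step maximizes the same objective); the test suite checks this
on every fixture run. Convergence is declared when no imputed cell moves
more than `tol` (standardized units, default 1e-4) between iterations.

Assumptions: cells are missing completely at random, and the trait matrix
is approximately low-rank plus isotropic noise. The package deliberately
does single imputation — the downstream mixed model treats imputed cells
as data, and imputation uncertainty is not propagated (a stated
non-goal). Traits are standardized on observed cells before fitting and
de-standardized after; observed cells are returned bit-identical.

## 3. Canonical orientation

ICA is indeterminate up to sign and order. `orient_and_order()` flips each
component so its largest-|weight| trait loads positively, sorts components
by explained variance (the variance of each component's rank-1
reconstruction relative to total variance), and assigns labels `C1..Ck`
afterwards. The transform is idempotent, leaves PCA output in its natural
order, and on well-separated sources makes the fitted weights invariant to
the random seed — which is what makes component labels citable across
runs.

## 4. Kinship and the polygenic mixed model

`kinship_matrix()` applies the classical recursion in topological order
(founders $\phi_{ii}=1/2$, unrelated; non-founder i with parents f, m:
$\phi_{ij}=(\phi_{fj}+\phi_{mj})/2$, $\phi_{ii}=(1+\phi_{fm})/2$).
Inbreeding needs no special casing — loops simply raise the diagonal. An
independent Monte-Carlo oracle, `gene_drop_kinship()`, transmits uniquely
labelled founder alleles Mendelianly and estimates kinship as the IBD
fraction over the four allele pairings; the two agree within 0.01 at 1e5
replicates on every fixture pedigree, including inbred loops.

The trait model for a metaphenotype y is

$$y \sim N(X\beta,\; \sigma_G^2\, 2\Phi + \sigma_e^2 I).$$

Although the source literature writes the polygenic variance as
"$\Phi\sigma_G$", we multiply $2\Phi$ (the additive/numerator relationship
matrix), the convention of the established variance-components software it
references: only then does $h2r = \sigma_G^2/(\sigma_G^2+\sigma_e^2)$
equal narrow-sense heritability under the standard additive model.

**Estimation.** $2\Phi$ is eigendecomposed once per kinship matrix and
reused for every trait and SNP. In the rotated basis the covariance is
diagonal in the heritability ratio, $\beta$ and the total variance profile
out in closed form, and the likelihood is maximized over the single ratio
parameter on [0, 1) (`optimize`, with the $h^2=0$ boundary checked
explicitly). Full ML — not REML — is used for *both* members of every
model comparison so that likelihood-ratio tests of fixed effects are
valid.

**Tests.** Heritability is tested against $\sigma_G^2=0$ with the boundary
mixture $\tfrac12\chi^2_0+\tfrac12\chi^2_1$ (a variance component lies on
the boundary of its parameter space under the null; the naive $\chi^2_1$
reference would be conservative by about a factor of two). SNP association
compares covariates-only vs covariates + additive SNP dosage on the same
complete-case individuals, referred to $\chi^2_1$; missing genotypes are
handled per-SNP complete-case (genotype imputation is out of scope).
Bonferroni correction is applied over all testable (SNP, metaphenotype)
pairs jointly — the unambiguous, conservative reading of "corrected using
the Bonferroni criterion" — with per-metaphenotype correction available as
an option.

## 5. The simulator as a stated world

`simulate_*()` generates the statistical structure every other module
assumes, shaped like the motivating family design: 21 extended families of
mean size 19 (three generations grown from founder couples, Poisson
offspring counts calibrated to the target size, founder spouses marrying
in), sex assigned with the 0.85 male:female ratio of that cohort, ages
uniform on 1–88 years. Genotypes are gene-dropped at unlinked SNPs from
Hardy–Weinberg founders. Traits are linear mixtures of unit-variance
latent sources — polygenic (breeding values with covariance $h^2\,2\Phi$,
drawn per family block since families are independent), SNP-driven
(standardized dosage explaining a stated variance fraction), or
non-Gaussian environmental (Laplace by default, because ICA
identifiability tolerates at most one Gaussian source) — plus isotropic
measurement noise (default sd 0.3 on unit-variance sources, a
signal-to-noise level at which components are clearly present but not
trivial) and optional covariate effects. Missingness is MCAR with a
guarantee of one observed cell per row and column.

What the simulator does **not** emulate — and hence what a green test does
not establish: linkage disequilibrium between markers (SNPs are unlinked,
so QC/LD behaviour on realistic haplotype structure is untested),
ascertainment through probands (families are random, while the motivating
cohort selected half its families through thrombophilic probands),
genotyping error, non-MCAR missingness, and household/shared-environment
variance. Results on simulated data bound what the methods can do under
their own assumptions, not what any particular cohort will show.

## 6. Numerical choices and degenerate inputs

* Population (1/n) variance convention throughout the decomposition stack;
  the standardize → decompose → reconstruct chain is internally consistent
  and tested to 1e-8.
* fastICA convergence: $\max_i |1-|\langle w_i^{new}, w_i\rangle||$ below
  `tol` (default 1e-4, the reference implementation's default); symmetric
  decorrelation via the inverse matrix square root; up to 5 seeded
  restarts.
* Minor-allele ties (frequency exactly 0.5) are broken alphabetically so
  additive coding is deterministic; a marker with only one observed allele
  codes 0 for everyone and records the minor allele as unknown.
* QC filter order is fixed and observable: sample call rate →
  heterozygosity (robust z + Benjamini–Hochberg; zero MAD yields a warning
  and no flags) → IBS duplicates (the pair member with lower call rate is
  dropped; ties break lexicographically) → marker call rate → MAF, with
  marker statistics computed after sample removal. `apply_qc()` is
  idempotent.
* The heritability optimizer works on the ratio scale with the boundary
  checked explicitly; `sigma_g2` is reported as exactly 0 when the
  boundary wins, and LRT statistics are clamped at 0 (tolerance −1e-8,
  beyond which a warning is raised).
* The pipeline writes no timestamps into artifacts, hashes every output
  file (md5) into a manifest, and derives all stage seeds from one master
  seed, so identical configs produce bit-identical output trees.

## 7. Known limitations

Single imputation (no uncertainty propagation); global Bonferroni is
conservative under correlated tests; the cross-validation criterion for k
is one concrete choice among several in the literature; IBS is computed on
all markers rather than a thinned subset (appropriate at desk scale only);
no household variance component; no X-linked kinship; text PLINK only.
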