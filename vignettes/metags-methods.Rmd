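---
title: "Methods: meta-analysis of SNP-BLUP evaluations from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of SNP-BLUP evaluations from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Within one population, `metags` assumes the standard sire-model SNP-BLUP.
The corrected phenotype of sire *k* (a daughter average, in trait units) is

$$y_{k} = \mu + \mathbf{z}_{k}\mathbf{g} + e_{k},
\qquad \operatorname{var}(e_{k}) = \sigma^2_e / n_{k},$$

where $\mathbf{z}_k$ is the row of centered genotypes (dosage minus twice
the allele frequency), $n_k$ is the effective daughter count carried by the
record, and all SNP effects are random with a common variance. The per-SNP
variance is tied to the variance of direct genomic values $\sigma^2$
through

$$\operatorname{var}(g_j) = \sigma^2\,\theta, \qquad
\theta = \frac{1}{\sum_j 2 p_j (1 - p_j)},$$

so that the implied DGV variance matches $\sigma^2$ regardless of panel
size. Across $c$ populations the effects of one SNP form a correlated
vector with covariance

$$\Sigma_{ik} = \rho_{ik}\sqrt{\sigma^2_i \sigma^2_k}\sqrt{\theta_i\theta_k},$$

with $\rho$ the genetic correlation between populations, supplied as input
(it is estimated externally, e.g. from breeding-value correlations or a
multi-trait REML fit). Because this covariance is identical for every SNP,
the full SNP-expanded prior is the Kronecker product $\Sigma \otimes I$ and
its inverse is $\Sigma^{-1} \otimes I$: the meta system only ever needs the
$c \times c$ inverse (`invert_g()`), never an $cm \times cm$ covariance.

The meta mixed-model equations stack each population's shared precision
matrix on the block diagonal, add $\Sigma^{-1}_{ii} I$ there and
$\Sigma^{-1}_{ik} I$ off the diagonal, and stack the shared right-hand
sides. Solving this system yields population-specific SNP effects equal to
a joint multi-trait BLUP on the pooled raw data in which each population's
phenotypes inform only its own trait.

## Mean absorption — the one structural choice

The single-population model fits a general mean, while the meta equations
carry none. For the two to be consistent the mean must be absorbed, and
absorbing it exactly touches both sides of the shared statistics. With
$\mathbf{W} = R^{-1}$ and weighted averages
$\bar{y} = \mathbf{1}'\mathbf{W}\mathbf{y}/\mathbf{1}'\mathbf{W}\mathbf{1}$,
eliminating $\mu$ from the full equations leaves

$$\left(\mathbf{Z}'\mathbf{W}\mathbf{Z}
  - \frac{(\mathbf{Z}'\mathbf{W1})(\mathbf{1'W}\mathbf{Z})}{\mathbf{1'W1}}
  + \lambda I\right)\hat{\mathbf{g}}
  = \mathbf{Z}'\mathbf{W}(\mathbf{y} - \bar{y}\mathbf{1}),$$

i.e. the precision matrix needs the rank-one Schur correction, not just the
phenotype centering. `summarize_population()` therefore stores the
*absorbed* precision matrix and right-hand side. Three exact identities
follow, and the test suite checks all of them at machine-level tolerances:

* the summary-path effects equal the explicit mean-fitted solve
  (`solve_single_pop()`);
* `recover_rhs()` inverts the solve exactly, so sharing effects or sharing
  the right-hand side is equivalent;
* `solve_meta()` equals the independent raw-data oracle
  (`solve_joint_mblup()`, which fits one mean per population) to numerical
  precision — agreement is exact algebra, not approximation.

Had we centered only the phenotypes (keeping the raw
$\mathbf{Z}'\mathbf{W}\mathbf{Z}$), the correction term — small but nonzero
whenever centering frequencies are not precision-weighted — would have
capped the achievable agreement below these tolerances. The raw,
trait-agnostic matrix remains available via `precision_matrix()`; it is the
natural object for cross-trait sharing and rescaling, where a scale factor,
not an exact identity, is at stake. Because the mean is fitted (then
absorbed), the SNP-effect BLUP is invariant to the frequencies used for
centering; the frequencies only move the intercept.

## Rescaling and imputation of shared statistics

**Rescaling.** A precision matrix built once from all `n_geno` genotyped
individuals is rescaled by `n_pheno / n_geno` for a trait phenotyped on a
subset. This is exact in expectation under random phenotyping: both the
full-matrix entries and the subset-built entries are sums of per-individual
terms, so masking a fraction scales the expectation linearly. The
`rescaling_experiment()` protocol (random masks, correlation and regression
slope over lower-triangle entries, normal-theory 95 % intervals over
replicates) verifies both the correlation and that the slope interval
covers 1.

**Imputation.** For SNPs absent from one population's panel, a reference
panel genotyped for the complete list provides least-squares mappings
$T = (Z_i'Z_i)^{-1} Z_i'Z_c$ per block of at most 200 adjacent SNPs within
a chromosome (the default; configurable). Reference genotypes are
column-centered with reference-panel frequencies before forming the
cross-products. Imputation is then pure linear algebra on the shared
objects: $\mathrm{rhs}_c = T'\,\mathrm{rhs}_i$,
$\mathrm{lhs}_c = T'\,\mathrm{lhs}_i\,T$, and after solving on the complete
list, $g_i = T g_c$ maps solutions back. Two choices deserve note:

* *Cross-block products are retained.* The block-diagonal $T$ makes
  $T' L T$ cheap, but $L$ itself carries cross-block LD; zeroing those
  products would discard real information, so block pairs are multiplied
  through.
* *Ridge fallback.* $Z_i'Z_i$ is singular whenever a block holds more
  observed SNPs than the reference has individuals (or under exact
  collinearity). With `ridge = "auto"` the solver stays exact when the
  cross-product is well conditioned and otherwise adds
  `1e-6 * mean(diag(Zi'Zi))` with a warning; with `ridge = 0` a singular
  block is a hard error suggesting the remedy. Exactness under perfect LD
  (a duplicated SNP recovers its twin's statistics exactly at ridge 0) is a
  test invariant.

Blocks in which *every* SNP is masked cannot be reconstructed from within
themselves; they are recorded (`empty_blocks`), receive zero right-hand
sides, and contribute to the system only through cross-block terms. This is
reported, not fatal.

`mask_and_evaluate()` reproduces the three-way validation protocol: per
replicate the population splits into a reference third (builds $T$), a
training third (summary statistics masked and imputed, system re-solved)
and a validation third (DGV accuracy). Correlations are computed over
masked entries only — masked positions of the vectors, masked rows/columns
of the matrix. The experiment reproduces the characteristic pattern:
precision-matrix and right-hand-side imputation stay accurate at high
masking while per-SNP effects do not (effects of SNPs in high LD are
interchangeable, so entry-wise agreement is the wrong scale for them), yet
prediction accuracy is barely affected because the system re-distributes
effects among LD partners.

## The synthetic data generator

`sim_scenario()` / `simulate_dataset()` emulate a reduced-scale two-breed
dairy evaluation: two populations (default 800 and 300 sires) on a shared
panel (default 2,000 SNPs on 2 chromosomes), block LD, cross-population
effect correlation 0.5, and sire-model phenotypes.

*Genotypes.* Haplotypes are copied per LD block from a two-founder pool:
each block holds a founder haplotype and its complement plus a
founder-choice weight drawn from U(0.25, 0.75); a haplotype copies one
founder and flips each allele independently with probability
$\varepsilon = (1 - \sqrt{\ell})/2$, where $\ell$ is the target
within-block dosage correlation. This yields pairwise within-block
$|r| \approx (1-2\varepsilon)^2 = \ell$ by construction (a one-factor LD
structure), independence across blocks, frequencies spread by the
founder-choice weight, and exact determinism given the seed. A joint MAF
filter (default floor 0.05, applied in every population) guarantees shared
polymorphic SNP lists. What this does *not* emulate: LD decay with
distance within blocks, allele-frequency divergence between breeds,
selection, pedigree structure, or genotyping error — passing tests
demonstrate algebraic correctness and robustness of the imputation under a
stylized, favourable LD structure, not field performance on real cattle
data.

*Effects and phenotypes.* Per SNP, the $c$-vector of effects is drawn from
$N(0, \Sigma)$ with $\Sigma$ built from the scenario variances and the
realized (post-filter) frequencies, so the realized DGV variance matches
the scenario's $\sigma^2$ in expectation. Phenotypes are generated directly
at the sire level, $y = \mu + \mathrm{DGV} + e$ with
$\operatorname{var}(e) = \sigma^2_e/n_k$ and $n_k$ uniform on the
daughter-count range — equivalent to, and much cheaper than, simulating
daughters individually. Defaults: $\sigma^2 = 1$, $\sigma^2_e = 10$,
$\mu = 1$, $n_k \in [20, 100]$, i.e. record reliabilities typical of
progeny-tested bulls.

## Numerical choices

* Solvers are direct symmetric (Cholesky) factorizations; failures report a
  reciprocal-condition estimate. A preconditioned conjugate-gradient path
  (`solve_meta(..., method = "cg")`, block-diagonal preconditioner,
  relative-residual tolerance 1e-8) exists for systems too large to
  factorize densely; at the package's default problem sizes the direct
  path is used.
* Correlation matrices are validated eagerly: asymmetry, non-unit
  diagonals, entries outside $[-1,1]$ and non-PSD matrices are errors, and
  off-diagonal magnitudes above 0.999 are rejected outright rather than
  silently regularized — a correlation that close to $\pm 1$ makes
  $\Sigma$ numerically singular and is almost certainly an input mistake.
* Supplied precision matrices are used as-is except for symmetrization
  $(A + A')/2$; asymmetry beyond 1e-8 (relative) draws a warning.
* Monomorphic SNPs are rejected at summarization (the simulator's MAF
  filter prevents them by construction); in a *reference* panel a SNP may
  drift to monomorphism in a small subsample, where it is handled by
  frequency clamping plus the ridge path instead of an error.
* The binary exchange format for the precision matrix stores the packed
  lower triangle (row-major, 8-byte little-endian doubles) after a 16-byte
  header (magic `MGSLHS01`, dimension as an 8-byte little-endian integer);
  round-trips are bit-exact, and size/magic mismatches are diagnosed with
  byte positions.

## Problem sizes and runtime

The shipped experiments run at desk scale, chosen so the full suite and the
reproduction script complete in seconds to a few minutes on one CPU: the
equivalence check at 800 + 300 individuals and 2,000 SNPs (dense
4,000-equation systems), the imputation protocol at 1,500 individuals and
2,000 SNPs with 70 % masking and 20 replicates, and the rescaling protocol
at 1,000 individuals, 1,000 SNPs and 100 replicates. The algebra is
size-agnostic; for panels approaching 40k+ SNPs the dense meta system
(~$(cm)^2$ doubles) becomes the binding constraint and the CG path with an
out-of-core or sparse representation of the blocks would be the natural
extension.

## Known limitations

* No residual polygenic effect is fitted alongside the SNP effects.
* Genetic correlations and variance components are inputs, never estimated
  here.
* The across-population prior assumes every population's effects share one
  correlation per population pair, constant across SNPs.
* Imputation quality is bounded by the LD between masked and observed SNPs
  in the reference panel and by reference-target relatedness; the
  block-diagonal $T$ ignores LD leakage across block boundaries when
  constructing the mapping (though not when applying it to the matrix).
* Bull-level international evaluations (MACE-style) are out of scope.

```{r example}
library(metags)
sc <- sim_scenario(seed = 11)
ds <- simulate_dataset(sc)
summaries <- lapply(1:2, function(i)
  summarize_population(ds$panels[[i]], ds$truth[[i]]$records,
                       err_var = sc$err_var[i], dgv_var = sc$dgv_var[i],
                       population = paste0("pop", i)))
theta <- sapply(summaries, function(s) compute_theta(s$allele_freq))
spec <- covariance_spec(sc$dgv_var, sc$effect_corr, theta)
sol <- solve_meta(assemble_meta(summaries, spec))
orc <- solve_joint_mblup(ds$panels, lapply(ds$truth, `[[`, "records"),
                         sc$dgv_var, sc$err_var, sc$effect_corr)
cor(sol[[1]], orc$effects[[1]])  # 1 to machine precision
```
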