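---
title: "Mixed models for genomic prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed models for genomic prediction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gblupr)
```

# The model

`gblupr` fits the linear mixed model

$$ y = X\beta + \sum_{i=1}^{j} Z_i u_i + \varepsilon, \qquad
   u_i \sim N(0, K_i \sigma^2_{u_i}), \qquad
   \varepsilon \sim N(0, I\sigma^2_e), $$

where each random term carries its own incidence matrix $Z_i$ and a
user-specified covariance structure $K_i$ among its levels. In genomic
selection the structures are relationship matrices estimated from markers,
and the BLUPs $\hat u_i$ are genomic estimated breeding values (GEBVs). The
marginal covariance is $V = \sum_i Z_i K_i Z_i' \sigma^2_{u_i} + I\sigma^2_e$,
and at fixed variance components the solver works through Henderson's
mixed model equations, whose inverse coefficient blocks also feed the
EM updates and standard errors. The residual is always $I\sigma^2_e$;
structured residuals (spatial or longitudinal) are out of scope.

## Relationship matrices

With markers coded $-1/0/+1$ against a reference allele and $p_j$ the
frequency of the $+1$ allele:

* **Additive (VanRaden):** $A = ZZ' / \big(2\sum_j p_j(1-p_j)\big)$, with $Z$
  the marker grid column-centered by $2p_j - 1$.
* **Dominance (Su):** markers recoded 0/1 for homozygote/heterozygote,
  centered by $2p_jq_j$, and scaled by $\sum_j 2p_jq_j(1-2p_jq_j)$. Published
  variants of this denominator disagree; we default to Su's
  $\sum 2p_jq_j(1-2p_jq_j)$ and expose `denominator = "simple"` for
  $\sum 2p_jq_j$ rather than choosing silently.
* **Epistatic:** Hadamard products $E_{aa}=A\#A$, $E_{dd}=D\#D$,
  $E_{ad}=A\#D$; the Schur product theorem keeps them positive
  semidefinite.

Allele frequencies default to those observed in the supplied individuals
(an `allele_freqs` argument accepts external ones). Missing genotype cells
are imputed to the per-marker mean of the coded values before centering —
the simplest choice that leaves expected relationships unbiased. Monomorphic
markers contribute nothing to numerator or denominator and are excluded
with a message; converting letter genotypes codes the minor allele $+1$,
breaking frequency ties by the lexicographically later allele letter so the
conversion is deterministic.

## Variance-component estimation

Three REML algorithms are provided, mirroring the division of labor common
in genomic-prediction software:

* **EMMA** (single random term): the kernel is rotated into the eigenbasis
  of its projection onto the orthogonal complement of the fixed-effect
  column space, reducing REML to a one-dimensional search over
  $\delta = \sigma^2_e/\sigma^2_u$. We maximize the profiled restricted
  likelihood on a 100-point log grid over $[10^{-9}, 10^9]$ and refine with
  Brent search in the best bracket. One eigendecomposition per fit makes
  this the fastest route, and `fit(method = "auto")` selects it whenever
  the model has one random term.
* **Average information (AI)**: Newton-type updates on all components using
  the average-information matrix
  $\mathrm{AI}_{ij} = \tfrac12 y'P\dot V_i P \dot V_j Py$ and scores
  $s_i = -\tfrac12[\mathrm{tr}(P\dot V_i) - y'P\dot V_i Py]$, with $P$
  computed on the dense $n \times n$ covariance (direct inversion, the
  efficient choice when covariance structures are dense). Steps that would
  lower the restricted likelihood are halved up to 10 times; if the AI
  matrix is singular or halving fails, one EM sweep substitutes for the
  Newton step and the event is recorded in the trace.
* **EM**: the classic fixed-point updates
  $\sigma^2_{u_i} \leftarrow (\hat u_i'K_i^{-1}\hat u_i +
  \mathrm{tr}(K_i^{-1}C^{ii}))/q_i$ and
  $\sigma^2_e \leftarrow (y'y - \hat b'W'y)/(n-p)$, monotone in the
  restricted likelihood and robust far from the optimum, but linearly
  convergent. Near a small variance component the contraction rate
  approaches one: on random single-kernel problems with $n = 100$ we
  observed ~3000 iterations needed to agree with EMMA/AI to $10^{-3}$
  relative, so the iteration cap defaults to 5000 (each sweep is one
  MME solve; costs are modest at these sizes).

All algorithms clamp components at a floor of
$10^{-10}\,\mathrm{Var}(y)$ — never negative — and flag boundary
estimates. Convergence requires both a restricted-likelihood change below
$10^{-8}$ and a maximum relative parameter change below $10^{-6}$. The
reported log-likelihood is
$-\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| - \log|X'X| + y'Py]$;
the $\log|X'X|$ term makes the value invariant to the basis chosen for the
fixed effects (some packages omit it, so their absolute values differ by a
constant while all differences of log-likelihoods agree). AIC/BIC count
only the estimated variance components, since REML profiles the fixed
effects out.

## Numerical policies

* **Near-singular structures.** Centered marker panels give rank-deficient
  kinships (an $n$-individual VanRaden $A$ has rank at most $n-1$), and
  Kronecker SCA kernels inherit the deficiency multiplicatively. At model
  assembly every structure whose smallest eigenvalue falls below
  $10^{-8}$ of its largest receives diagonal jitter starting at
  $10^{-6}\,\overline{\mathrm{diag}(K)}$, escalating tenfold as needed, with
  a message. The jittered matrix is then used *everywhere* — Henderson
  equations, marginal covariance, spectral rotation — so all computational
  routes describe the same model. (A plain Cholesky is not a reliable
  singularity test: it can succeed on numerically singular matrices and
  silently yield a useless inverse, which is why the gate is spectral.)
* **Missing responses.** Records with missing response are dropped from the
  estimation rows while every random-effect level keeps its column, so
  unphenotyped levels receive BLUPs through their covariance with observed
  levels. This is the entire mechanism for predicting unrealized crosses
  and unobserved hybrids; no separate extension step exists.
* **Rank-deficient fixed effects** are reduced by pivoted QR with a
  warning, matching common mixed-model software.
* **Ties in cross rankings** share a dense rank; rows of equal value are
  ordered by parent labels so output files are reproducible.

## Hybrid prediction

For a factorial cross between two parental panels the model carries three
random terms — female GCA with $K_1$, male GCA with $K_2$, and SCA with
$K_3 = K_1 \otimes K_2$ over all female:male combinations (labels in
female-outer order, matching the incidence columns `mm_spec()` builds).
A hybrid's predicted genetic value is
$\hat u_{GCA_1}[f] + \hat u_{GCA_2}[m] + \hat u_{SCA}[f{:}m]$, reported
relative to the intercept by default; `include_fixed = TRUE` adds the mean
fixed-effect value, i.e. the prediction at the average of the fixed levels
(location effects are rarely of interest when ranking crosses). For
species without heterosis, cross prediction is simply the mid-parent mean
of GEBVs. Heritability is $\sigma^2_u/(\sigma^2_u+\sigma^2_e)$ in the
single-kernel design and
$(\sigma^2_{GCA_1}+\sigma^2_{GCA_2})/(\sigma^2_{GCA_1}+\sigma^2_{GCA_2}+\sigma^2_e)$
in the hybrid design — SCA enters neither numerator nor denominator —
and $\sqrt{h^2}$ bounds the achievable predictive correlation.

A GCA-only model with a single shared parental variance ($G = K\sigma^2_u$
over all parents of both groups) needs an incidence with two ones per
record; `mm_spec()` accepts such custom incidences via
`list(Z = , K = )` random terms, with `half_diallel_incidence()` building
the two-ones-per-cross design matrix.

## Cross-validation

`kfold_cv()` masks folds of *observed* records, refits, and correlates
predictions with the held-out values. Partitioning is by grouping unit —
by default the levels of the random term with the most levels — so
replicate records of one genotype never straddle folds; `group` overrides
this, including `group = ".record"` for record-wise partitioning. The
distinction matters scientifically: with hybrids replicated across
locations, record-wise folds let a masked record's SCA be informed by its
replicates, which is how replicated trials reveal the value of modeling
dominance, while genotype-wise folds measure prediction of genuinely
unobserved hybrids, whose SCA is nearly unpredictable because Kronecker
covariances are products of (small) parental relationships. Both questions
are legitimate; the default answers the stricter one. Run $r$ seeds its
partition with `seed + r`, making results bit-reproducible under a fixed
BLAS.

## The synthetic-data generator

`simulate_markers()` draws per-marker allele frequencies uniformly (default
0.05–0.5) and genotypes under Hardy–Weinberg equilibrium.
`simulate_phenotype()` assigns additive (and optionally dominance) effects
to a random QTL subset and **rescales the realized genetic-value columns to
the requested variances exactly**, unlike expectation-scaled simulators;
at small $n$ this makes recovery tests sharp — equal additive and residual
variance gives a generating $h^2$ of exactly 0.5 in the realized sample.
`simulate_hybrid_system()` emulates a two-heterotic-group factorial:
511 markers per panel of 20 + 20 parents, hybrid effects drawn from
$N(0, K_1\sigma^2)$, $N(0, K_2\sigma^2)$, $N(0, K_3\sigma^2)$, 25% of the
400 hybrids observed, in 4 locations (with one location per hybrid the SCA
and residual variances are confounded, so replication is the default).
Unit variances are the default where no design dictates otherwise.

What the generator does *not* emulate: linkage disequilibrium and genetic
maps, population structure and family stratification, selection, non-HWE
genotype frequencies, genotyping error, and marker ascertainment. Passing
tests therefore demonstrate correctness of the estimation machinery under
the stated generative model, not robustness to the structure of real
breeding populations.

## Association scan

`mm_scan()` estimates the polygenic and residual variances once on the
marker-free null model (spectral path), then holds them fixed while each
marker enters the fixed effects — the P3D / EMMAX-style approximation,
chosen for speed and recorded in the scan's metadata. After whitening by
the Cholesky factor of the null covariance, each marker's Wald test is an
ordinary partitioned regression; with $K = I$ and no polygenic variance
the p-values reduce exactly to OLS t-tests. Monomorphic or aliased markers
are reported as missing. A Bonferroni threshold accompanies the raw
$-\log_{10}p$ scores; no FDR machinery is included. Diploid genotypes
only.

## Problem sizes used in the test suite

The packaged checks run at desk scale, chosen to keep the full suite in a
few minutes while leaving the statistics sharp: heritability recovery uses
20 replicates of $n=500$, $m=1000$; algorithm-equivalence uses 20 random
instances at $n=100$; the hybrid comparisons use the 20 + 20 parent design
with 100 observed hybrids in 4 locations; the additive vs
additive+dominance comparison runs 100 paired 5-fold cross-validations
with SCA variance 4 against GCA and residual variances of 1 (a strongly
heterotic trait — with SCA a minor variance fraction the comparison would
measure mostly fold noise); scan calibration uses 20 replicates of 500
markers. Estimation itself is deterministic; only simulation and
cross-validation consume seeds.

## Known limitations

Residual covariance structures, Bayesian samplers, polyploid scan models,
pedigree-based relationship matrices, LD pruning and multi-trait models
are all out of scope. The AI implementation inverts the dense $n \times n$
covariance, the right regime for dense genomic kernels at these scales;
sparse-MME AI variants suited to very large, sparse pedigree models are
not provided. EM remains available as the robust fallback the AI path
invokes automatically.
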