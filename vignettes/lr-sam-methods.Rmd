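---
title: "Logistic-regression significance analysis for MRM proteomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logistic-regression significance analysis for MRM proteomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrsam)
```

## The problem

Multiple reaction monitoring (MRM) quantifies a preselected panel of
peptides as surrogates for their parent proteins. Each serum sample is
measured in a run together with a spiked-in stable-isotope reference, and
the export carries one *Area Ratio* (endogenous over reference intensity)
per sample, run, protein and peptide. The scientific question is almost
always the same: which proteins differ in abundance between two groups of
subjects (cases and controls, responders and non-responders)?

The prevailing approach models the absolute log2 intensities with a linear
mixed model (LMM) in the style of MSstats,

$$y_{i,j(i),k,l} = \mu + G_i + S(G)_{j(i)} + P_k + R_l
  + (G\times P)_{i,k} + (P\times R)_{k,l} + \varepsilon_{i,j(i),k,l},$$

with group $G_i$ (the reference channel is group 0 with its effects
anchored at zero), subject-within-group $S(G)_{j(i)}$, peptide $P_k$, run
$R_l$ and the two interactions, and tests $H_0: G_1 = G_2$ with a t-test
on the fitted contrast. The analyst must decide whether subject and run
effects are fixed or random -- four variants, `FF`, `FR`, `RF`, `RR` --
and the decision matters: when the model treats truly random subject
effects as fixed, the standard error of the group contrast omits the
between-subject variance and the test rejects far too often. This package
implements all four variants (plus AIC-based selection among them) exactly
so that this behaviour can be studied, not because we recommend them.

## The logistic-regression tests

The alternative implemented here turns the regression around. Working on
log2 *relative* intensities $y_{j,k}$ -- which cancel $P_k$, $R_l$ and
$(P\times R)_{k,l}$ by construction, so no run-effect decision is needed --
group membership is modelled as the outcome:

$$\operatorname{logit} P(Z_j = 1) = \alpha + \beta_1 y_{j,1} + \dots +
  \beta_K y_{j,K},$$

and protein-level significance is the joint null
$H_0: \beta_1 = \dots = \beta_K = 0$. Batch indicators, when present, enter
as additional fixed columns. Five tests are provided:

* **L** — likelihood-ratio test against the intercept(+batch) model,
  $\chi^2_K$ null;
* **W** — Wald quadratic form of the peptide coefficients in their
  estimated covariance, $\chi^2_K$ null;
* **W1** — inverse-variance-pooled one-parameter Wald test: with weights
  $t_k \propto 1/\widehat{\operatorname{Var}}(\hat\beta_k)$, the pooled
  $\hat\beta_p = \sum_k t_k\hat\beta_k$ with variance
  $A = t'\widehat{\operatorname{Var}}(\hat\beta)t$ gives
  $W_1 = \hat\beta_p^2/A$, $\chi^2_1$ null;
* **WS** — Wald test of $\beta^*$ in the collapsed model
  $\operatorname{logit}P(Z_j=1) = \alpha + \beta^* \sum_k y_{j,k}$,
  $\chi^2_1$ null;
* **SVC** — a variance-component score test in the style of kernel
  association tests: the $\beta_k$ are treated as random with variance
  $w_k\tau$ and $H_0:\tau = 0$ (a boundary hypothesis) is scored as
  $Q = (Z-\hat\mu_0)' Y W Y' (Z-\hat\mu_0)$ with $\hat\mu_0$ the null
  fitted probabilities and flat prior weights $w_k = 1$ by default.

`W1` and `WS` presume homogeneous peptide effects; `W`, `L` and `SVC` do
not, which is why only the latter respond to sign-mirrored
group-by-peptide interaction patterns.

### The SVC null distribution

Under $H_0$, $Q$ is distributed as a weighted mixture
$\sum_k \lambda_k\chi^2_{1,k}$, where the $\lambda_k$ are the nonzero
eigenvalues of $P^{1/2} K P^{1/2}$ with kernel $K = YWY'$. For $P$ we use
the score-variance projection of the null logistic model,

$$P = \hat V - \hat V X_0 (X_0'\hat V X_0)^{-1} X_0'\hat V, \qquad
  \hat V = \operatorname{diag}\{\hat\mu_{0j}(1-\hat\mu_{0j})\},$$

with $X_0$ the intercept-plus-batch design. This is the standard form for
score tests of variance components in generalized linear models; its
correctness here is certified empirically by the type-I calibration checks
in the test suite rather than by fiat. The eigenvalues are computed from
the $K\times K$ matrix $W^{1/2}Y'PYW^{1/2}$ (identical nonzero spectrum),
so the cost does not grow with the number of subjects, and eigenvalues
below $10^{-10}\,\lambda_{\max}$ are truncated: the numerical rank is at
most $\min(n - \operatorname{rank} X_0,\ K)$.

Tail probabilities of the mixture come from numerical inversion of the
characteristic function (the Davies/Imhof integral),

$$P(Q > q) = \frac12 + \frac1\pi \int_0^\infty
  \frac{\sin\theta(u)}{u\,\rho(u)}\,du,$$

integrated panel by panel (one half oscillation period per panel) and
truncated when analytic tail bounds fall below $10^{-7}$, inside the
$10^{-6}$ absolute-accuracy target. If the integration fails, a Liu-type
four-moment chi-square approximation is substituted and the result records
which path was taken. The test suite checks the inversion against closed
forms (equal weights, single weight) and against $10^6$-draw Monte-Carlo
tails.

### Fitting and the small-sample failure mode

The logistic maximum-likelihood fit is a plain Newton/IRLS iteration with
convergence declared when the largest absolute score component drops below
$10^{-8}$ (at most 100 iterations), with step-halving as a safeguard. At
$n = 20$ subjects and $K = 4$ peptides, quasi-complete separation is
common. Two things happen then: the deviance still converges -- so the
likelihood-ratio test remains computable and in fact becomes anti-
conservative -- while the Wald statistics collapse toward zero because the
coefficient variance grows faster than the coefficient (the Hauck--Donner
effect). We flag fits whose coefficients pass 15 on the log-odds scale
without score convergence (or whose information matrix degenerates) as
separated; Wald-type tests on flagged fits report `NA`, and the benchmark
counts `NA` as a non-rejection (a converged-only rate is reported
alongside). This reproduces the near-zero Wald rejection rates at small
sample sizes without discarding repetitions.

## The LMM baselines

All four variants are estimated by maximum likelihood (`REML = FALSE`),
not REML, because the variants differ in their fixed-effect structure and
their AIC values are only comparable under ML. The all-fixed variant is a
constrained least-squares fit on a hand-built design with sum-to-zero
contrasts for every fixed factor and the reference group anchored at zero;
the same fixed design (minus the random factors) is passed to `lme4` for
the random variants. The group contrast $G_1 - G_2$ is twice the
coefficient of the $\pm 1$ group column.

Two conventions had to be fixed because the field leaves them open:

* **Degrees of freedom for the t-test**: residual degrees of freedom,
  observations minus the rank of the fixed design, for every variant
  (Satterthwaite-type corrections are deliberately out of scope). At the
  sample sizes studied the t is close to normal and the choice is
  immaterial to two decimals.
* **Batch in fixed-subject variants**: a subject-constant batch column is
  collinear with a fixed subject block, so batch enters only the
  random-subject variants of the LMM (it always enters the logistic
  models).

## The simulator

`simulate_dataset()` draws complete two-channel tables from the model
above: total sample size $n \in \{20, 50, 100\}$ split equally between two
groups, $K = 4$ peptides, global mean 15 (log2 scale), error variance 0.5
per channel, subject and run variances 0.25, peptide and peptide-by-run
variances 0.1. Fixed-effect versions of subject, run and the interactions
use equally spaced symmetric grids $-e, \dots, +e$ with
$e = \sqrt{3(m-1)/(m+1)}\,\sigma$, so every grid has exact mean zero and
population mean square $\sigma^2$ (an algebraic identity the test suite
checks for $m = 2..10$); random versions are independent normals with the
same variances. Group scenarios are GS0 ($G_i = 0$) and GS1
($G_2 - G_1 = 1/3$); interaction scenarios none / IS1 / IS2 put
$\sigma^2_{GP} = 0, 0.05, 0.1$ on the sign-mirrored ($(-1)^i$)
group-by-peptide profiles.

Design choices the generative description leaves open, decided once here:

* **Runs**: one run per endogenous sample, with the reference measured in
  the same run. This is the standard spike-in MRM design and is exactly
  what makes the ratio transform cancel $R_l$ and $(P\times R)_{k,l}$.
* **Run assignment**: groups alternate across the run sequence (odd runs
  group 1, even runs group 2). With the monotone fixed-run grid, a
  block-wise assignment would confound group with run level; interleaving
  keeps the grid balanced between groups, which is what any sensible
  randomization achieves and what the reported behaviour of the
  random-run LMM variants requires.
* **Sample-size semantics**: `n_total` is the total endogenous sample
  size, split equally ($J(1) = J(2) = n/2$).
* **Seeding**: every repetition derives its own stream from
  (master seed, repetition counter), so Monte-Carlo cells are reproducible
  and order-invariant, and all derived seeds stay below $2^{31}$.

An important, non-obvious consequence of the *fixed*-subject scenarios:
both groups receive the same subject grid, so every covariate profile in
one group has a near-twin in the other. The design is then nearly
mirrored, the logistic MLE is pulled toward zero, and all LR-SAM tests
become conservative -- strongly so for the pooled 1-df tests. This is a
property of the study conditions, not a bug; under random subject effects
the same tests sit at their nominal level, which is what the calibration
tests assert.

## Data handling

Readers accept both the Area-Ratio layout and raw endogenous/reference
intensity pairs (CSV or TSV, remappable column names); the canonical
internal form is the log2 ratio. Non-positive intensities are rejected by
default (their logarithm is undefined) with an explicit opt-in to drop
them; transition-level duplicates can be rolled up by the mean (or median)
of log2 values. Per-protein matrices are complete-case: subjects missing
any peptide of a protein are dropped and counted -- no imputation is ever
performed, since none is defined for this design. Quantile normalization
(the classical rank-mean algorithm, with average-tie handling and linear
interpolation for unequal per-sample counts) is delegated to
`limma::normalizeQuantiles()` and verified against hand-computed oracles.

## What the tests do and do not show

The acceptance layer of the test suite re-estimates a set of published
type-I-error and power cells by Monte Carlo (1000 repetitions per cell,
nominal level 0.05, three-binomial-standard-error tolerances) and checks
the exact structural properties: grid moments, the K = 1 coincidence of
`W`/`W1`/`WS`, the mixture tail against simulation, the equivalence of the
all-fixed LMM to constrained least squares, and recovery of a planted
signal in a ten-protein synthetic study at a Bonferroni threshold.
Problem sizes in the routine suite are chosen to keep a full run in
minutes: the heaviest cells are $n = 100$ with 1000 repetitions and a
single random-subject LMM cell at $n = 50$.

The simulator emulates balanced, complete, normally distributed data with
at most one batch structure and exactly two groups. Real MRM studies have
missing peptides, heavy-tailed and heteroscedastic intensities,
transition-level interference and unbalanced groups; passing the synthetic
benchmarks therefore certifies the statistical machinery, not robustness
to those artefacts. Known limitations, deliberate: no Firth or exact
logistic regression for the separated small-sample fits, no more than two
comparison groups, Bonferroni as the only multiplicity correction, and no
Satterthwaite/Kenward-Roger degrees of freedom for the LMMs.
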