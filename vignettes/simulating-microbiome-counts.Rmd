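---
title: "Simulating realistic microbiome count data with micosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating realistic microbiome count data with micosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Benchmarking a statistical method for microbiome data requires simulated
count tables in which the truth is known but the data look real: sparse
(most cells are zero), overdispersed, compositional (each row of relative
abundances sums to one), with heavily skewed per-taxon distributions and
non-trivial taxon–taxon correlation. `micosim` fits a generative model to
a *template* count table — a real samples × taxa OTU table — and simulates
new tables that reproduce the template's marginal distributions and
correlation structure, optionally with controlled changes (library sizes,
mean abundances, zero proportions, sample size, covariate effects) for
differential-abundance benchmarks.

## The model

Write $C_{ij}$ for the count of taxon $j$ in sample $i$,
$N_i = \sum_j C_{ij}$ for the library size,
$\pi_{ij} = C_{ij}/N_i$ for relative abundance, and
$Z_{ij} = I(C_{ij} > 0)$ for presence. The per-taxon margins are
$m_j = \sum_i Z_{ij}$, $p_j = \tfrac1n\sum_i \pi_{ij}$,
$\delta_j = m_j/n$; per-sample, $n_i = \sum_j Z_{ij}$.

**Step 1 — presence–absence.** Presence is modeled by thresholding a
latent Gaussian: $Z_{ij} = I(D_{ij} > 0)$ with
$D_{i\cdot} \sim \mathrm{MVN}(\theta + \eta_i, \tilde\rho)$. The taxon
effects $\theta_j$ and sample effects $\eta_i$ solve the margin equations
$$\sum_i \Phi(\theta_j + \eta_i) = m_j, \qquad
  \sum_j \Phi(\theta_j + \eta_i) = n_i,$$
iterated alternately from $\eta_i = 0$,
$\theta_j = \Phi^{-1}(m_j/n)$. Each coordinate update is a strictly
monotone scalar equation, solved by safeguarded Newton with bisection
fallback (inner tolerance $10^{-8}$); the outer loop stops when the
maximum margin residual falls below $10^{-6}$ or after 500 sweeps.
Margins are clipped into $[0.5,\, n-0.5]$ (and $[0.5,\, J-0.5]$) first,
because $m_j \in \{0, n\}$ forces an infinite effect; if user-supplied
margins leave the two totals unequal (the system is then inconsistent,
since both must equal the number of non-zero cells), the sample targets
are rescaled proportionally.

The latent correlation $\tilde\rho$ is the tetrachoric correlation matrix
of $Z$: for each pair of taxa, the bivariate-normal correlation whose
dichotomization at the margin-implied thresholds maximizes the 2×2 table
likelihood. Empty table cells receive a $+0.5$ continuity correction
before the likelihood is evaluated, except that perfectly concordant
(both off-diagonal cells empty) and perfectly discordant tables return
$\pm 1$ exactly, and pairs involving a constant column return 0. Because
pairwise estimates need not form a positive-definite matrix, eigenvalues
below $10^{-6}$ of the largest are floored, the matrix is rebuilt and
rescaled to unit diagonal.

**Step 2 — relative abundances.** Non-zero cells are filled through a
Gaussian copula with correlation $r^*$ estimated from ranks: all ties
(zeros included) are broken by `K = 100` independent random orderings;
each ordering's Spearman correlation $\phi^{(k)}$ is mapped to the
Pearson correlation of the latent normal via
$r^{(k)} = 2\sin(\pi\phi^{(k)}/6)$ and the $K$ matrices are averaged.
The average is made positive definite by flooring eigenvalues below
$10^{-10}$ of the largest and rescaling all eigenvalues to preserve the
trace — deliberately *not* re-normalizing the diagonal, in contrast to
the step-1 smoother.

To simulate, copula scores $W_{i\cdot} \sim \mathrm{MVN}(0, r^*)$ are
drawn and, per taxon, the $\tilde m_j$ present cells receive values in
the rank order of their $W$ scores:

* *nonparametric mode*: drawn from the template's non-zero values —
  without replacement when $\tilde m_j \le m_j$ (a permutation of the
  observed values), otherwise all $m_j$ values plus extra draws with
  replacement;
* *parametric mode*: each present cell gets the quantile
  $u = \Phi(W_{ij})$ of its fitted generalized-gamma distribution
  truncated at the library size (below).

Counts are then $C̃_{ij} = \tilde\pi_{ij} N_i$ with products in $(0,1)$
rounded up to one read (preserving the presence pattern) and all others
rounded to the nearest integer (half-up — R's banker's rounding would
send 2.5 to 2); realized library sizes $\tilde N_i$ are the row sums and
final abundances are renormalized by them.

## The parametric marginal

Each taxon's abundances define "survival times" $t_{ij} = 1/\pi_{ij}$,
right-censored at the library size: a cell is zero exactly when
$t_{ij} > N_i$ (the taxon fell below one read). Times follow a
three-parameter generalized gamma in the Prentice location-scale form
$$\ln t = -\mu + \sigma\,\ln(Q^2 g)/Q,\qquad g \sim \mathrm{Gamma}(Q^{-2}, 1),$$
with the lognormal limit $F(t) = \Phi((\ln t + \mu)/\sigma)$ at $Q = 0$.
The sign of $\mu$ is chosen so that larger $\mu$ means larger abundance.
The gamma shape is taken as $Q^{-2}$ rather than $1/|Q|$: only the
former admits the lognormal limit at $Q = 0$, and it is the choice under
which the moment-existence constraint $\sigma < 1/(2Q)$ (needed for the
second inverse moment when $Q > 0$) is exact. Distribution functions
delegate to `flexsurv`'s generalized gamma with the location negated;
moments use the closed form
$E[t^r] = e^{-r\mu}(Q^2)^{r\sigma/Q}\,\Gamma(Q^{-2} + r\sigma/Q)/\Gamma(Q^{-2})$.

**Fitting** is by censored moment matching plus a profile likelihood —
maximum likelihood on these sparse, heavy-tailed columns is deliberately
avoided. The first two empirical moments of $\pi$ are computed over all
observations with censored cells as zero. For a candidate $Q$,
$\sigma(Q)$ solves the CV² match (the squared coefficient of variation is
free of $\mu$), bracketed on $(10^{-6}, 0.999/(2Q))$ for $Q>0$ and
$(10^{-6}, 20)$ otherwise; $\mu(Q)$ then matches the first moment
exactly. $Q$ maximizes the zero-pattern profile likelihood
$$\sum_{i:\pi_{ij}=0} \ln S(N_i) + \sum_{i:\pi_{ij}>0} \ln F(N_i)$$
over the grid $Q \in [-3, 3]$ in steps of 0.1 (feasible points only),
refined by golden-section search to $10^{-4}$; $|Q| < 10^{-3}$ is
evaluated through the lognormal limit, and if no candidate admits a
feasible $\sigma$ the fit falls back to lognormal with a warning. The
indicator in the zero-pattern likelihood partitions zero and non-zero
cells (an abundance cannot exceed one, so the non-zero term's condition
is $\pi > 0$).

The fitted CDF predicts presence: $P(Z_{ij}=1) = F_j(N_i)$. Parametric
presence sampling thresholds $D \sim \mathrm{MVN}(0, \tilde\rho)$ at
$\Phi^{-1}(1 - F_j(N_i))$, so each cell's marginal presence probability
is honored without needing $\theta, \eta$. Present cells draw
$t = F^{-1}(u\,F(N_i))$ — the inverse CDF on the truncated support — with
$u = \Phi(W_{ij})$, which preserves both the per-cell truncation and the
cross-taxon dependence. (The coupling of marginals to the copula is not
uniquely determined by the model description; per-cell quantile coupling
was chosen over rank assignment of an i.i.d. truncated sample because it
makes the parametric and nonparametric paths structurally identical and
keeps the truncation exact per cell.)

### When the parameters are identifiable

Three regimes matter, and the test suite exercises all of them:

* **No zeros.** If a taxon is always present, $F(N_i) = 1$ to machine
  precision for every feasible $Q$, the profile likelihood is numerically
  flat, and $Q$ (hence $\sigma$, which is solved given $Q$) is
  *unidentifiable* — only $\mu$ (the first moment) is pinned. This is a
  property of the estimator, not a bug.
* **Mild censoring** (roughly 5–30 % zeros): all three parameters are
  well identified; with 5000 observations the fit recovers them to a few
  percent.
* **Heavy censoring** (≳ 40 % zeros): replacing censored abundances by
  zero is no longer a negligible perturbation of the moments — the
  typical abundance is near the detection limit $1/N$ — so $\sigma$ and
  $Q$ absorb the truncation bias. Prevalence predictions remain accurate
  (the profile step matches the zero pattern by construction), which is
  what the simulator actually needs.

## Changing the simulation

* **Mean abundances, parametric.** $E[\pi] \propto e^{\mu}$, so a target
  $p_j$ maps to $\mu_j \mapsto \mu_j + \ln(p_j^{new}/p_j^{cur})$ with
  $(\sigma_j, Q_j)$ fixed; library-size changes propagate through
  $F_j(N_i)$ to the zero pattern automatically.
* **Mean abundances, nonparametric.** The target mean of non-zero cells
  is $p_j^{(1)} = p_j/\delta_j$; the exponent $\alpha_j$ solving
  $\mathrm{mean}(v^{\alpha}) = p_j^{(1)}$ over the taxon's non-zero
  values $v$ is unique (the mean of $v^\alpha$ is strictly decreasing in
  $\alpha$ for $v \in (0,1)$) and found by bracketed root finding.
* **Zero proportions, nonparametric.** Target $\delta_j$ become margins
  $m_j = \mathrm{round}(n\,\delta_j)$ and the occupancy model is
  refitted; sample margins are rescaled so the totals stay consistent.
  Changing library sizes nonparametrically requires explicit $m_j, n_i$
  overrides — the empirical model cannot predict how the zero pattern
  responds to depth, which is the main argument for the parametric mode
  in controlled experiments.
* **Covariate effects.** Two balanced binary covariates split the sample
  into four equal groups; "causal" taxa drawn from the top-100 abundance
  pool (sets of 10 or 20 with a fixed overlap of 5) receive log-linear
  effects, and group means are renormalized to the simplex:
  $$p_j = \frac{e^{X_1\beta_1 I(j\in M_1) + X_2\beta_2 I(j\in M_2)}\,p^0_j}
    {\sum_{j'} e^{\,\cdot\,}\,p^0_{j'}}.$$
  Renormalization shifts *every* taxon — the compositional null — and its
  log is the location offset applied to all taxa in parametric mode.
  Correlation matrices are not refitted per group; group library sizes
  are resampled with replacement from the template on dedicated seed
  streams. The default effect grid is $\beta_1 \in \{0.5, 1, 1.5, 2\}$
  with $\beta_2 = 1$ as a fixed confounder.

## The synthetic template generator

`make_synthetic_template()` exists so every stage is testable without any
external download. It draws latent Gaussian scores with a known block or
exchangeable correlation, pushes them through per-taxon generalized-gamma
marginals, censors below one read, and rounds with the same rules as the
simulator. Communities are two-tier, as in real data: a few dominant taxa
(default 5) with modest dispersion carry most of the read mass and are
essentially always present, while the sparse remainder draws target
prevalences from a Beta distribution whose mean is set so the expected
zero fraction matches its target (default 0.85), each location pinned so
the detection probability at the reference library size equals the target
prevalence. Expected relative abundances sum to one, so realized library
sizes track the drawn log-normal sizes (default log-mean 9.2, log-sd 0.5,
i.e. median ≈ $10^4$ reads). The default 150 × 100 shape mirrors a
moderately sparse stool template at a taxon count chosen for fast tests;
dispersion defaults ($\sigma \in [1.5, 2.5]$ for rare taxa) are what give
rare taxa realistic intermittent detection.

What the generator does *not* emulate: taxonomy and phylogeny, batch or
longitudinal structure, and — most importantly — zeros that are not
censoring (true absences). Two of its artifacts are worth knowing when
interpreting passing tests. First, *compositional closure*: the
mass-carrying taxa of any closed composition are pushed toward negative
pairwise correlation regardless of the latent correlation used to
generate them, so latent-correlation recovery is verified on data from
the estimator's own sampling model, while count-table fidelity is
verified as self-consistency (the simulated rank correlation converges to
the fitted $r^*$). Second, *rank attenuation at the detection limit*:
randomly broken ties carry no dependence signal, so the copula
correlation estimated from a very sparse taxon is attenuated toward zero
— by design, since re-simulation re-applies the same mechanism and
reproduces the observed-data correlation.

## Numerical conventions and degenerate inputs

* Distances involving two all-zero samples are 0 with a warning; an
  all-zero sample has richness 0 and Shannon 0.
* Beta-dispersion uses the principal-coordinate convention: squared
  distances to the centroid subtract the imaginary-axis contribution of
  negative eigenvalues and are floored at zero before the square root; an
  all-identical group short-circuits to zero distances.
* PERMANOVA permutes labels freely (no strata), 999 permutations by
  default, $p = (1 + \#\{F_{perm} \ge F\})/(1 + n_{perm})$.
* Rank ties in copula scores (possible only through floating-point
  coincidence) break by cell index.
* All sampling derives named substreams from one top-level seed, so
  adding a stage never perturbs earlier draws and every result is exactly
  reproducible from `seed`.
* Template filtering defaults (`min_lib_size = 3000`,
  `min_taxon_prevalence = 4`) follow common template-preparation
  practice; the explicit `keep_samples` list (applied before the
  library-size filter, a documented and configurable order) stands in
  for study-specific metadata filters such as keeping first visits only.

## Problem sizes used by the tests

The default test suite fits the 150 × 100 synthetic fixture, checks
margin calibration over 20 simulated replicates, and runs
template-vs-simulated PERMANOVA over 20 seeds at 999 permutations;
distributional checks use up to $10^6$ Monte-Carlo draws and parameter
recovery uses 5000 observations per fit. These sizes were chosen so the
whole suite documents the method's behaviour at meaningful scale while
remaining quick to run on a laptop.

## Worked example

```{r, eval = FALSE}
library(micosim)

syn <- make_synthetic_template(seed = 42)
ct  <- filter_template(syn$ct, min_lib_size = 0, min_taxon_prevalence = 4)

model <- micosim_fit(ct, mode = "nonparametric", seed = 1)
sim   <- micosim_simulate(model, seed = 2)

glance(model)
tidy(model)
compare_report(ct, sim, n_perm = 999, seed = 3)
autoplot(sim, model = model)
```

## Known limitations

Inherited from the modeling approach: correlations are those expressible
by a Gaussian copula and a probit threshold model; zeros are treated as
censoring; covariates are binary and cross-sectional; the parametric
location shift encodes only compositional mean effects. Inherited from
the estimators: $Q$ is unidentifiable for taxa without zeros, and
$\sigma, Q$ are biased for taxa whose typical abundance sits at the
detection limit. The nonparametric mode is the more faithful reproduction
of a template; the parametric mode is the right tool when simulations
must change means, depths, or covariates coherently.
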