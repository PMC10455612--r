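---
title: "Methods: Bayesian estimation of the multidimensional generalized graded unfolding model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian estimation of the multidimensional generalized graded unfolding model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Noncognitive items (personality, attitudes, interests) are often answered by
an *unfolding* process: a respondent endorses an item most strongly when the
item's position on the latent continuum matches their own, and endorsement
falls off in both directions.  The generalized graded unfolding model (GGUM)
formalizes this for polytomous responses $Z \in \{0, \dots, C\}$.  With
$M = 2C + 1$, discrimination $\alpha_i > 0$, location $\delta_i$, and
subjective response category thresholds $\tau_{i1}, \dots, \tau_{iC}$
(with $\tau_{i0} \equiv 0$), the category probabilities are

$$
P(Z_{ij} = z \mid \theta_j) =
\frac{\exp\{\alpha_i [z(\theta_j - \delta_i) - \sum_{k=0}^{z}\tau_{ik}]\} +
      \exp\{\alpha_i [(M - z)(\theta_j - \delta_i) - \sum_{k=0}^{z}\tau_{ik}]\}}
     {\sum_{w=0}^{C} \left(
      \exp\{\alpha_i [w(\theta_j - \delta_i) - \sum_{k=0}^{w}\tau_{ik}]\} +
      \exp\{\alpha_i [(M - w)(\theta_j - \delta_i) - \sum_{k=0}^{w}\tau_{ik}]\}
      \right)}.
$$

Each numerator pairs a category $z$ with its mirror $M - z$, which makes the
response function symmetric about $\delta_i$ — the defining property of an
ideal-point model.

The multidimensional extension (MGGUM) implemented here assumes
*between-item simple structure*: each item loads exactly one of $D$
correlated traits.  The multidimensional kernel replaces the signed distance
by the weighted Euclidean distance
$\sqrt{\sum_d \alpha_{id}^2 (\theta_{jd} - \delta_{id})^2}$ and the
thresholds by $\psi_{ik} = \sum_d \alpha_{id} \tau_{ik}$.  Because the
unidimensional response function is symmetric about $\delta$, the
multidimensional kernel restricted to one loading dimension is *identical*
to the unidimensional one; the package enforces this reduction in its test
suite to $10^{-10}$.

Traits follow $\boldsymbol\theta_j \sim \mathrm{MVN}(\mathbf{X}_j
\boldsymbol\beta, \boldsymbol\omega)$: an optional latent regression on
person covariates $\mathbf{X}$ (measurement-error-free estimates of
trait-covariate relations), with $\boldsymbol\omega$ restricted to a
*correlation* matrix so the latent scale is identified (mean 0, unit
residual scale per dimension).  A consequence of keeping the printed model
form is that the marginal trait variance exceeds 1 when
$\boldsymbol\beta \neq 0$; we do not re-standardize.  Missing responses are
assumed missing completely at random and simply drop out of the likelihood;
missing covariates are not supported.

## Priors and estimation settings

Items are labelled by *direction* from their location: `negative`
($\delta < -1.5$), `positive` ($\delta > 1.5$), `neutral` otherwise
(boundaries inclusive to neutral).  Priors (second arguments are SDs):

| parameter | prior | constraint |
|---|---|---|
| $\delta$, negative items | $N(-1, 1)$ | $\delta \le 0$ |
| $\delta$, neutral items | $N(0, 1)$ | none |
| $\delta$, positive items | $N(1, 1)$ | $\delta \ge 0$ |
| $\tau$, 2 options | $N(-2, 2)$ | none |
| $\tau_{1..3}$, 4 options | $N(-3, 2), N(-2, 2), N(-1, 2)$ | none |
| $\alpha$ | $\log N(0, 0.5)$ | $\alpha > 0$ |
| $\beta$ | independent $N(0, 1)$ | none |
| $\boldsymbol\omega$ | LKJ(1) | correlation matrix |

Defaults: 2 chains, 2000 iterations each with the first 1000 discarded as
burn-in, so 2000 retained draws.  Convergence is declared when the
Gelman-Rubin statistic
$\hat R = \sqrt{\{(n-1)/n \cdot W + B/n\}/W}$ is below 1.05 for every
scalar parameter (undefined $\hat R$ from zero within-chain variance counts
as nonconverged).  Point estimates are posterior means (EAP), uncertainty
is posterior SDs, and intervals are equal-tailed 95% quantiles; a
regression coefficient is "significant" when its 95% interval excludes 0.

## The sampler

No Hamiltonian Monte Carlo backend is used; the package implements an
adaptive Metropolis-within-Gibbs sampler designed around the specific
geometry of the unfolding posterior:

* **Person traits** $\boldsymbol\theta_j$: coordinate-wise slice sampling
  (stepping-out with shrinkage) against the conditional normal prior given
  the other coordinates — tuning-free and nearly uncorrelated from draw to
  draw — plus one *independence* proposal per iteration drawn from the
  trait prior $\mathrm{MVN}(\mathbf{X}_j\boldsymbol\beta,
  \boldsymbol\omega)$.  The independence move matters because a single
  person's posterior can be bimodal — a low-agreement response pattern fits
  on either side of the item locations — and a local move cannot cross
  between those modes.
* **Item blocks**: each item's $(\log\alpha_i, \delta_i, \psi_{i1..C})$ with
  $\psi_{ik} = \alpha_i\tau_{ik}$ is updated jointly with a Haario-style
  adaptive proposal (empirical covariance of the visited states, scaled
  toward 30% acceptance, frozen at the end of burn-in).  The $\psi$
  parametrization is used because in $(\alpha, \tau)$ the posterior lies on
  a hyperbolic ridge ($\tau \sim 1/\alpha$) that defeats Gaussian
  proposals.  A 15% share of proposals is over-dispersed ($3\times$ scale)
  and 5% are reflections through the adapted mean, both of which help the
  chain traverse between local modes.  Each iteration additionally runs one
  coordinate-wise slice-sampling sweep over the same block, which crosses
  the long flat ridges of binary and extreme-location items that
  random-walk proposals cover slowly.
* **Regression coefficients** $\boldsymbol\beta$: exact conjugate Gibbs draw
  (multivariate-normal full conditional).
* **Trait correlations** $\boldsymbol\omega$: element-wise random-walk
  Metropolis on the off-diagonals under the flat LKJ(1) prior, with a
  positive-definiteness check; several rounds per iteration since each
  costs only $O(D^3)$ after the residual cross-product is cached.
* **Reflection moves.**  The unfolding kernel is symmetric in
  $(\theta - \delta) \to -(\theta - \delta)$, which creates genuine
  multimodality: (i) a *neutral* item's location is sign-ambiguous when the
  rest of the model only weakly pins it — handled by a per-item sign-flip
  proposal $\delta_i \to -\delta_i$; (ii) when *every* item on a dimension
  is neutral, flipping $\theta_d$, those $\delta$s, the $d$-th row of
  $\boldsymbol\omega$ and the $d$-th column of $\boldsymbol\beta$ is an
  *exact* symmetry of the posterior — handled by a dimension-reflection
  proposal whose Metropolis ratio involves only the dimension's
  sign-bounded items (and is accepted with probability 1 when there are
  none).  (iii) For polytomous items, swapping adjacent thresholds changes
  only one cumulative sum, a label-switching near-symmetry handled by an
  explicit swap proposal.
* **Threshold ordering** is *not* enforced at estimation time (GGUM
  thresholds need not be monotone); ordered thresholds arise in simulation
  only from the disjoint generating intervals of the 4-option design.

Because a random-walk sampler needs more sweeps per effective draw than
Hamiltonian methods, one recorded iteration comprises several internal
scans (`n_person_scans`, `n_item_scans` in `mcmc_config()`); the
iteration/burn-in accounting above is unchanged.  All randomness flows
through R's RNG, so a seed fixes the entire fit; chain $c$ runs under
`seed + c - 1`.

A consequence of sampling the *honest* posterior under the exact
dimension-reflection symmetry: in replications where a dimension has no
directional anchor item, the chains hop between the mirrored modes, the
EAP of those locations shrinks toward zero, and recovery correlations for
that dimension are diluted.  With 5 items per trait and locations drawn
from $U(-2, 2)$ this happens in roughly a quarter of simulated dimensions.
We consider mode-committed chains (which would report an arbitrary sign
with high confidence) a worse alternative, and note the dilution when
interpreting recovery summaries.

## The synthetic-data generator

The generator reproduces the simulation studies' design: $\alpha \sim
U(0.5, 2)$, $\delta \sim U(-2, 2)$; thresholds $U(-3, -1)$ for two response
options and $U(-3.5, -2.5), U(-2.5, -1.5), U(-1.5, -0.5)$ for four; traits
and two covariates jointly multivariate normal with zero means, unit
variances, a common between-trait correlation, zero between-covariate
correlation, and a common trait-covariate correlation; responses drawn
from the kernel; and missingness applied completely at random as an
*exact-count* mask (`round(p * J * I)` cells drawn without replacement), so
small instances hit the nominal proportion exactly — a testability choice;
i.i.d. Bernoulli masking differs only at $O(1/\sqrt{JI})$.  Items load
traits in consecutive blocks, which is statistically equivalent to any
fixed assignment under simple structure.  What the generator does *not*
emulate: non-normal trait distributions, informative (MAR/MNAR)
missingness, cross-loadings, local dependence, or careless responding —
so passing recovery tests speaks to the estimator under the model's own
assumptions, not to robustness against real-data violations.

## Model comparison

`waic()` and `loo()` work on the draws-by-observations pointwise
log-likelihood matrix and report on the deviance scale ($-2 \times$ elpd),
so *smaller is better*: lppd and $p_\text{WAIC}$ use log-sum-exp and the
$(S-1)$-denominator variance; PSIS-LOO smooths the largest
$\min(0.2S, 3\sqrt{S})$ importance ratios per observation with a
generalized Pareto fit (profile-likelihood point estimate with a weak
prior pulling the shape toward 0.5), truncated at the raw maximum, and
reports the shape $\hat k$ per observation ($\hat k > 0.7$ flags an
unreliable observation; a degenerate tail falls back to truncated
importance sampling and records `NA`).  `select_model()` picks the smaller
criterion; exact ties go to the fewer-dimension candidate, mirroring the
parsimony argument for equivalent models.

## Replication harness

`run_condition_study1()` scores parameter recovery (Pearson correlation,
bias = mean of estimate minus truth, absolute error) per dimension and
averages over dimensions and replications; trait scores are additionally
split at $\pm 1.282$ (the standard-normal 10th/90th percentiles, boundaries
to the middle group) because extreme trait levels are known to be harder
to estimate.  `run_condition_study2()` fits the unidimensional and
2-dimensional models to the same 2-trait data and records which WAIC and
LOO prefer.  Replication seeds derive deterministically from (base seed,
replication, redraw counter); nonconverged replications are discarded and
reproducibly replaced, and a run aborts if more than half of all attempts
fail to converge.  Aggregates are invariant to replication order.

## Problem sizes and numerical choices

Probability work is done in log space with max-subtraction and is finite
for $|\alpha(\theta - \delta)|$ up to at least 50; normalization is checked
to $10^{-10}$.  The test suite runs the harness at deliberately small
problem sizes (the 2-trait analogue of the hardest recovery cell at
$N = 200$ with four replications per setting, dimensionality-selection
cells at three replications each, one favorable recovery fit at
$N = 1000$ with 20 four-option items) and the acceptance script uses the
same favorable fit plus 10 selection replications at $N = 200$; these sizes were chosen so a
full run completes on a single CPU in minutes while keeping Monte-Carlo
error quantifiable (reported as $\pm 2$ empirical SEs).  The full
condition grids (192 and 96 cells, 100 replications) are reachable through the same
functions by passing larger `n_reps` and the full condition lists.

## Known limitations

* Within-item multidimensionality (cross-loadings) is out of scope.
* Marginal maximum likelihood is not provided; estimation is MCMC-only.
* Missing covariate values are rejected, not imputed.
* The random-walk sampler, even with the mode-jumping moves, mixes more
  slowly than Hamiltonian Monte Carlo; hard cells (4 options, missing
  data, unanchored dimensions) show nonconvergence rates above the few
  percent reported for HMC backends, which the harness absorbs by
  discard-and-redraw.
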