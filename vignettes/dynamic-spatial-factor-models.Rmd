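---
title: "Dynamic spatial factor models for censored areal count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic spatial factor models for censored areal count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsfactor)
```

## The model

dsfactor jointly models `K` related count outcomes observed on `I` areal
units (counties, districts) over `J` time points.  The motivating setting
is syndemic surveillance — several outcomes (overdose deaths, emergency
department visits, treatment counts, buprenorphine prescriptions, HCV and
HIV diagnoses) that are believed to reflect common latent processes — but
nothing in the package is specific to those outcomes.

Counts are Poisson around a population-scaled offset,

$$Y_{ijk} \sim \mathrm{Poisson}(E_{ijk}\,\lambda_{ijk}), \qquad
  E_{ijk} = P_{ij}\, r_k,$$

where `P` is the unit-time population and `r_k` the statewide rate of
outcome `k` at the baseline time (`baseline_rates()`), so that
$\lambda_{ijk}$ is a relative risk.  The log relative risk is a
confirmatory factor model

$$\log \lambda_{ijk} = \Gamma_k' F_{ij} + \varepsilon_{ijk},
  \qquad \varepsilon_{ijk} \sim N(0, \sigma^2_k),$$

with an `K x m` loadings matrix $\Gamma$ whose sparsity pattern is fixed a
priori.  The default pattern (`default_pattern()`, `K = 6`, `m = 4`) has a
first factor shared by all outcomes and three further factors each shared
by one meaningful pair — a deliberate departure from the conventional
lower-triangular loadings constraint, chosen for interpretability.

Small-count suppression is handled in the likelihood: a censored cell is
known only to lie in the interval `[1, 5]` (read inclusively, matching
surveillance suppression practice) and contributes
$\log \sum_{y=1}^{5} \mathrm{Poisson}(y; E\lambda)$
(`pois_interval_loglik()`).  Overdispersion is carried by
$\varepsilon_{ijk}$; the censored term uses the standard Poisson pmf.

## The latent factor prior

Each factor column follows an intrinsic CAR (ICAR) prior in space with
AR(1) dynamics in time.  Writing innovations
$e_{i1m} = f_{i1m} - \mu_{1m}$ and, for $j \ge 2$,
$e_{ijm} = (f_{ijm} - \mu_{jm}) - \eta_m (f_{i(j-1)m} - \mu_{(j-1)m})$,
the joint density is, up to a constant,

$$\log \pi(F \mid \mu, \eta) =
  -\tfrac12 \sum_{m}\sum_{j}\sum_{(i,l) \in \mathcal{E}}
  (e_{ijm} - e_{ljm})^2
  \;-\; \tfrac{I}{2} \sum_m \sum_j \bar e_{jm}^2 .$$

The first (pairwise) part reproduces exactly the familiar ICAR
conditionals — mean equal to the neighbour average around the (AR-shifted)
centering level and variance $1/w_{i+}$ — which `joint_logprior()` exposes
and the test suite verifies by numerical differentiation (a Brook's-lemma
check).  The fully specified conditional variance is what makes the factor
scale identifiable.

The second term needs explanation, because it is the package's own design
choice.  The pairwise density is flat along the constant vector within
each (year, factor): it cannot distinguish fields that differ by a
statewide shift, which is why ICAR models are usually paired with a
per-year sum-to-zero constraint.  Instead of enforcing that constraint by
projection inside the chain, dsfactor completes the prior with a proper
Gaussian component on the mean innovation,
$\bar e_{jm} \sim N(0, 1/I)$.  Three properties motivate this choice:

* the completed prior is proper, so every Gibbs/MH block targets a
  well-defined posterior;
* the statewide mean $\mu_{jm}$ acquires exactly the Gaussian full
  conditional (precision `I` from the year-`j` term, `I eta^2` from year
  `j+1`) that `update_mu()` draws from — under a hard constraint the mean
  would be a deterministic function of the field and a flat-prior Gibbs
  draw would not exist;
* the constraint still holds in distribution: the per-year mean of
  `f - mu` stays within $O(1/\sqrt{I})$ of zero, vanishing at exactly the
  rate at which the hard constraint becomes binding.

During development we also ran the variant that hard-centers the field
after every sweep.  Because the projection is likelihood-blind, it injects
level noise of order $1/\sqrt{I}$ per year and factor on every iteration;
empirically the chain then drifts into the saturated mode in which the
heterogeneity terms absorb the factor signal and $\sigma^2$ diverges.  The
completion removes the injection and the pathology with it.
`center_factors()` is still exported for constructing exactly centered
fields (the generator uses it implicitly: `sample_factor_prior()` draws
exactly centered innovations through the eigendecomposition of the graph
Laplacian, i.e. with covariance equal to the Laplacian pseudo-inverse on
the sum-to-zero subspace).

Priors elsewhere are weakly informative: free loadings $N(0, 10^2)$ (one
anchor per factor truncated to the positive half-line, which fixes column
signs), $\eta_m \sim \mathrm{Unif}(0,1)$,
$\sigma^2_k \sim \mathrm{InvGamma}(0.5, 0.5)$, and flat priors on the
statewide means $\mu_{jm}$.

## Identification by LQ decomposition

The likelihood is invariant under $\Gamma \to \Gamma H$,
$F \to H'F$ for any orthogonal `H`.  With a non-lower-triangular pattern
this rotation cannot be removed by the usual triangular constraint, so the
package identifies the model through an LQ decomposition *inside* the
sampler: for any conforming $\Gamma$,

1. transpose and partition $\Gamma' = [\Gamma_1' \mid \Gamma_2']$ with
   $\Gamma_1'$ the square block of the first `m` outcomes (in the
   pattern's outcome order);
2. QR-decompose $\Gamma_1' = Q_g R_1$ by modified Gram-Schmidt (the pivot
   is a column norm, hence positive — `gram_schmidt_qr()` enforces the
   positive-diagonal convention explicitly regardless);
3. set $R_2 = Q_g' \Gamma_2'$, $R = [R_1 \mid R_2]$, and return
   $L = R'$, $Q = Q_g'$, so that $\Gamma = LQ$ holds exactly.

The orientation deserves a note: with $\Gamma' = Q_g R$ one has
$\Gamma = R' Q_g'$, so returning $Q = Q_g'$ makes the stated identity
$\Gamma = LQ$ literally true.  `L` (leading block lower triangular with
positive diagonal) and $\tilde F = Q F$ are invariant to the rotation and
are the quantities parameter recovery is scored on.  The likelihood is
always evaluated through the product `L Q` ("the decomposition is enforced
in the likelihood"), and the equality with the direct
$\Gamma' F$ evaluation is itself a tested invariant.

A pattern is usable when its leading `m x m` block is generically
invertible.  `validate_pattern()` checks a structural transversal (a
nonzero generic permanent), which subsumes the row/column coverage
condition, and proposes a repairing row permutation when the supplied
outcome order is rank deficient.  Rank deficiency of a *numeric* proposal
inside the sampler (post-projection column norm below `1e-12` times the
largest column norm — a scale-free threshold) is treated as a
prior-support violation and the move is rejected.

One consequence of the default pattern worth knowing: because the first
two outcomes load only on factors 1-2 and span that coordinate plane, the
third and fourth Gram-Schmidt vectors reduce to coordinate axes, and three
entries of `L` below the diagonal (rows hcv/hiv in the pair columns) are
*identically zero* for every conforming loadings matrix.
`recovery_metrics()` detects and skips such entries: their posterior is
floating-point noise and a coverage verdict on them would be meaningless.

## The sampler

`dsfm_fit()` runs a single-threaded Metropolis-within-Gibbs sweep in a
fixed block order, with the heavy inner loops (full likelihood, factor
site sweep, heterogeneity sweep) in C++:

1. **loadings** — per-entry normal random walk in a fixed column-major
   scan; every proposal is LQ-decomposed and accepted with the
   Metropolis ratio of likelihood-through-`LQ` times the loadings prior;
   anchors proposed nonpositive are rejected outright;
2. **scale interweaving** — per factor column, propose
   $\Gamma_{\cdot m} \to c\,\Gamma_{\cdot m}$,
   $F_{\cdot\cdot m} \to F_{\cdot\cdot m}/c$,
   $\mu_{\cdot m} \to \mu_{\cdot m}/c$ with a random walk on $\log c$.
   The likelihood is essentially invariant along this direction, so the
   move travels the $\Gamma$-`F` scale ridge that single-site updates
   cross only diffusively; the acceptance ratio carries the factor prior,
   the loadings prior, the exact Jacobian and the (numerically tiny)
   likelihood difference.  Without it, desk-scale chains take an order of
   magnitude longer to find the prior-consistent scale;
3. **factor sites** — single-site random walks against the ICAR/AR
   conditional (both adjacent years) plus the statewide-mean term, times
   the Poisson/interval likelihood of the `K` outcomes at that cell;
4. **heterogeneity** $\varepsilon_{ijk}$ — per-cell random walk (exact
   Gibbs draw from $N(0, \sigma_k^2)$ in prior-only mode, where that is
   the full conditional);
5. **statewide means** — exact Gaussian Gibbs draws (above);
6. **AR coefficients** — random walk with reflection at 0 and 1;
7. **variances** — exact conjugate draws,
   $\sigma^2_k \sim \mathrm{InvGamma}(0.5 + IJ/2,\; 0.5 + \tfrac12\sum
   \varepsilon^2_{ijk})$.

Proposal scales adapt toward 44% acceptance in batches of 50 during
burn-in only (Robbins-Monro-style, frozen afterwards to preserve the
stationary target).  All randomness flows through R's RNG — including the
C++ kernels — so a seed fixes the entire chain bit for bit.

**Initialization.** By default the chain starts from a deterministic
confirmatory alternating-least-squares fit to the empirical log relative
risks $\log((y + 0.5)/E)$ (censored cells at the interval midpoint 3),
which also seeds $\sigma^2$ with the residual variances.  A neutral start
(anchors at 1, everything else at prior-neutral values) is available as
`dsfm_init_state(model, "neutral")` and is used automatically in
prior-only mode.  The neutral start is statistically valid but begins in
the saturated basin described above; at desk-scale chain lengths the
empirical start is the difference between converging in thousands of
iterations and not converging at all.  Production-scale chains
(the default config: 500,000 iterations, half burn-in, thin 50) are far
less sensitive to the choice.

**Default configuration.** `sampler_config()` defaults mirror a
production run; the test suite and examples use reduced settings
(hundreds to tens of thousands of iterations) chosen so the full suite
runs on one CPU in minutes.  The synthetic benchmark below states its
sizes explicitly.

## The synthetic benchmark and what it does (and does not) show

`simulate_panel(truth_config(), seed)` generates data with exactly the
model's structure at the scale of a statewide county surveillance panel:
a 10x10 rook lattice (100 units, matching a 100-county state), `J = 5`
years, `K = 6` outcomes, `m = 4` factors, populations log-uniform on
`[1e4, 1e6]` held constant over years, baseline rates
`(2.4e-4, 1.2e-3, 4e-4, 1.5e-4, 5e-4, 1e-4)` per outcome (deaths through
HIV, the order of magnitude of published statewide rates), truth loadings
at empirically plausible values (`default_truth_loadings()`), a mild
upward statewide trend on the shared factor
(`mu[j,1] = 0.1 (j-1)`, others 0), `eta = 0.5` and `sigma2 = 0.1`.
Counts of the "treatment" outcome landing in `[1, 5]` are censored, as
suppression policy does to the real data.

Recovery is scored on the identified quantities only — entries of `L`,
$\tilde F$ on a fixed cell subsample, plus `mu`, `eta`, `sigma2` — via
posterior-mean bias, RMSE and strict 95%-interval coverage
(`recovery_metrics()`).  Under the reduced benchmark chain
(20,000 iterations, 10,000 burn-in, thin 10, about five minutes on one
core) the informative `L` entries achieve interval coverage above 80%,
all anchor signs are recovered, and the `sigma2` mean absolute relative
bias stays well under 50%.

Passing this benchmark shows that the sampler targets the right posterior
and that the LQ identification resolves the rotation at realistic signal
strengths.  It does **not** show that real surveillance data satisfy the
model: the generator has no reporting artefacts, no population drift, no
mis-specified adjacency, constant loadings in space and time, and a
separable space-time covariance.  Conclusions about real data still
require the usual goodness-of-fit checks (the package reports
`variance_explained()` and exposes `split_rhat()`/`ess()` as diagnostics,
not gates).

Two benchmark-scale caveats are worth stating.  The baseline rates are
*estimated* from the baseline year of the simulated panel (as a real
analysis must), so the fitted offsets differ from the generative ones by
per-outcome factors; the posterior absorbs most of that through
$\Gamma'\mu$, which is why `mu` itself is recovered less sharply than `L`.
And the statewide-mean completion gives `mu` a posterior spread of order
$1/\sqrt{I}$ at best, so `mu` coverage is reported but not gated.

## Numerical choices

* Censored-interval probability: evaluated in log space from the exact
  nested-product partial sum; verified against the brute-force pmf sum to
  `1e-12` across means in `[1e-3, 50]`.
* Gram-Schmidt: modified (sequential re-projection) rather than
  classical, for stability at no cost; rank tolerance `1e-12` relative to
  the largest column norm.
* Quantiles: equal-tailed 95% intervals from `quantile()` type 7;
  structural zeros are reported as exact `0`, as a loadings table should
  print them.
* Degenerate inputs: empty panels, disconnected graphs, isolated units,
  self-edges, rank-deficient outcome orders, zero baseline totals and
  incomplete panels are all rejected with named errors before any
  sampling starts.
* Graphs must be connected; per-component centering for disconnected
  graphs is rejected rather than silently handled.

## Known limitations

* Proper CAR (with a spatial autocorrelation parameter), non-separable
  space-time covariances and spatially varying loadings are out of scope.
* The heterogeneity terms make the model deliberately overparameterized;
  with very short chains or very weak factor signal the saturated mode
  (everything explained by $\varepsilon$) can trap a badly initialized
  chain.  The empirical start and the scale move mitigate this; trace
  plots of $\sigma^2$ are the practical diagnostic.
* Interval censoring is specific to the `[1, 5]` suppression rule;
  arbitrary per-cell intervals would be a small extension of
  `pois_interval_loglik()` but are not exposed.
* Single-chain inference: `split_rhat()` operates on one chain's halves;
  nothing stops the user from running multiple seeds and pooling, but the
  package does not orchestrate it.
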