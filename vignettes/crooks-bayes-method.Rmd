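---
title: "Estimating protein redox potentials from nonequilibrium work values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating protein redox potentials from nonequilibrium work values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxcb)
```

## The problem

The midpoint (redox) potential of a heme protein sets the thermodynamics of
its electron transfer chemistry, and protein engineers routinely want to
predict how a point mutation shifts it. The reduction free energy and the
potential are linked by

$$\Delta G = -nFE,$$

with $F = 96485.3$ C mol$^{-1}$ and, for a heme, $n = 1$. redoxcb estimates
$\Delta G$ (and hence $E$, in mV) from paired potential energies of the
oxidized and reduced states evaluated on equilibrium snapshots of molecular
dynamics simulations.

## Work values from instantaneous redox switches

Each snapshot drawn from the oxidized ensemble yields a forward (reduction)
work value $W = \epsilon_{red} - \epsilon_{ox}$; each snapshot from the
reduced ensemble yields a backward (oxidation) work value
$W = \epsilon_{ox} - \epsilon_{red}$. Because the electron appears or
disappears instantaneously, no heat flows and the energy difference *is* the
work (the Kubo–Onsager picture of an instantaneous perturbation). Forward
work always comes from oxidized-ensemble frames and backward work from
reduced-ensemble frames — the package never cross-assigns them. The energies
are protein-only force-field contributions as delivered by the upstream
simulations: they omit electronic (quantum) effects such as polarization and
ionization energy, which is why absolute potentials computed this way are
uncalibrated and only *shifts* between a variant and a reference protein are
reported as predictions.

## The Crooks–Bayes estimator

The Crooks fluctuation relation ties the forward and backward work
distributions to the equilibrium free-energy difference:

$$\frac{p(W \mid \Lambda)}{\tilde p(-W \mid \tilde\Lambda)} =
  e^{\beta (W - \Delta G)}, \qquad \beta = \frac{1}{k_B T}.$$

Rather than locating the histogram crossing (which needs large samples to be
stable), the package builds a Bayesian posterior over free-energy hypotheses
$\Delta g$ with a flat prior and the two-sided logistic likelihood of
Maragakis and co-workers:

$$p(\Delta g \mid \mathbf W) \propto
  \prod_{i \in \mathrm{fwd}} f\!\big(\beta (W_i - \Delta g) + M\big)
  \prod_{j \in \mathrm{bwd}} f\!\big(\beta (W_j + \Delta g) - M\big),$$

where $f(x) = 1/(1+e^{-x})$ and $M = \ln(n_F/n_R)$ handles unequal sample
counts ($M = 0$ in the usual equal-count design). The posterior mean is the
square-error-optimal point estimate and the posterior SD is the reported
error. The posterior SD is deliberately conservative: Monte Carlo
experiments in the test suite show the sampling SD of the estimate is
smaller, so $\pm 3$ SD intervals over-cover. Both choices — the likelihood
form and reporting the posterior SD as the error — are the natural reading
of "minimal prior information" and of a mean-square-error criterion; a
jackknife error was considered and rejected as it would not reflect
small-sample information the posterior already carries.

### Numerical choices

* **Grid.** The posterior is evaluated on a uniform grid centred on the BAR
  estimate, spanning $\pm\max(10\,k_BT,\ 5\,\mathrm{sd})$ of the pooled work
  values (backward values negated), 4001 points by default (minimum 101).
  If more than $10^{-4}$ of the mass lands in the outermost grid cells the
  span doubles and the density is recomputed (up to six doublings, then an
  error). This guarantees normalization without the user choosing a window.
* **Log domain.** All likelihood products are accumulated as sums of
  $\log f(\cdot)$ with max-subtraction before exponentiation; work values of
  hundreds of kJ/mol would otherwise overflow. The grid sweep is implemented
  in C++ with saturating branches ($\log f(x) \approx 0$ for $x > 37$,
  $\approx x$ for $x < -37$), which makes the 200-replication validation
  runs cheap.
* **Quadrature.** Normalization and both posterior moments use the trapezoid
  rule on the uniform grid.

## Comparison estimators

* **BAR** solves the likelihood stationarity condition
  $\sum_i f\big({-\beta(W_i - \Delta g) - M}\big) =
   \sum_j f\big({-\beta(W_j + \Delta g) + M}\big)$
  — exactly the equation the posterior mode satisfies, so the two agree
  within grid resolution. For equal counts ($M = 0$) this is equivalent, via
  $f(-x) = 1 - f(x)$, to the familiar balance
  $\sum_i f(\beta(W_i - \Delta g)) = \sum_j f(\beta(W_j + \Delta g))$; for
  unequal counts the naive balance is biased by roughly $2M/\beta$ and the
  stationarity form must be used. The root is bracketed by the two
  one-sided Jarzynski estimates (expanded until the strictly increasing
  residual changes sign, at most $50\,k_BT$ beyond the data range) and
  solved to better than $10^{-10}$ kJ/mol. Its standard error is the BAR
  asymptotic (maximum-likelihood) variance; the test suite verifies it
  matches the empirical sampling SD.
* **Histogram crossing** bins forward and negated-backward work on shared
  uniform bins (Freedman–Diaconis width) anchored at the pooled mean — the
  anchoring makes the estimator exactly antisymmetric under direction swap —
  and interpolates the density-difference sign change linearly. Real data
  can show several crossings; the one inside the sample-overlap region
  closest to the BAR estimate is returned. No standard error is defined, and
  disjoint or identical samples raise informative errors.
* **Jarzynski / FEP** is the one-sided estimator
  $-\beta^{-1}\ln\langle e^{-\beta W}\rangle$, computed via log-sum-exp; for
  instantaneous switches it coincides with Zwanzig's free-energy
  perturbation. Applied to backward samples it estimates $-\Delta G$ of the
  forward process.
* **Linear response** assumes Gaussian work:
  $\Delta G = \langle W\rangle - \beta\sigma^2/2$ with the unbiased sample
  variance.

Convergence is monitored by re-estimating on *prefix* subsets (the first
$\mu$ values in each direction), not random subsamples: this matches the
"estimate as iterations accumulate" reading of a convergence curve and is
reproducible without extra seeds.

## The synthetic generator

`generate_crooks_gaussian()` draws forward work from
$N(\Delta G + \beta\sigma^2/2,\ \sigma^2)$ and backward work from
$N(-\Delta G + \beta\sigma^2/2,\ \sigma^2)$. This pair satisfies the Crooks
relation *exactly* with ground truth $\Delta G$, and collapses to the
quasistatic limit $W \equiv \Delta G$ at $\sigma = 0$. A Gaussian-mixture
stress generator (`generate_crooks_mixture()`) provides non-Gaussian work
distributions that are still exactly Crooks-consistent: given forward
components, the relation fixes both the ground truth in closed form and the
backward mixture (mean-shifted, reweighted components).

The generator emulates the *statistical* structure of production work data
— two overlapping work distributions tied by the fluctuation relation — at
the study's operating points: $\sigma \in \{1, 5, 20\}$ kJ/mol spans
comfortable to near-disjoint overlap at $T = 298$ K, 2000 values per
direction matches the per-system sample sizes a multi-replicate MD campaign
delivers (the convergence checks extend to 4000), and the energy-table
wrapper splits frames over 10 replicates of a few hundred frames each. What
it does **not** emulate: conformational autocorrelation between successive
frames, slow conformational substates that can trap one redox state (the
practical failure mode for hard mutants), force-field and solvent detail,
or protonation coupling. Passing the recovery tests therefore demonstrates
estimator correctness given representative sampling, not that any given MD
campaign has sampled enough.

All synthetic randomness flows from one integer seed through an isolated RNG
scope; the global RNG state is untouched.

## Nernst fitting of titration data

Experimental midpoints come from fitting the one-electron Nernst equation to
normalized absorbance-vs-potential curves:

$$\mathrm{response} = b + a\,\frac{1}{1 + e^{\,nF (E_{app} - E)/RT}},
 \qquad n = 1.$$

The reduced fraction decreases with applied potential (reduction is favoured
at low potential); at 298 K one decade of $[ox]/[red]$ spans
$RT\ln 10/F = 59.13$ mV. Baseline $b$ and amplitude $a$ are floated because
experimental normalization is imperfect (defaults 0 and 1 as starting
guesses); whether to float them at all was an open choice, recorded here as
this package's default rather than a claim about any particular experiment.
$n$ is fixed at 1 unless `fix_n = FALSE`. The midpoint is initialized at the
potential whose response is closest to mid-range, and the fit uses
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`, `ftol = ptol =
1e-10`) called directly on the residual function rather than through the
`nls`-style formula wrapper: on noiseless data the baseline converges to
$\sim 10^{-11}$, where the wrapper's numeric-derivative step degenerates
and raises a spurious "singular gradient" error, while the direct solver
recovers noiseless midpoints to $\sim 10^{-8}$ mV at any true midpoint.
Curves whose response range is below 0.3 are rejected as
ill-conditioned (one plateau only), since the midpoint is then unidentified.
Mediator equilibration, reference-electrode calibration and replicate
averaging are upstream data preparation; the fitter consumes normalized mean
curves.

## Shift tables and benchmarking

`compute_shift()` subtracts the reference protein's potential estimate and
propagates errors in quadrature. `benchmark_report()` correlates each
prediction method against experiment twice — over all variants and over
single mutants only (one-substitution labels such as `T19D`; a double mutant
like `DM` is excluded from the single-mutant set) — always excluding the
reference's definitional (0, 0) row, which would otherwise inflate the
correlation. On the bundled maquette table this reproduces the published
correlations (0.97/0.85 for the work-based predictions, 0.61/0.84 for the
continuum-electrostatics baseline). Because the sign convention of a "mean
offset between prediction and experiment" is ambiguous, the report prints
the mean signed offset under both conventions.

## Validation problem sizes

The shipped validation suite uses 200 replications per operating point for
the 3-SE recovery checks, $10^5$ work values per direction for the
empirical Crooks-relation regression, 20 replications over
$\mu \in \{250, \dots, 4000\}$ for the $\mu^{-1/2}$ posterior-SD scaling
check, and 100 noisy titrations for midpoint coverage — sizes chosen so the
binomial/regression noise of each check sits well inside its acceptance
margin.

## Known limitations

* Absolute potentials are uncalibrated (no quantum/polarization corrections)
  and flagged as such; only shifts are comparable to experiment.
* All work values are used as given: no reweighting, trimming, or
  decorrelation of frames is attempted.
* One-sided data limit the toolbox to Jarzynski/FEP and linear response;
  the two-sided estimators refuse such input explicitly.
* Path-ensemble (finite-time) work protocols and multi-state estimators
  (MBAR) are out of scope.
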