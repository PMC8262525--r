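---
title: "Identifiability of layer-wise hopping rates from first-exit times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifiability of layer-wise hopping rates from first-exit times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layerwalk)
```

## The model

`layerwalk` studies a discrete-space, discrete-time unbiased random walk on
the lattice $0, 1, \dots, L$, partitioned into $m$ layers by interfaces
$0 = \hat x_0 < \hat x_1 < \dots < \hat x_m = L$. Inside layer $i$ a walker
hops one site left or right each with probability $h_i \le 0.5$ and stays
put with probability $1 - 2h_i$; at an interior interface $\hat x_i$ the
left hop uses $h_i$, the right hop $h_{i+1}$. Position $0$ absorbs; right
hops from $L$ are aborted (reflecting). The observable is the *first-exit
time* $T$: the number of steps until a walker released at $S$ is absorbed
at $0$. The motivating application is diffusive transport (heat, solutes)
through layered biological tissue, where a probe can only record when a
disturbance released at one boundary arrives at the other — so the data
are exit times and nothing else.

The scientific question is one of **practical identifiability**: given a
finite sample $\mathbf t = (t_1, \dots, t_R)$ of exit times from known
release positions, how well are the layer rates
$\theta = (h_1, \dots, h_m)$ constrained?

## Exact likelihood

Conditional on release at $S$, the walk is an absorbing Markov chain with
a tridiagonal transition matrix. The exit-time CDF is the mass accumulated
at the absorbing state, $F(t\mid\theta)$, and the pmf is
$f_e(t\mid\theta) = F(t) - F(t-1)$, with $f_e(0) = 0$. The log-likelihood
is $\ell_e(\theta \mid \mathbf t) = \sum_r \ln f_e(t_r \mid \theta)$,
summed over all released particles regardless of release site.

Numerically, the transient block $Q$ of the transition matrix is
*symmetric* tridiagonal under the unbiased interface rule (the left rate
out of $\hat x_i + 1$ equals the right rate out of $\hat x_i$), so we
evaluate the pmf spectrally: with $Q = U \Lambda U^\top$, the survival
probability is $P(T > t) = \sum_j c_j \lambda_j^t$ with
$c_j = (\sum_k U_{kj}) U_{Sj}$, giving every $f_e(t_r)$ in $O(n)$ after
one $O(n^3)$ eigendecomposition per $\theta$. An iterated banded
propagation of the occupancy vector (also exported, in compiled code) is
retained as an independent route; the test suite requires the two to
agree to $10^{-10}$. We chose the spectral path as the primary route
because profiling evaluates the likelihood thousands of times, and the
decomposition cost is independent of how deep in the tail the data lie.
Zero mass (including underflow for observations deep in the tail) yields
$-\infty$ with a flag rather than an error, so optimizers can back away.

## Continuum moments and the Gamma approximate likelihood

In the continuum limit the layer diffusivity is
$D_i = h_i \Delta^2/\tau$ ($= h_i$ on the unit lattice). The $n$-th raw
moment $M_n(x)$ of the exit time for release at continuous $x$ solves,
layer by layer,
$$ D_i \, M_n^{(i)\prime\prime}(x) = -\,n\,M_{n-1}^{(i)}(x), \qquad
   M_0 \equiv 1, $$
with $M_n(0) = 0$, $M_n'(L) = 0$, and continuity of $M_n$ and the flux
$D M_n'$ at interfaces. Note the factor $n$: it is required for the
hierarchy to produce the correct second moment — dropping it makes the
"variance" $M_2 - M_1^2$ negative, while with it the pipeline reproduces
both the fundamental-matrix chain moments and the published reference
values below. Within layer $i$, $M_n$ is a polynomial of degree $2n$; we
propagate coefficients in layer-local coordinates and fix the $2m$ free
constants per order with one dense $2m \times 2m$ solve — an exact
numeric-symbolic hybrid that needs no computer algebra. A closed form for
$M_1$ (piecewise quadratic with layer cross terms) is implemented
independently and checked against quadrature of
$T(x) = \int_0^x (L - s)/D(s)\,\mathrm d s$ on random geometries.

The approximate likelihood assumes $T \sim$ Gamma with shape
$a = T^2/V$ and scale $b = V/T$, matching the continuum mean
$T(x) = M_1$ and variance $V(x) = M_2 - M_1^2$ at each release point —
an indirect-inference auxiliary model with an explicitly computable
parameter mapping $\theta \mapsto (a, b)$. For the reference three-layer
configuration (interfaces $0, 30, 60, 100$, rates $0.2, 0.3, 0.4$,
release at $100$):

```{r gamma}
geom <- layered_geometry(c(0, 30, 60, 100), c(0.2, 0.3, 0.4))
gamma_parameters(geom, 100)
```

Two conventions for the second Gamma parameter circulate (rate vs scale);
the published value $1.45 \times 10^4$ for this configuration multiplies
out as shape $\times$ scale $\approx T(100) = 20250$, i.e. it is the
*scale*. The package stores shape and scale and documents the ambiguity.
By default the Gamma log-"pmf" is the continuous density evaluated at the
integer exit time; an interval mode (mass of $[t-1, t]$) is provided for
sensitivity checks — at the time scales of interest the two differ
negligibly, and density evaluation is the standard indirect-inference
reading.

With the spectral exact likelihood, the approximate likelihood is a few
times cheaper per evaluation; the dramatic ($\gg 100\times$) savings the
approximation is designed for apply against the full-distribution
Markov-chain construction, which remains the cost model whenever the
whole pmf (not just observed times) is needed.

## Profiling, intervals, coverage

`exit_fit()` maximizes either log-likelihood over the box
$[0.05, 0.5]^m$ with multistart `L-BFGS-B` from a small deterministic
start set. `profile()` sweeps a uniform 40-point grid per parameter
(matching common practice for this problem class), optimizing the
nuisance rates out at each grid value and warm-starting each point from
its already-profiled neighbour, outward from the MLE in both directions —
bidirectional sweeping reduces stuck-optimizer artifacts relative to a
single pass. `profile_pair()` does the same on a $20 \times 20$ grid for
a parameter pair. Confidence sets use the chi-squared calibration of the
normalized profile: thresholds $-1.92$ (1 df) and $-3.00$ (2 df) at 95%,
computed at run time from `qchisq` and rounded only for display. Crossing
points are linearly interpolated; when the profile is still above the
threshold at a box edge the interval endpoint is the bound and is flagged
*censored* — the signature of one-sided identifiability. Multi-modal
profiles report every interval. If a profile point beats the global
optimum (possible with any local optimizer), the profile is renormalized
to the better value and flagged.

Optimizer tolerances: function $\sim 10^{-8}$ at the fitting stage
(`factr` scaled accordingly), looser ($10^{-7} \cdot$ machine epsilon
scale) inside profile sweeps where warm starts make convergence cheap.
These are our defaults, chosen for robustness at desk scale, not values
inherited from elsewhere.

`coverage_study()` wraps the full loop — simulate, fit, profile,
interval — and reports per-component coverage of the true rates along
with bound-censoring rates. Coverage counts the truth as covered if it
lies in *any* reported interval (coverage of the confidence set).

## The simulator and what the synthetic data do (and do not) show

`simulate_exit_times()` is the package's data generator: a direct
step-by-step implementation of the walk rules in compiled code, seeded
through R's RNG (`set.seed(seed)` fixes the dataset byte-for-byte).
Records are drawn sequentially from one stream; we did not implement
per-record substreams because nothing in the package simulates in
parallel. A hard step cap (default $10^9$) turns a pathological
non-terminating configuration into an error rather than a hang.

The generator's default study conditions follow the published designs:
two-layer problems with interfaces $(0, 30, 70)$ and rates $(0.2, 0.4)$
under designs of $R = 100$ at $S = 70$, $R = 50$ each at $S = 30, 70$,
and $R = 500$ each at two sites; and the three-layer configuration above
with $R = 50$ at each of $S = 30, 60, 100$. Synthetic data are exactly
the model: tests built on them validate the inferential machinery, not
the adequacy of an unbiased, non-decaying walk for any particular tissue.
Real measurements would add observation noise, biased motion, particle
loss, and uncertainty in the interface positions, none of which the
generator emulates.

## Numerical choices and known limitations

* **Lattice corrections.** The continuum moments differ from the exact
  chain moments by $O(1/L)$ (e.g. the discrete homogeneous mean from
  $S = L$ is $L(L+1)/2h$ vs the continuum $L^2/2h$). At $L = 100$ the
  mean and variance agree within $0.9\%$ and $1.8\%$; at $L = 70$ the
  variance discrepancy reaches $2.4\%$. The Gamma approximation inherits
  this bias, which contributes to its degraded interval coverage.
* **Histogram-scale distribution comparisons.** Per-integer total
  variation between an empirical pmf from $10^4$ draws and a smooth pmf
  supported on $\sim 10^5$ integers is dominated by sampling sparsity
  (most integers receive 0 or 1 draws). `compare_distributions()` offers
  equal-mass binning of the reference CDF; simulator validation uses 25
  bins, where the expected total variation under perfect agreement is
  $\approx 0.02$ at $n = 10^4$.
* **Distribution truncation.** Automatic `t_max` grows geometrically
  until $F(t_{\max}) \ge 1 - 10^{-8}$ (then bisects); a user-supplied
  `t_max` that covers less mass flags the result and warns. Likelihood
  evaluation never needs the full distribution, only observed times.
* **Degenerate inputs.** $x = 0$ has no variance (absorbing boundary);
  single-record summaries flag an undefined variance; rates are required
  strictly positive since $h_i = 0$ makes a layer impassable and the
  exit time improper.
* **Model reduction.** `reduce_geometry()` + `fit_reduced()` implement
  partial homogenization: keep a subset of interfaces, refit the smaller
  model to the same data. Release sites interior to a merged layer are
  allowed. Which interfaces to merge is left to the analyst — no
  automatic model selection is attempted.
* **Scale of the shipped experiments.** Test-suite replicate counts (20
  recovery replicates, 5 profile replicates, 100 coverage replicates)
  are desk-scale choices that keep the full suite in minutes while
  leaving Monte-Carlo margins comfortably wide of the asserted bounds.

## Scope

One dimension only; unbiased walks without decay; Gamma (two-moment)
auxiliary likelihood. Biased/decaying walks, higher-dimensional media,
three-moment generalized-Gamma or phase-type auxiliaries, and Bayesian
analyses are natural extensions but out of scope.
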