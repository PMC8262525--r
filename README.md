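# layerwalk

Likelihood inference for diffusion through layered media from
first-exit-time data.

## The problem

In many transport experiments on layered materials — heat conduction
through skin (epidermis / dermis / fat), solute diffusion through
laminated membranes or liner systems — the only practical observable is
*when* a disturbance released at one boundary arrives at the other. The
medium is modelled as an unbiased random walk on the lattice
`0, 1, ..., L` partitioned into `m` layers with per-layer hopping
probabilities `θ = (h₁, ..., h_m)`, `0 < hᵢ ≤ 0.5` (continuum
diffusivity `Dᵢ = hᵢΔ²/τ`). Position 0 absorbs, `L` reflects; at the
interface between layers `i` and `i+1` the left hop uses `hᵢ` and the
right hop `hᵢ₊₁`. The data are first-exit times
`t = (t₁, ..., t_R)` of particles released at known positions `S`.

`layerwalk` asks and answers the *practical identifiability* question:
do such data pin down the layer rates, and with what uncertainty? It is
aimed at modellers designing release/measurement protocols for layered
transport experiments.

## What is in the package

* **Exact likelihood** — the walk is an absorbing Markov chain with
  tridiagonal transition matrix `P`; the exit-time CDF is the absorbed
  mass `F(t|θ)`, the pmf `f_e(t|θ) = F(t) − F(t−1)`, and
  `ℓ_e(θ|t) = Σ_r ln f_e(t_r|θ)`. Evaluated spectrally (the transient
  block is symmetric tridiagonal), cross-checked against banded
  propagation.
* **Gamma approximate likelihood** — continuum exit-time moments from
  the layered boundary-value problems `Dᵢ Mₙ″ = −n Mₙ₋₁`
  (with `Mₙ(0)=0`, `Mₙ′(L)=0`, continuity of `Mₙ` and flux `D Mₙ′`)
  give `T(x) = M₁` and `V(x) = M₂ − M₁²`; exit times are approximated
  as Gamma with shape `a = T²/V` and scale `b = V/T` — a cheap
  indirect-inference auxiliary likelihood.
* **Profile likelihood machinery** — `exit_fit()` (multistart, box
  constraints `[0.05, 0.5]`), `profile()` / `profile_pair()` with
  warm-started nuisance optimization, chi-squared thresholds −1.92 /
  −3.00, interpolated confidence intervals with bound-censoring flags,
  and `coverage_study()` for simulated interval coverage.
* **Model reduction** — `reduce_geometry()` / `fit_reduced()` merge
  adjacent layers (partial homogenization) and refit effective rates;
  `compare_distributions()` quantifies full-vs-reduced agreement in
  total variation.
* **Simulator** — `simulate_exit_times()`: seeded, compiled,
  step-by-step walk realizations; the package's synthetic-data
  generator.

## Worked example

Two layers with interfaces `(0, 30, 70)` and true rates
`θ = (0.2, 0.4)`; 500 particles released at each of `S = 30` and
`S = 70`; exact-likelihood fit and profile intervals:

```r
library(layerwalk)

geom <- layered_geometry(c(0, 30, 70), c(0.2, 0.4))
dat  <- simulate_exit_times(geom,
                            data.frame(release = c(30, 70),
                                       count   = c(500, 500)), seed = 1)
fit  <- exit_fit(dat, layered_geometry(c(0, 30, 70)),
                 likelihood = "exact")
fit
#> Exit-time fit (exact likelihood), 1000 observations
#>     h1     h2
#> 0.1963 0.4119
#> log-likelihood: -10060.2760

confint(profile(fit))
#>   parameter  estimate     lower     upper lower_censored upper_censored
#> 1        h1 0.1963251 0.1849482 0.2096283          FALSE          FALSE
#> 2        h2 0.4119365 0.3229352 0.5000000          FALSE           TRUE
```

The first-layer rate is tightly identified (interval `[0.185, 0.210]`
around the truth 0.2). The second-layer interval runs into the upper
bound 0.5 (`upper_censored`): with exit-time data alone, `h₂` is only
*one-sided* identifiable under this design — the central phenomenon the
package is built to diagnose.

The moment-matched Gamma parameters for the three-layer reference
configuration:

```r
gamma_parameters(layered_geometry(c(0, 30, 60, 100),
                                  c(0.2, 0.3, 0.4)), 100)
#> Moment-matched Gamma: shape a = 1.4, scale = 1.447e+04 (release 100)
#>   matches mean T = 20250, variance V = 2.92958e+08
```

A thin command-line wrapper over the same functions lives in
`inst/cli/layerwalk.R` (subcommands `simulate`, `moments`, `pmf`, `fit`,
`profile`, `reduce`, `run`), driven by YAML configurations; see
`?run_case_study` for the configuration format.

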