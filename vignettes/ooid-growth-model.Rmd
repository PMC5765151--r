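---
title: "Nutrient-limited biofilm growth, limiting size and laminations of ooids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient-limited biofilm growth, limiting size and laminations of ooids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ooidgrowth)
```

## The model and its assumptions

`ooidgrowth` treats an ooid as the product of a mineralising biofilm
growing in a nutrient-limited environment. The assumptions are the same
ones that make avascular tumour spheroids size-limited: nutrients arrive
only by diffusion from the surrounding medium and are consumed at a
constant volumetric rate, so beyond a threshold size they are exhausted in
an outer rim before reaching the interior. The biofilm then has two
regions — an actively growing outer layer of near-constant width `w`, and
a starved inner zone where microbes decay and organomineralisation
replaces them with mineral. Growth is taken to be radially symmetric, and
the compartments are well-mixed volumes; there is no spatially resolved
biofilm simulation here, and the biochemistry of the mineralisation itself
is deliberately a black box represented by a single rate constant.

Three volumes evolve:

* `V_m` — mineral, growing at `k_m V_b_I`: deposition is proportional to
  the microbial volume being overwhelmed in the inner zone;
* `V_b_I` — inner-zone biotic volume, decaying at `k_b_I` (no nutrients)
  and fed at `k_b` by microbes transitioning in from the outer layer;
* `V_b_II` — outer-layer biotic volume, growing at the per-capita rate
  `k_b_II` net of the transition loss `k_b`.

One notational caution: `k_b_II` multiplies a *growth* term in the outer
layer. Descriptions of this class of model sometimes gloss it as a decay
rate; the equations, which this package follows, use it as the per-capita
growth rate of nutrient-supplied microbes.

Biofilm volume is proportional to microbial volume through the
dimensionless factor `c`, so the whole ooid occupies
`V = V_m + c V_b_I + c V_b_II` and

```
dV/dt = -(c k_b_I - k_m) V_b_I + c k_b_II V_b_II .
```

When `c k_b_I > k_m` (the *size-limited regime*,
`is_size_limited()`) the inner zone is a net volume sink and a stationary
size exists.

## Parameters

| name    | meaning                                         | units       | default |
|---------|-------------------------------------------------|-------------|---------|
| `k_m`   | mineralisation rate, inner zone                 | 1/time      | 0.5     |
| `k_b`   | outer→inner microbe transition rate             | 1/time      | 0       |
| `k_b_I` | inner-zone biotic decay rate                    | 1/time      | 1       |
| `k_b_II`| outer-layer biotic growth rate                  | 1/time      | 0.2     |
| `c`     | biofilm volume per microbial volume             | –           | 1       |
| `c_I`   | survival-threshold nutrient concentration       | conc.       | 0       |
| `c_II`  | background nutrient concentration               | conc.       | 1       |
| `D`     | nutrient diffusivity                            | length²/time| 1       |
| `k`     | nutrient consumption rate                       | conc./time  | 1       |

The kinetic defaults were chosen once to sit squarely inside the
size-limited, finite-upper-bound regime (`c k_b_I - k_m = 0.5`,
`c k_b_II = 0.2`) with rates of order one in the natural time unit
`1/k_b_I`; nothing in the analysis depends on their particular values, and
every function takes explicit parameter objects.

## The limiting size

The stationarity condition, with the rim volume `4πR²w` and inner volume
`(4/3)πR³`, is the cubic `-A R³ + B R² + C = 0` with

```
A = (4π/3) |k_b_I - k_m/c| ,   B = 4π k_b_II w ,   C = |k_b_I - k_m/c| V_m .
```

With one sign change in the coefficient sequence, Descartes' rule gives
exactly one positive root — a property the test suite verifies on a
thousand seeded random parameter draws using an independent polynomial
root counter. `limiting_radius()` locates the root by bracketed bisection
(`uniroot`) with Newton polishing rather than by the closed-form cubic
radicals, which cancel catastrophically for extreme parameter ratios; at
`V_m = 0` the cubic degenerates and `B/A` is returned exactly.

Two analytic bounds follow. Setting `V_m = 0` gives the lower bound
`3 c k_b_II w / (c k_b_I - k_m)`; since `V_m = 0` attains it, the package
treats it as an attained infimum rather than a strict bound. Substituting
the largest mineral volume compatible with an intact rim,
`V_m = (4/3)πR³ - 4πR²w + 4πRw²`, gives the upper bound

```
R_max = w (c k_b_I - k_m) / (c k_b_I - k_m - c k_b_II) ,
```

finite only when the denominator is positive; otherwise
`radius_bounds()` reports an explicit `unbounded_upper` flag (never an
infinity literal in serialised output). The numerator used here is the one
this substitution actually produces, `c k_b_I - k_m`; statements of the
bound with `c k_b` in the numerator circulate, but the derivation is
reproducible and the package follows it. Both bounds are exactly linear in
`w`, so with `w = sqrt(2 (c_II - c_I) D / k)` the limiting size inherits
the exponents `+1/2` in `D` and `-1/2` in `k` —
`sensitivity_exponents()` measures them empirically as log–log
least-squares slopes over two-decade sweeps and recovers ±0.5 to 1e-6.

### The rim width beyond the thin-shell limit

`outer_width()` is the thin-shell formula. `shell_width_exact()` drops the
thin-shell approximation: for steady diffusion with constant consumption
in a spherical shell, concentration `c_II` at the outer radius and `c_I`
with zero flux at the inner interface, radial symmetry reduces the
boundary-value problem to the exact algebraic relation

```
(k / 6D) (R² - 3 R_i² + 2 R_i³ / R) = c_II - c_I ,
```

whose left side decreases strictly in `R_i`, so the interface is a
bracketed root found to machine precision. We chose this exact reduction
over a discretised boundary-value solve — there is no discretisation error
to control — and kept a second-order finite-difference solver (with grid
refinement) as the *independent oracle* in the test suite. When even full
penetration cannot consume the nutrient supply (`k R²/6D ≤ c_II - c_I`)
there is no starved zone yet — the initial growth stage — and the function
reports `full_penetration = TRUE` instead of inventing an interface.

## The mineralisation front and laminations

With no replenishment (`k_b = 0`), integrating the inner-zone decay from
the onset time τ (when the biofilm has reached its pre-onset radius `R`)
gives

```
V_m(t) = (4π k_m R³ / 3 k_b_I c) (1 - exp(-k_b_I (t - τ)))
```

and the front radius is its cube root. The amplitude only scales the
pattern and `k_b_I` only scales time, so the canonical internal
representation sets both to one
(`k_m R³ / (k_b_I c) = 1`, `k_b_I = 1`, onset at dimensionless time 1) and
`mineral_front_radius()` works in these units; the dimensional wrapper
`mineral_front_radius_dimensional()` converts in and out. The same
dimensionless front follows from a second route — holding the total volume
fixed and letting mineral replace biotic volume at rate `k_m c` — and
`mineralisation_ode_alternative()` implements it; the two routes agree to
below 1e-8 in the tests, which is a strong regression guard on both.

With replenishment from an outer layer of constant volume `V₀`, the cubed
front gains a linear term `α (t - 1)` with

```
α = k_b V₀ / (k_b_I V_b_I(τ) - k_b V₀) .
```

This expression was fixed by derivation *and* by an ODE-integration
oracle: solving the inner-zone balance with constant feed in closed form
gives a single power of `k_b` in the numerator, and integrating the
compartment system numerically confirms proportionality of `V_m(t)` to
`1 + α(t-1) - e^{-(t-1)}` to solver precision with this α (and rules out
the variant with `k_b²`, which misses by tens of percent). At `α = 0` the
generalised law reduces *bit-for-bit* to the plain one: the code path is
`α s - expm1(-s)`, which for `α = 0` is exactly `-expm1(-s)`. Early-time
behaviour is `R_m ≈ ((1 + α) s)^{1/3}`, the one-third coarsening exponent
for every α; `expm1` keeps this regime accurate where `1 - exp(-s)` would
cancel.

Laminations are the front sampled at `t = 1 + jΔt`, `j = 1, 2, …` — ring
1 bounds the rendered nucleus disc, matching the large central region of
natural ooids. Radii increase strictly, spacings decrease strictly, and
for `α = 0` the supremum over rings is the magnification itself. These are
exact-arithmetic statements; in double precision `1 - e^{-s}` saturates to
exactly 1 beyond `s ≈ 37`, so tests assert strict monotonicity on grids
with `jΔt ≲ 30` and non-strict boundedness beyond. The SVG renderer writes
deterministic text output (fixed 6-decimal formatting, byte-identical for
identical input) so renders are testable by element count and hash;
annulus shading is a cosmetic flag, since nothing in the model prescribes
the dark/light couplets of real cortices.

## Fitting ring radii

`fit_rings()` minimises the sum of squared radial residuals between
observed radii and `scale · (1 + α(j + j0)Δt - e^{-(j + j0)Δt})^{1/3}`.
Design choices, made where the procedure was genuinely open:

* **Objective**: unweighted least squares on radii, not on spacings —
  the most direct reading of fitting "the laminations"; spacing-based
  fitting would upweight the noisy outer rings.
* **Search**: the model is linear in `scale`, so `scale` is profiled out
  in closed form at each candidate `(Δt, α, j0)`; `Δt` is searched on a
  61-point logarithmic grid over `[1e-3, 10]` and refined locally
  (`optimize` in the bracketing grid cell). The objective is smooth in
  `Δt`, so grid-plus-refinement finds the global optimum without a
  stochastic search, keeping fits deterministic.
* **α and j0**: fixed to 0 unless freed. Freeing α runs coordinate
  refinement (alternating line searches), and the α = 0 solution is always
  retained as a candidate, so the nested-model inequality
  `rmse(free α) ≤ rmse(α = 0)` holds by construction. `j0`, an integer
  offset for innermost rings unresolved in an image, is searched
  exhaustively over 0–5.
* **Identifiability**: on noiseless model output the recovered `(scale,
  Δt)` reproduce the truth to better than 1e-6 relative and no cell of a
  surrounding `(Δt, scale)` grid beats the returned objective (asserted in
  the tests).

## The synthetic ring generator

`synth_rings()` is the package's stand-in for digitised ring measurements
from micrographs of laboratory-grown ooids (such measurements are not
shipped; the generator is clearly synthetic and all test inputs come from
it). It emulates digitisation error as *multiplicative* zero-mean Gaussian
noise on each radius — measurement error in an image scales with
magnification — at a default study level of 1% (`noise_sd = 0.01`),
`n = 12` rings, `Δt = 0.4` and `scale = 500` (a lamination pattern tens to
hundreds of µm across, the size range of experimentally grown ooids).
Strict monotonicity is enforced by deterministic whole-vector rejection
resampling under the given seed; at 1% noise the outermost rings are
spaced at the same order as the noise, so the resample cap is generous
(20000). The generator does **not** emulate systematic digitisation bias,
environmentally driven Δt variation between rings, ring-boundary blur, or
diagenetic overprint — so passing recovery tests show the fitter works on
the model's own noise process, not that real, possibly recrystallised
cortices are this well behaved.

Under these conditions a 100-replicate recovery study (seeded, rerun from
scratch by `scripts/acceptance.R`) recovers Δt with ~3% median relative
error and the magnification with ~0.4%.

## Numerical choices

* ODE integration: `deSolve::lsoda` at `rtol = 1e-10`, `atol = 1e-12`.
  The system is linear and non-stiff; the tight tolerances exist so
  closed-form comparisons at 1e-8 are meaningful. The integrator never
  clips negative volumes — the linear system preserves non-negativity —
  but any volume below `-10·atol` aborts the run as solver misuse.
* Onset: `mineral_front_radius()` returns exactly 0 at dimensionless time
  1 (the closed-interval limit) and raises a domain error before it.
* Cubic root: residual polished below 1e-10 of the largest term; the
  bisection oracle in the tests agrees to 1e-10 on every sweep draw.
* Serialisation: all numeric CSV/JSON output carries ≥ 12 significant
  digits so round-trips do not destroy oracle comparisons.

## Problem sizes

The test suite and acceptance script use 1000-draw parameter sweeps,
500-point time grids, and 100-replicate recovery studies — sizes chosen so
the full suite runs in well under a minute while keeping Monte-Carlo
medians stable to the tolerances asserted.

## Known limitations

* Compartments are well-mixed; there is no moving-boundary PDE coupling
  between the rim-width problem and the growth ODEs (the rim width enters
  the limiting-size analysis as a steady-state constant).
* The replenished front law assumes a *constant* outer-layer volume; the
  fully coupled case with growing outer layer is integrated numerically
  but has no closed form here.
* Lamination roughness, cerebroid morphologies and diagenetic overprints
  (spindle/cone recrystallisation fabrics) are outside the model: rendered
  rings are smooth circles by construction.
* No uncertainty quantification on fitted parameters beyond the seeded
  recovery study; bootstrap intervals are a natural extension.
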