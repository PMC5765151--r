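# ooidgrowth

Ooids are (near-)spherical sediment grains built from a nucleus wrapped in
concentric mineral laminations. `ooidgrowth` models their genesis as
nutrient-limited biofilm growth with organomineralisation: a biofilm coats
a spherical surface, diffusing nutrients are consumed in an outer rim
before reaching the interior, microbes in the starved inner zone die and
are progressively replaced by mineral. The same mechanism that limits the
size of avascular tumours then limits the size of the ooid, and sampling
the advancing mineralisation front at constant time intervals reproduces
concentric laminations whose spacing shrinks outward.

The package is aimed at geomicrobiologists and carbonate sedimentologists
who want to simulate this growth model, explore its limiting-size
predictions, generate model lamination patterns, and fit the lamination
law to ring radii digitised from thin sections.

## The model

Three well-mixed volume compartments: mineral `V_m`, inner-zone biotic
volume `V_b^I`, outer-layer biotic volume `V_b^II`, with

    dV_m/dt    =  k_m  V_b^I
    dV_b^I/dt  = -k_b^I V_b^I + k_b V_b^II
    dV_b^II/dt = (k_b^II - k_b) V_b^II

and total ooid volume `V = V_m + c V_b^I + c V_b^II`. Growth stalls when
the rim gain balances the inner loss; with rim volume `4πR²w` and rim
width `w = sqrt(2 (c_II - c_I) D / k)` (Greenspan's active-layer width),
the limiting radius is the unique positive root of

    -A R³ + B R² + C = 0,
    A = (4π/3)|k_b^I - k_m/c|,  B = 4π k_b^II w,  C = |k_b^I - k_m/c| V_m,

which is bounded between `3 c k_b^II w / (c k_b^I - k_m)` and
`w (c k_b^I - k_m) / (c k_b^I - k_m - c k_b^II)`, both linear in `w` — so
the limiting size scales as `D^(1/2)` and `k^(-1/2)`.

With no replenishment of the inner zone (`k_b = 0`) the mineralisation
front has the closed form, in scaled units with onset at dimensionless
time 1,

    R_m(t) = (1 + α (t-1) - e^{-(t-1)})^{1/3},

with `α = k_b V₀ / (k_b^I V_b^I(τ) - k_b V₀)` when the outer layer holds a
constant volume `V₀` (α = 0 without replenishment). Near onset
`R_m ~ (t-1)^{1/3}` for every α — the classic coarsening exponent.
Lamination rings are this front sampled at `t = 1 + jΔt`; fitting observed
ring radii therefore needs only two parameters, the magnification and Δt.

## Worked example

```r
library(ooidgrowth)

## limiting size for a mid-range parameter set
p   <- model_params(k_m = 0.5, k_b = 0, k_b_I = 1, k_b_II = 0.2, c = 1)
nut <- nutrient_params(c_I = 0.1, c_II = 1.1, D = 1, k = 1)
limiting_radius(p, w = outer_width(nut), V_m = 1)
#> Limiting ooid size
#>   R     = 1.773000326
#>   lower = 1.697056275
#>   upper = 2.357022604
#>   rim width w = 1.41421; cubic A = 2.0944, B = 3.55431, C = 0.5
```

The limiting radius (1.773) sits strictly between the `V_m = 0` lower
bound (1.697) and the rim-shell upper bound (2.357); already-deposited
mineral pushes the limiting size up.

```r
## lamination pattern and a two-parameter fit to noisy synthetic rings
obs <- synth_rings(12, scale = 500, dt = 0.4, noise_sd = 0.01, seed = 42)
fit_rings(obs)
#> Lamination-law fit
#>   scale = 501.43022, dt = 0.39465639, alpha = 0, j0 = 0
#>   rmse = 2.25577 over 12 rings (converged: TRUE)
```

The recovered magnification (501.4 vs 500 µm) and sampling interval
(0.395 vs 0.4) come back within ~0.3% and ~1.3% despite 1% radial noise;
`rmse` is the root-mean-square radial misfit in the units of the input
(here µm).

From a shell, the same functionality is exposed by the bundled CLI:

```sh
ooid rings --n 12 --dt 0.35 --out pattern.svg --csv rings.csv
ooid fit --rings rings.csv --report fit.json
ooid limit --V_m 1 --c_II 1.1 --c_I 0.1
```

(`ooid` is the script installed at
`system.file("exec", "ooid", package = "ooidgrowth")`.)

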