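# dynexposure

Heat- and cold-mortality assessments usually pin every resident to their
home address. Real urban populations move: commuters converge on city
centres by day, and tourists and seasonal workers swing city totals month by
month. Because the urban heat island (UHI) and the density of destinations
both peak near the centre, these flows push people into the warmest parts of
the city, so a static census misstates who is actually exposed to
temperatures away from the local optimum.

`dynexposure` quantifies that effect for anyone working with gridded urban
climate and dynamic (day/night, monthly) population rasters —
epidemiologists, urban climatologists, and exposure modellers. It computes,
per city and across city ensembles:

* **Mobility metrics** — daily (`ΔP_daily`, July day − night) and seasonal
  (`ΔP_seasonal`, July − January nighttime) population changes, the
  four-quadrant mobility classification, and the cross-city scaling law
  `ΔP_daily ∼ P_night^β` (gravity theory predicts β = 1).
* **Seasonal models** — nonlinear least-squares fits of the 12-month cosine
  `P_t = A·cos(2π(t + b)/12) + c` (phase bounded to `b ∈ [−2, 0]` for
  population, free for temperature) and the linear population–temperature
  coupling in ‰/°C.
* **Radial profiles** — 0.5-km annular means of population and temperature
  deviation after rescaling distance and population by
  `k = (P_city/P_ref)^(1/3)`, with exponential
  `P = a·exp(λ·(T − T̄))` fits.
* **Exposure and risk** — population above/below each city's minimum
  mortality temperature (MMT, the optimum of its exposure–response function,
  ERF) under monthly-mean or extreme (hottest/coldest 3 % of days)
  temperature scenarios; mobility-induced exposure deltas; the
  incoming-population-weighted temperature `⟨T⟩ = ΣT_iP_i/ΣP_i` over cells
  gaining population; and the relative-risk change
  `100·(RR(⟨T⟩) − RR(T̄))/RR(T̄)`.
* **Synthetic cities** — a seeded generator (exponential density, radially
  decaying UHI on a sinusoidal seasonal climate, gravity-law commuter
  inflow, piecewise-linear U-shaped ERFs with known MMT) so the whole
  pipeline runs and is tested offline.

## Worked example

```r
library(dynexposure)

cfg   <- synthetic_city_config(seed = 7)   # default mid-sized city, 2010-2012
st    <- make_city_stack(cfg)
curve <- make_synthetic_erf(mmt = 18)
rep   <- run_city(st, curve)

rep$mobility
#>       city_id dP_daily dP_seasonal pct_daily pct_seasonal quadrant
#> 1 synthetic-7 123950.8   -44121.91  11.46645    -3.921569        I

rep$exposure[, c("side", "timescale", "exposure_static",
                 "exposure_dynamic", "delta", "delta_pct")]
#>   side timescale exposure_static exposure_dynamic     delta delta_pct
#> 1 heat     daily         1080987          1204938 123950.82 11.466452
#> 2 cold     daily         1125109          1254119 129010.03 11.466452
#> 3 heat  seasonal         1125109          1080987 -44121.91 -4.081633

rep$temperatures
#>      t_bar t_weighted t_elevation
#> 1 20.24896   20.83667   0.5877074

rep$risk
#>   T_weighted   T_mean rr_weighted  rr_mean delta_rr_pct clamped
#> 1   20.83667 20.24896    1.141834 1.112448     2.641505   FALSE
```

Reading this: the city gains 11.5 % of its July nighttime population every
day (quadrant I: daytime- and winter-peaked). That influx raises summer heat
exposure (population above the 18 °C MMT) by ~124 k people and, because the
commuters land 0.59 °C above the city-mean temperature, raises their
relative mortality risk by 2.6 %. Seasonally the city loses population in
July, so the summer swing *reduces* heat exposure by 4.1 %. The
`fraction_above_mean` in `rep$curve_summary` (82.9 %) says where the influx
goes: overwhelmingly to cells warmer than the city average.

## Analysis workflow

The `analysis/` scripts run the ensemble study end to end, writing tables
under `results/`:

```sh
Rscript analysis/01_simulate_ensemble.R    # configs + synthetic ERFs
Rscript analysis/02_mobility_and_scaling.R # deltas, quadrants, scaling fit
Rscript analysis/03_seasonal_fits.R        # cosine + coupling fits
Rscript analysis/04_radial_profiles.R      # rescaled profiles, exp fits
Rscript analysis/05_exposure_and_risk.R    # exposure deltas, <T>, deltaRR
```

The ensemble is 12 synthetic cities spanning baseline populations of
~1e5–1e7 in a quadrant mix dominated by daytime/winter-peaked cities. All
rasters are rebuilt deterministically from the stored configs, so `results/`
holds only small tables.

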