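# seapump

Seasonal particle-flux attenuation in the ocean's biological carbon pump.

The downward flux of sinking organic particles is classically described by
the Martin power law

    F(z) = F(z0) * (z / z0)^(-b)

whose exponent *b* ("Martin b") sets how quickly the export flux is
remineralised in the mesopelagic. In explicit-detritus biogeochemical
models *b* is imposed through the sinking-speed law *w(z) = a z* with
*a = λ/b*, where λ is the detritus remineralisation rate (0.05 day⁻¹
here). `seapump` asks: what happens when *b* — and with it the sinking
speed — varies **seasonally**,

    b(t, φ) = b_ref ∓ δb cos(2π t/T + θ π/6)      (∓: North/South)

with amplitude δb, phase θ (months) and a 360-day year? Because 1/b is
convex, the annual-mean sinking coefficient is biased fast,
mean(A) = λ/√(b_ref² − δb²): a symmetric seasonal cycle in *b* behaves on
annual average like a *smaller* constant exponent, moving carbon deeper.

The package is aimed at ocean biogeochemists who want a desk-scale,
fully testable version of that analysis. It provides:

* **attenuation** — all closed forms: Martin flux and transfer efficiency
  (TE = (1080/120)^(-b) between the 120 m export and 1080 m transfer
  horizons), a = λ/b, the seasonal parameterisation, its annual-mean
  identities, sinking speeds W(z,t) = A(t) z and transit times ln(z2/z1)/a.
* **ecosystem** — a five-tracer NPZD-DOP phosphorus ecosystem
  (PO₄, phytoplankton, zooplankton, detritus, dissolved organic P) with an
  explicit detritus tracer sinking at the depth-linear, seasonally varying
  speed. The sinking scheme reconstructs the within-layer power-law shape,
  so the no-circulation steady state reproduces the Martin profile to
  machine precision on the coarse 15-layer grid.
* **transport** — synthetic, mass-conserving monthly transport operators
  (seasonal mixed-layer homogenisation plus a meridional overturning loop)
  standing in for transport-matrix circulation, with a documented
  plain-text sparse format.
* **integrate / diagnostics / experiments** — spin-up to a quasi-repeating
  annual cycle, the metric suite (PP_global, F₁₂₀, F₁₀₈₀, TE maps,
  emergent-b fits, layer-wise fractional transfer, comparison tables), and
  the full experiment grid (non-seasonal b ∈ {0.555, 1.110, 1.388, 2.221};
  δb/b_ref ∈ {0.2, 0.4, 0.6} × θ ∈ {0, 3, 6, 9}).

Phosphorus is converted to carbon with the Redfield ratio
C:N:P = 106:16:1 (1 mmol P = 1.273 g C).

## Worked example

```r
library(seapump)

p <- seasonal_attenuation(b_ref = 1.388, delta_b_frac = 0.6, theta = 0)
p
#> <seasonal_attenuation> b_ref=1.388 delta_b=0.8328 (60%) theta=0 months lambda=0.05/d

mean_A(p)                       # annual-mean sinking coefficient
#> 0.045 per day                 # vs lambda/b_ref = 0.036: seasonality is faster
equivalent_b(p)
#> 1.11                          # the constant b with the same mean sinking
martin_te(1.388)                # Martin-curve TE, 120 -> 1080 m
#> 0.047
range(sinking_speed(120, seq(0, 360, 0.1), -45, p))
#> 2.70 10.81                    # m/day at the export depth over the year
transit_time(120, 1080, sinking_coefficient(0.05, 1.388))
#> 61                            # days through the mesopelagic

# no-circulation column: the model must converge onto the Martin curve
out <- run_to_cycle(column_config(b = 1.388))
out
#> <annual_cycle> 8 years, converged (final drift 7.53e-05)
fl  <- rowMeans(out$monthly_flux[, 2, ])
fit_emergent_b(out$grid$interfaces, fl)$b
#> 1.388                         # emergent exponent = imposed exponent
fl[out$grid$i1080] / fl[out$grid$i120]
#> 0.0474                        # = martin_te(1.388): the analytic limit
```

The numbers mean: with 60 % seasonality the mean sinking coefficient rises
from 0.036 to 0.045 day⁻¹ (equivalent constant b drops from 1.388 to
1.110), and with circulation off the simulated flux profile fits the
Martin curve with the imposed exponent exactly — so any departure seen in
circulating runs is an emergent circulation effect, not numerics.

With circulation on (`smoke_config()`), the diagnosed global TE exceeds
the Martin-curve value, TE maps develop spatial structure that vanishes
when circulation is switched off, and seasonal runs raise TE and the
1080-m flux relative to the non-seasonal reference for every phase, most
strongly when the sinking-speed maximum coincides with the bloom (θ = 6).

## Experiments and CLI

```sh
Rscript inst/cli/seapump.R tables   --out out      # closed-form tables (CSV)
Rscript inst/cli/seapump.R run      --variant db0.6_th6 --out out
Rscript inst/cli/seapump.R grid     --out out      # all 16 variants (resumable)
Rscript inst/cli/seapump.R report   --out out      # comparison table vs reference
Rscript inst/cli/seapump.R fixtures --out out      # synthetic forcing + matrices
```

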