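# capturesim

Deterministic process models for the protein A capture step in monoclonal
antibody (mAb) downstream processing — the unit operation where clarified
cell culture fluid is loaded onto a protein A stationary phase, washed,
eluted at low pH and the phase regenerated. The package is aimed at
downstream-process engineers comparing stationary phases (membrane
adsorbers vs packed resins) and tuning the operating point: load flow rate,
feed titer and cleaning frequency.

## What it computes

* **Dynamic binding capacity** from breakthrough/fraction data:
  total DBC = V₀% · C₀ / Vₘ (last fraction with no detectable product) and
  DBC₁₀% = (V₁₀% − V₀) · C₀ / Vₘ (interpolated 10% breakthrough crossing,
  void-corrected); UV-threshold elution pooling (the 100–100 mAU rule).
* **Capacity vs residence time**: piecewise-linear interpolation over
  measured anchors, or a saturation fit
  DBC(τ) = d_max · τ / (k_half + τ).
* **Cycle model**: declarative recipes (phases in membrane volumes MV,
  flows in MV/min; duration = volume/flow), load volume from the
  80%-of-DBC₁₀% rule and the feed titer, buffer consumption, and average
  cycle time when regeneration runs only every k-th cycle:
  t̄(k) = ((k−1)·t_nr + t_full)/k.
* **Productivity**: PR = m_eluted / (Vₘ · t_c) in g·L⁻¹·h⁻¹, exactly
  invariant to device size; titer × flow sweeps, flow-rate optimization,
  regeneration-frequency curves, membrane-vs-resin comparison.
* **Quality metrics**: step yield and impurity log reduction values,
  LRV = log₁₀(c_feed / c_eluate).
* **Synthetic data**: Thomas-model breakthrough curves with closed-form
  V₁₀/DBC₁₀% oracles, single-cycle UV/pressure traces, and feeds drawn
  within reported impurity ranges — everything needed to test the pipeline
  without instrument exports.

## Worked example

```r
library(capturesim)

dev <- device("membrane-prototype", 1.2, kind = "membrane", bed_height_mm = 4)

# one bind-elute cycle at 3.12 g/L feed titer, loaded to 34.4 g per L of
# membrane (80% of the measured DBC10%), 94.7% step yield
bd <- cycle_breakdown(membrane_recipe(), dev, feed(3.12),
                      load_density_g_per_l = 34.4, yield = 0.947)
bd$total_time_min
#> [1] 9.605128
productivity(bd)$pr_g_per_l_h
#> [1] 203.4963
buffer_per_gram(bd, dev)
#> [1] 1.626925
```

A 9.6-minute cycle eluting 32.6 g of mAb per litre of membrane gives
~203 g·L⁻¹·h⁻¹ — roughly 14-fold the productivity of a packed protein A
resin running the same chemistry at a 100-minute cycle (compare with
`recipe_preset("resin")` and `compare_devices()`). Buffer use is
~1.6 L per gram of product.

The capacity/flow trade-off:

```r
anchors <- read_dbc_anchors(system.file("extdata", "dbc_anchors.csv",
                                        package = "capturesim"))
model <- dbc_rt_interpolator(anchors)
optimal_flow(10, c(3, 5, 10), model, membrane_recipe("sweep"), dev)$flow_mv_min
#> [1] 3
optimal_flow(1, c(3, 5, 10), model, membrane_recipe("sweep"), dev)$flow_mv_min
#> [1] 10
```

At high titer the load phase is short, so a slower flow with higher binding
capacity wins; at low titer the load phase dominates and the fastest flow
wins despite its lower capacity.

The numbered scripts under `analysis/` run the full workflow (breakthrough
simulation and DBC recovery, cycle reconstruction, residence-time fit,
productivity sweeps and regeneration-frequency curves, synthetic cycle
trace with quality tables) and write their tables under `results/`.

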