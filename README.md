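# bloomregime

Neural modelling of chlorophyll-a dynamics in regulated rivers whose
phytoplankton community shifts with water temperature.

In weir-regulated temperate rivers, the relationship between phytoplankton
biomass (chlorophyll-a, mg/m³) and its environmental drivers is not constant
through the year: cold seasons are dominated by diatoms whose growth is
phosphorus-limited, warm seasons by buoyant cyanobacteria whose blooms are
controlled mainly by water residence time — which, at a gated weir with fixed
surface elevation, is proxied by the discharge. A single regression model
fitted to all seasons blurs these regimes. `bloomregime` implements the
regime-resolved alternative for researchers and river managers working with
daily monitoring tables of water temperature (WT, °C), electrical
conductivity (EC, µS/cm), total nitrogen (TN, mg/L), total phosphorus
(TP, mg/L), weir discharge (Q, m³/s) and chlorophyll-a (CHLA, mg/m³):

1. **Regime partitioning** — 1-D K-means on WT (Lloyd iterations with
   k-means++ seeding and restarts), minimising
   E = Σₗ Σ_{xᵢ∈Cₗ} ‖xᵢ − μₗ‖², with clusters relabelled cold → warm.
2. **Per-regime neural regression** — one single-hidden-layer network per
   cluster: Hⱼ = Σᵢ xᵢWᵢⱼ + bⱼ, δ(Hⱼ) = tanh(Hⱼ), Ĉ = Σⱼ δ(Hⱼ)Wⱼₖ + bₖ,
   trained on min-max normalised inputs Xᵢ = (xᵢ − min xᵢ)/(max xᵢ − min xᵢ)
   by full-batch AdaGrad on the cost SSE = ½ Σ (Ĉᵢ − Cᵢ)², from Xavier
   initialisation (weights uniform on ±1/√fan-in, biases zero), with a
   seeded 70/30 train/test split and optional k-fold cross-validated
   hidden-size selection.
3. **Variable importance** — Garson partitioning of the connection weights:
   per hidden node, shares of |Wᵢⱼ·Wⱼₖ| across inputs, aggregated over nodes
   and normalised so Σ RIᵢ = 100%.
4. **Evaluation** — R² = 1 − Σ(Cᵢ−Ĉᵢ)²/Σ(Cᵢ−C̄)², RSR (RMSE over the SD of
   the observations) and APBIAS (absolute bias as a percent of the observed
   total), always on the concentration scale, with clustered-model test
   predictions pooled across clusters.
5. **Scenario analysis** — sweeps of discharge (optionally crossed with
   conductivity) through a trained warm-regime model to locate the
   *mitigation discharge*: the smallest Q at which the predicted bloom falls
   to 50% of the sweep maximum (or to an absolute target).
6. **Synthetic data** — a seeded generator with a known regime-dependent
   response (P-limited diatom regime, discharge-dominated cyanobacteria
   regime, switchable tributary conductivity effect), calibrated to the
   marginal statistics of a heavily monitored station downstream of a
   polluted tributary confluence, so the whole pipeline is testable without
   any field data.

## Worked example

```r
library(bloomregime)

sim  <- simulate_monitoring(goryung_config(n_days = 1825, seed = 1))
cfg  <- train_config(seed = 1)
fit1 <- fit_regime_models(sim$data, k = 1, hidden_size = 15, config = cfg, seed = 1)
fit3 <- fit_regime_models(sim$data, k = 3, hidden_size = 15, config = cfg,
                          seed = 1, split = fit1$split)

comparison_report(list("K=1" = fit1, "K=3" = fit3))
#> # A tibble: 4 × 6
#>   model set          n r_squared   rsr apbias_percent
#>   <chr> <chr>    <int>     <dbl> <dbl>          <dbl>
#> 1 K=1   training  1277     0.623 0.614           25.1
#> 2 K=1   testing    548     0.589 0.641           26.3
#> 3 K=3   training  1277     0.697 0.551           22.6
#> 4 K=3   testing    548     0.661 0.583           23.6
```

Partitioning by thermal regime lifts the pooled test R² from 0.589 to 0.661
and lowers both RSR and APBIAS: the three per-regime networks capture
relationships the single network averages away. The importance profiles say
why:

```r
importance_by_cluster(list(station = fit3)) |>
  tidyr::pivot_wider(names_from = variable, values_from = ri_percent)
#>   station    cluster    TP     Q    TN    WT    EC
#> 1 station          1  23.2  21.9  20.1  19.7  15.0
#> 2 station          2  17.8  27.4  17.3  17.9  19.6
#> 3 station          3  10.6  55.6  12.7  10.4  10.7
```

In the cold (diatom) cluster phosphorus leads; in the warm (cyanobacteria)
cluster discharge dominates at 55.6% — the residence-time control on summer
blooms. That makes discharge the management lever:

```r
res <- run_q_sweep(fit3, scenario_grid(q_values = seq(20, 600, by = 20),
                                       fixed_inputs = cluster_means(fit3, 3),
                                       cluster = 3))
res
#> Discharge sweep over 30 points (20-600 m3/s)
#> max Chl-a 36.67 mg/m3; criterion 50% of sweep maximum (threshold 18.34)
#> mitigation discharge: 240 m3/s
autoplot(res)
```

Holding the other drivers at the warm-cluster training means, predicted
chlorophyll-a peaks at 36.7 mg/m³ at the lowest discharge and falls to half
that once the weir releases 240 m³/s — the smallest grid discharge meeting
the 50%-of-maximum suppression criterion. `run_q_ec_grid()` repeats the
sweep over a conductivity range to show how much more water is needed when a
polluted tributary raises EC.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the package's main computation from scratch under the given seed:
it simulates five years of daily data, fits the non-clustered and 3-cluster
models on a common split, prints the comparison table, the per-cluster
importance profiles and both discharge scenarios, and writes the acceptance
JSON to `--out`.
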