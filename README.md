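# yoyrockfish

Spatiotemporal analysis of pelagic young-of-the-year (YOY) rockfish
(*Sebastes* spp.) catches from coastwide midwater-trawl surveys of the
California Current. The package turns haul-level catch tables into:

- **QC'd, station-assigned hauls** — exclusion ledgers, 10-km
  station association, pseudo-stations at cluster centroids, and
  climatology-station selection;
- **spatial climatologies** — station-level mean `ln(catch+1)`, per-year
  z-score anomaly fields, occurrence frequencies, fishery-group
  aggregations, and inverse-distance-weighted surfaces;
- **standardized regional indices** — per-region delta-GLM (hurdle)
  models of haul catches with year/depth/station/season factors, AIC
  covariate selection, and a lognormal-bias-corrected annual index;
- **shared trends** — dynamic factor analysis of the regions × years
  index matrix, `y_t = Z x_t + v_t`, `x_t = φ x_{t-1} + w_t` with
  `w_t ~ N(0, I)`, fitted by Kalman smoother + ECME over an 18-model grid
  (1–3 trends × equal/unequal diagonal R × shared/per-trend/fixed-1 φ),
  compared by AICc and Akaike weights, with varimax-rotated loadings and
  confidence intervals;
- **cross-checks** — PCA of complete-coverage years correlated against
  the DFA trends, and a 3-D NMDS of the fourth-root-transformed species
  matrix (Bray–Curtis) with a fitted latitude surface.

A synthetic-data generator (`simulate_survey`) reproduces the survey's
statistical structure — zero-inflated lognormal catches driven by two
latent AR(1) trends through a regional loadings matrix, the published
effort table with its missing-year gaps, and a latitude-graded 20-species
composition — with full ground truth, so every stage of the pipeline is
testable against known parameters. See the methods vignette
(`vignettes/methods.Rmd`) for the models, assumptions, calibration of the
synthetic world, and known limitations.

## Worked example

```r
library(yoyrockfish)
sim  <- simulate_survey(seed = 1)          # 3,689 hauls, 12 regions, 2001-2019
ann  <- tapply(scope_catch(sim$hauls), sim$hauls$year, mean)
range(ann)                                  # 2.5 to 391 fish/haul
pipe <- regional_index_pipeline(sim$hauls) # delta-GLM per region, z-scored
fits <- lapply(list(dfa_spec(1), dfa_spec(2), dfa_spec(3)),
               em_fit, data = pipe$matrix, n_starts = 4)
aicc_and_weights(fits)[, c("model", "k", "AICc", "delta_AICc", "weight")]
#>                                model  k     AICc delta_AICc     weight
#> m=2, R=diagonal-unequal, phi=shared 36 532.4623    0.00000 9.9927e-01
#> m=3, R=diagonal-unequal, phi=shared 46 546.9612   14.49887 7.1005e-04
#> m=1, R=diagonal-unequal, phi=shared 25 553.8442   21.38193 2.2733e-05
```

The 2-trend model wins by 14.5 AICc points over the 3-trend model —
matching the generating truth (`m_true = 2`). `rotate_loadings(fits[[2]])`
then gives varimax loadings whose central-coast block (rows 3–9 positive
on one trend) mirrors the generator's `Z_true`;
`vegan::protest(sim$truth$Z_true, rotate_loadings(fits[[2]])$Z)` scores
the match (Procrustes correlation ≈ 0.9 at this seed).

## Command line

`inst/scripts/yoy_cli.R` wraps the main stages:

```sh
Rscript inst/scripts/yoy_cli.R simulate    --seed 1 --out hauls.csv
Rscript inst/scripts/yoy_cli.R standardize --input hauls.csv --out index_matrix.csv
Rscript inst/scripts/yoy_cli.R dfa         --input index_matrix.csv --out comparison.csv
Rscript inst/scripts/yoy_cli.R assemblage  --input hauls.csv --out assemblage.json
```
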