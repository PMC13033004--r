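# isojuv

Stable-isotope resource-use estimation and juvenile-performance analysis
for lake fish surveys.

Littoral/pelagic fish polyphenisms hinge on whether juveniles can actually
make a living in each habitat. `isojuv` quantifies that from standard
survey data: bulk carbon and nitrogen stable isotopes of age-0 fish and of
reference taxa (mussels, snails, zooplankton), plankton-tow records, and
fish morphometrics. It implements:

- **Lipid normalization** of bulk δ¹³C: the invertebrate mass-balance
  correction δ¹³C_ex = δ¹³C_bulk + 6.3 (C:N − 4.2)/C:N, and the
  Kiljunen-type fish normalization δ¹³C_ex = δ¹³C_bulk + D(I + a/(1 + b/L))
  with L = 93/(1 + (0.246 C:N − 0.775)⁻¹), D = 7.018, I = 0.048, a = 3.90,
  b = 287.
- **A two-end-member mixing model**:
  %Planktonic = 100 (δ¹³C_consumer − δ¹³C_base2)/(δ¹³C_base1 − δ¹³C_base2),
  with pelagic mussels as the planktonic end-member and littoral snails as
  the benthic one, plus a baseline-validation step (taxon summaries,
  Tukey-family pairwise comparisons, and the ten-fold mussel-proxy
  adequacy ratio).
- **Tow volume and density estimation**: volume = n_nets π (d/2)² v t,
  zooplankton density in mg dry mass/m³, pooled larval density per m³.
- **The performance battery**: habitat × month ANOVA with ln(x+1) and
  arcsine-√ transforms, per-month Kruskal–Wallis with pairwise Wilcoxon
  compact-letter displays, ANCOVA of mass on length with Tukey-adjusted
  means at the grand-mean length, residual-mass condition, and
  Bartlett/Levene variance tests.
- **A forward synthetic-data generator** with known ground truth (true
  mixing fractions, density decline, growth allometry) so every stage is
  verifiable by parameter recovery.

## A worked example

```r
library(isojuv)
res <- run_pipeline(list(scenario = list(seed = 7), outdir = "report"))
res$headline
#> # A tibble: 10 × 2
#>    quantity                                value
#>    <chr>                                   <dbl>
#>  1 sl_excess_pelagic_sept_pct              15.9
#>  2 mass_excess_pelagic_sept_pct            39.2
#>  3 adj_mass_excess_littoral_pct            12.0
#>  4 june_july_density_factor                 4.25
#>  5 planktonic_june_mean_pct                88.0
#>  6 planktonic_july_mean_pct                78.1
#>  7 planktonic_august_mean_pct              73.1
#>  8 planktonic_september_mean_pct           74.3
#>  9 planktonic_september_pelagic_median_pct 87.6
#> 10 proxy_adequacy_ratio                     9.33
```

Reading the output: in this simulated survey, September pelagic juveniles
are 15.9% longer and 39.2% heavier on average than littoral ones, yet
littoral fish are 12.0% heavier than pelagic fish *of the same length*
(the ANCOVA-adjusted contrast) — fast growth and high length-specific
condition need not coincide. Zooplankton density fell 4.25-fold from June
to July. Mean %-planktonic tissue declines over the summer (88 → 74) as
juveniles shift toward benthic resources, while the September pelagic
median stays near 88%, and the mussel-proxy adequacy ratio (~9.3 here,
threshold 10) quantifies how safely mussels stand in for the planktonic
end-member. `report/` receives the tidy CSV tables, a run log recording
every interpreted-formula decision (delta ×1000 convention, fish-formula
parenthesization, clamping events), and a `config_echo.yaml` that re-runs
the analysis identically.

Individual stages are plain functions: `lipid_correct_fish()`,
`percent_planktonic()`, `summarize_baselines()`, `tow_volume()`,
`two_factor_anova()`, `condition_analysis()`, `generate_survey()`, and so
on; `read_survey_csv()`/`write_survey_csv()` enforce the four documented
CSV schemas in `survey_schemas` (see `inst/extdata/` for the published
summary tables used as generator defaults).

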