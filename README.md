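# invasim

Analysis pipeline for pulse-disturbance invasion experiments in bacterial
microcosms, for microbial ecologists studying how disturbance frequency and
resource abundance jointly decide whether an invader establishes.

The experimental template: resident *Pseudomonas fluorescens* populations in
static microcosms at three resource levels (100%/10%/1% King's medium B) are
disturbed every 1, 2, 4, 8 or 16 days by a 1% transfer into fresh medium
(99% mortality — a pulse disturbance of equal intensity at every frequency),
and invaded on days 4, 8 and 12 with a marked strain of either a
fast-growing "colonizer" morphotype (SM) or a slower, biofilm-forming
"competitor" (WS). At day 16, resident and invader colonies are counted by
morphotype (SM, WS, FS).

At the core is the relative-fitness ratio of invader proportional change,

```
v = x2 (1 - x1) / (x1 (1 - x2))
```

where the initial invader proportion averages the three invasion events,
`x1 = mean over t in {4,8,12} of I_t / (I_t + R_t)`, with unmeasured
resident densities `R_t` imputed from day-4 reference microcosms by
dividing out the disturbance survival fraction where the culture was in
fact undisturbed. Success is analysed as `log(v + 1)`; values above
`ln 2 ≈ 0.69` mean the invader increased in proportion. Around the
statistic sits the full inference battery — the disturbance × resource ×
invader-type interaction model, per-morphotype models with per-resource
slopes and 95% CIs, quadratic diversity/density models reduced by
likelihood-ratio selection, type III→II ANOVA, Bonferroni-adjusted marginal
comparisons — plus Simpson's diversity and log-density community summaries,
tidy-CSV plate-count io, a mechanistic serial-transfer simulator, and a
parametric generator with known truth for calibration.

## Worked example

```r
library(invasim)

sim <- simulate_experiment(seed = 42)        # 180 invaded + 45 day-4 microcosms
ft  <- compute_fitness_table(sim$counts, sim$day4_reference)
dplyr::select(ft[c(1, 91), ], microcosm_id, x1, x2, v, log_v_plus_1, increased)
#>   microcosm_id          x1       x2           v log_v_plus_1 increased
#> 1 high_d16_SM_r1 0.0000993 7.06e-11 0.000000711  0.000000711 FALSE
#> 2 low_d2_WS_r1   0.416     6.17e- 3 0.00871      0.00867     FALSE
```

The first microcosm is an undisturbed, resource-rich culture invaded by SM:
the invader entered at a frequency of about `1e-4` and was essentially gone
by day 16 (`v` near 0, score below 0.69 — invasion failed). Running the full
battery:

```r
report <- run_invasion_analysis(sim$counts, sim$day4_reference)
print(report)
#> Invasion analysis report ( 180 microcosms, 0 undefined v )
#> Three-way disturbance x resource x invader interaction: p = 1.05e-06 (significant)
#>
#>  SM invader per-resource disturbance slopes:
#>  resource       slope       ci_lo       ci_hi significant
#>       low -0.05684144 -0.09253889 -0.02114399        TRUE
#>    medium -0.02140280 -0.05710025  0.01429465       FALSE
#>      high  0.09107005  0.05537260  0.12676751        TRUE
#>
#>  WS invader per-resource disturbance slopes:
#>  resource       slope      ci_lo        ci_hi significant
#>       low -0.08067708 -0.1594020 -0.001952204        TRUE
#>    medium -0.16625775 -0.2449826 -0.087532873        TRUE
#>      high -0.26495477 -0.3436797 -0.186229890        TRUE
```

Slopes are per disturbance event over the 16-day experiment: disturbance
helps the colonizer under high resources (+0.09) and harms it under low
(−0.06), while it harms the competitor most under high resources (−0.26) —
the same disturbance regime is good or bad for an invader depending on
resources and its life history. `report_to_json()` serialises every ANOVA
table, slope and post-hoc comparison.

The numbered scripts under `analysis/` run the same sequence as a narrated
workflow (simulate → fitness → community → inference → calibration), writing
tables under `results/`.

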