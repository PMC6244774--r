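# oscillomark

Oscillatory brain activity as a biomarker of diffuse-glioma progression.

Preclinical work shows that neuronal activity accelerates glioma growth
through activity-dependent secretion of neuroligin-3 (NLGN3). oscillomark
implements the clinical analysis of that hypothesis as a tested R
pipeline, for neuro-oncology and clinical-neurophysiology researchers who
want to compute the biomarker on their own cohorts or audit every step of
the original analysis:

1. **Activity scores** — per-region broadband (0.5–48 Hz) MEG power
   (Welch PSD) is summarised into *peritumor* (regions overlapping the
   twice-dilated tumor mask, 3×3×3 box kernel), *global* (all 78 regions)
   and *non-tumor* activity, then z-scored across the cohort. The three
   means satisfy `R·global = k·peritumor + (R−k)·nontumor` exactly.
2. **NLGN3 association** — Kruskal–Wallis (midranks, tie-corrected) plus
   pairwise Mann–Whitney tests with *exact* small-sample p-values by
   enumeration of the U null distribution, reported as `min(U₁, U₂)`.
3. **Survival** — Cox proportional hazards fitted from the partial
   likelihood up (Breslow/Efron ties, safeguarded Newton–Raphson, Wald
   inference: HR = exp(β̂), CI = exp(β̂ ± 1.96·se)), Kaplan–Meier curves,
   median split.
4. **Validation** — leave-one-out Cox refits and a seeded 1000-shuffle
   permutation null for the Cox p-value with the add-one estimator
   `(1 + #{p_perm ≤ p_obs})/(B+1)`.
5. **Synthetic cohorts** — a generator for atlas volumes, ellipsoidal
   tumor masks, 1/f-plus-alpha region signals and Weibull
   proportional-hazards survival (default log-HR = ln 2.10 per SD of
   global activity), so the whole pipeline is testable end to end.

A 24-patient diffuse-glioma cohort (survival in weeks, progression
indicator, global-activity z-scores, NLGN3 tiers, clinical covariates) is
packaged as `glioma_cohort()`; the column dictionary is
`patient_column_dictionary()`.

## Worked example

```r
library(oscillomark)
coh <- glioma_cohort()

# Does global activity differ across NLGN3 expression tiers?
tiers <- split(coh$oba_global_z, coh$nlgn3_tier)
kruskal_wallis(tiers[c("low", "moderate", "high")])
#> H(2) = 11.13, p = 0.003822  [chi_square_approx; n = 12/6/3]
mann_whitney_u(tiers$high, tiers$moderate)
#> U = 1, p = 0.04762  [exact; n = 3/6]

# Does global activity predict progression-free survival?
cox_fit(coh$time_weeks, coh$event, cbind(global_z = coh$oba_global_z))
#> Cox proportional hazards (breslow ties): n = 24, events = 17
#>            coef     HR lower95 upper95     se     z      p
#> global_z 0.7435 2.1032  1.2166   3.636 0.2793 2.662 0.0078

# Is that association robust?
leave_one_out(coh$time_weeks, coh$event, coh$oba_global_z)
#> Leave-one-out: 24 refits, p in [0.0042, 0.0354]
permutation_null(coh$time_weeks, coh$event, coh$oba_global_z,
                 B = 1000, seed = 7)
#> Permutation null (B = 1000, seed = 7): observed p = 0.007767, empirical p = 0.006993
```

A hazard ratio of 2.10 per SD means each standard deviation of additional
global oscillatory power roughly doubles the instantaneous progression
hazard; lower activity predicts longer progression-free survival. The
exact Mann–Whitney p of 0.048 (high vs moderate tier, n = 3 vs 6) is
2 × P(U ≤ 1) = 4/84 under the enumerated null — a value the normal
approximation cannot produce at these sample sizes.

The `analysis/` directory holds the narrative workflow over the same
functions: `01_simulate.R` (synthetic end-to-end pipeline),
`02_nlgn3_association.R`, `03_survival_models.R` (including the ten
bivariate confounder models and Kaplan–Meier export) and
`04_validation.R`; each writes its tables under `results/`.

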