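# kneefatigue

Probabilistic fatigue modelling of medial knee cartilage under gait
loading.

## The problem

Running roughly doubles the peak load on the medial knee compared with
walking, yet runners are not at elevated risk of knee osteoarthritis.
`kneefatigue` is for biomechanists and tissue modellers who want to
quantify this puzzle at the tissue level: it estimates the compressive
strains that walking and running impose on the medial tibiofemoral
cartilage and converts daily walking/running distances into the
cumulative probability of structural cartilage failure over an adult
lifespan, with and without natural repair and load-induced adaptation.

## The model

Three stages, each exposed as ordinary R functions:

1. **Knee load reduction.** Joint moments become muscle forces via moment
   arms and PCSA weighting; the medial/lateral split of the axial force
   follows from a frontal-plane balance about the lateral contact point,
   `F_med = (M_add + F_ax d_lat) / (d_med + d_lat)`.
2. **Discrete-element contact.** A rigid two-arc femoral condyle is
   pressed into a bed of nonlinear springs (`sigma = -E ln(1 - eps)`,
   `eps = y/h`, `F = d^2 sum(sigma_i)`; 7,326 elements at d = 0.5 mm) on
   a concave tibial plateau; the flexion-axis height is solved so the
   total force matches the subject's peak medial force, yielding the
   strain field and its peak.
3. **Weibull fatigue with damage, repair and adaptation.** A strain-life
   power law `N_f = C (b eps)^-n` sets the fatigue life at `D/L` loading
   cycles per day; failure probability is
   `P_f(t) = 1 - exp[-(V/V_ref)(t/t_f)^(m/n)]`; repair competes through
   `P_fr = int Q_f (1 - P_r) dt` with `P_r = 1 - exp[-(t/t_r)^v]`;
   activities mix by Miner's rule; adaptation raises moduli, thickness
   and radii in SD steps until running's risk matches walking's.

A seeded synthetic cohort generator reproduces the summary statistics of
the 22-subject reference cohort (e.g. peak medial forces 2.90 +/- 0.55 BW
walking, 5.59 +/- 0.99 BW running), so the whole chain runs without the
original gait recordings. See the vignette
(`vignettes/cartilage-fatigue-model.Rmd`) for the full model account,
parameter meanings and calibration notes.

## Worked example

```r
library(kneefatigue)

cohort  <- generate_cohort(cohort_spec(n_subjects = 22, seed = 1))
strains <- cohort_strains(cohort, knee_geometry())
sprintf("mean peak strain: walk %.1f%%, run %.1f%%",
        100 * mean(strains$strain_walk), 100 * mean(strains$strain_run_stiff))
#> "mean peak strain: walk 23.7%, run 38.1%"

walk    <- cohort_failure_curves(cohort, scenario = "walk")
walkrun <- cohort_failure_curves(cohort, scenario = "walkrun")
cohort_report(walk, snapshot_age = 55, cutoffs = 0.2)
#> Cohort failure probabilities (with repair), n = 22
#>   at age 55: 0.186 +/- 0.271
#>   at horizon end: 0.186 +/- 0.271
#>   subjects >=0.2 at age 55: 6
cohort_report(walkrun, snapshot_age = 55, cutoffs = c(0.27, 0.89))
#> Cohort failure probabilities (with repair), n = 22
#>   at age 55: 0.923 +/- 0.207
#>   at horizon end: 0.923 +/- 0.207
#>   subjects >=0.27 at age 55: 21
#>   subjects >=0.89 at age 55: 19

time_to_failure(0.23, fatigue_params(), 5000)  # 10,000 steps/day
#> [1] 64.1

paired_t_test(strains$strain_run_stiff, strains$strain_walk,
              labels = c("run", "walk"))
#> Paired t-test (run vs walk, n = 22): t(21) = 10.741, p = 5.462e-10, dz = 2.290
```

Reading: walking 6 km/day leaves a mean lifetime failure probability of
about 19% once repair is included, while replacing half the walking with
running pushes it to 92% — running strains (38%) are far beyond walking
strains (24%), and fatigue life falls off as strain to the power -12.9.
At walking strain levels the model predicts about 64 years of 10,000
steps/day before failure is expected. `sweep_required_adaptation()` then
finds the adaptation magnitude at which running stops being riskier.

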