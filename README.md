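# dielkit

Temporal-activity analysis for camera-trap studies of sympatric wildlife.

Camera-trap surveys record *when* animals pass a camera as well as where.
For guilds of similar species — sympatric forest carnivores are the classic
case — the timing of activity is often the axis along which coexistence is
organised: two morphologically similar predators may avoid competition by
being active at different hours. dielkit provides the complete statistical
workflow for that question, aimed at field ecologists and analysts working
with detection tables exported from camera-trap databases:

1. **Independence filtering** — collapse photo bursts into independent
   events with the conventional 30-min rule (`independent_events()`), and
   standardise encounter rates to events per 100 camera-trap days
   (`capture_frequency()`).
2. **Circular density estimation** — fit the diel activity curve
   f̂(t) = (1/n) Σᵢ exp{κ cos(t − tᵢ)} / (2π I₀(κ)), a kernel density on
   the 24-h circle with a von Mises kernel and plug-in bandwidth
   (`fit_vonmises_kde()`).
3. **Activity level** — the mean-to-peak ratio â = 1/(2π max f̂), the
   fraction of the day the population is effectively active, with
   bootstrap confidence intervals (`activity_level()`) and Wald tests for
   differences among study sites (`compare_activity_levels()`).
4. **Activity-pattern classification** — nocturnal / diurnal /
   crepuscular / cathemeral (or compound labels), via a Poisson mixed
   model on per-camera period counts for well-sampled species (> 50
   events) or Manly design-I selection ratios against period availability
   for sparser ones (10–50), with species under 10 events excluded
   (`activity_pattern_report()`).
5. **Temporal overlap** — the coefficient Δ = ∫ min(f̂, ĝ), estimated by
   Δ̂₁ (grid integration, samples < 75) or Δ̂₄ (density-ratio form,
   ≥ 75), with smoothed-bootstrap 95% CIs and the conventional
   low (≤ 0.50) / moderate / high (> 0.75) categories
   (`estimate_overlap()`).
6. **Synthetic studies** — a generator with known ground truth
   (archetypal diel densities, three-site uneven-effort design, photo
   bursts) so the whole stack is testable without field data
   (`simulate_camera_study()`).

`run_pipeline()` drives everything from a YAML/list config and writes the
standard report tables (capture frequencies, period proportions, activity
levels, patterns, overlaps) plus density and overlap plots;
`inst/cli/dielkit.R` is a thin command-line wrapper over the same
functions. The methods vignette
(`vignettes/diel-activity-methods.Rmd`) documents the statistical choices
in detail.

## Worked example

```r
library(dielkit)

study  <- simulate_camera_study(study_config(seed = 42))  # ground-truthed study
events <- independent_events(study$detections, window_minutes = 30)
nrow(study$detections)  # 5508 photos
nrow(events)            # 1832 independent events

head(capture_frequency(events, study$deployments), 3)
#>   species site n_events rate rate_display
#> 4 civet A   DV      301 2.16         2.16
#> 5 civet A   LK      364 2.06         2.06
#> 6 civet A   TW      133 1.83         1.83

activity_pattern_report(events, study$deployments)
#>   species   n route           pattern statistic   p_value         details
#> 1    bear 265  glmm diurnal+nocturnal      26.3  1.97e-06 Wald chisq 2 df
#> 2 civet A 798  glmm         nocturnal     461.4 6.46e-101 Wald chisq 2 df
#> 3 civet B 465  glmm         nocturnal     249.3  7.45e-55 Wald chisq 2 df
#> 4 linsang 144  glmm         nocturnal      91.2  1.59e-20 Wald chisq 2 df
#> 5  marten 160  glmm           diurnal     102.5  5.60e-23 Wald chisq 2 df

th <- function(sp) to_radians(events$timestamp[events$species == sp])
estimate_overlap(th("civet A"), th("civet B"), n_boot = 1000, seed = 1)
#> overlap Dhat4 = 0.972 (high), 95% CI 0.914-0.970, n = 798/465, 1000 resamples
study$truth$true_overlap["civet A", "civet B"]   # 1 (identical generating density)

estimate_overlap(th("civet A"), th("marten"), n_boot = 1000, seed = 1)
#> overlap Dhat4 = 0.057 (low), 95% CI 0.036-0.093, n = 798/160, 1000 resamples
study$truth$true_overlap["civet A", "marten"]    # 0.048
```

Reading the output: the two "civet" species were generated from the same
nocturnal density, and the estimated overlap is high (Δ̂₄ = 0.97 against
a true value of 1 — KDE-based overlap estimators are biased slightly
downward at finite n). The nocturnal civet versus the diurnal marten gives
Δ̂₄ = 0.06: near-complete temporal separation. The "bear" species is
generated uniform over the day; under the default count-scale offset its
counts split 10:10:4 with the period lengths, hence the compound
`diurnal+nocturnal` label — use `offset = "day_period_hours"` for the
rate-scale comparison on which it is classified cathemeral (see the
methods vignette).

Note `events$timestamp` holds naive local clock time; all circular
statistics use `to_radians()` (midnight = 0, noon = π).

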