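# circavar

Intraindividual (day-to-day) variability of the circadian rhythm of
heart rate, from long-term wearable recordings.

Wrist wearables record heart rate by photoplethysmography for months.
Heart rate carries a strong ~24-h oscillation, so these recordings can
quantify how *stable* a person's circadian rhythm is — a candidate
wearable biomarker for circadian disruption in epilepsy and other
conditions. `circavar` implements the whole chain for analysts working
with such cohorts:

1. **Preprocessing** — linear interpolation of gaps < 8 h, splitting
   into runs at gaps ≥ 8 h, exclusion of participants without a run
   longer than 7 days, window-mean downsampling to a working grid.
2. **Rhythm extraction** — singular spectrum analysis per run
   (FFT-based Hankel products and a randomized truncated SVD for
   month-long runs), Fourier scoring of each component's central
   period, and selection of the component closest to 24 h, with
   sidebands within ±0.5 cycles/day re-absorbed so day-to-day timing
   wander is retained.
3. **Cycle properties** — instantaneous phase from the Hilbert
   transform's analytic signal; cycles split at phase troughs; per
   cycle the *period* (trough-to-trough duration, min), *acrophase*
   (clock time of zero phase, minutes-of-day), and *amplitude* (peak
   minus preceding trough magnitude, bpm).
4. **Summaries** — consecutive non-overlapping 7-cycle segments; per
   property, the mean of segment means (*intraindividual average*) and
   the mean of segment SDs (*intraindividual variability*); circular
   statistics for acrophase. Segment acrophase SDs of 34 and 59 min
   summarise to (34 + 59)/2 = 46.5 min.
5. **Cohort statistics** — Wilcoxon rank-sum (exact for small samples,
   midranks under ties) with Cohen's d; a 10 000-iteration random
   subsampling control for unbalanced groups; |z| > 3 outlier
   exclusion; Pearson correlation of variability with log10 seizure
   frequency; paired signed-rank comparison of seizure-containing vs
   seizure-free weeks.
6. **Synthetic cohorts** — a generator with per-cycle ground truth
   (jittered period with mean-reverting acrophase, truncated-normal
   amplitude, ultradian harmonics, AR(1) sensor noise, log-normal
   gaps, Poisson seizure diaries) so every stage is testable by
   parameter recovery.

## Worked example

```r
library(circavar)

cfg <- crhr_config(n_days = 35, sampling_interval_s = 60,
                   period_sd = 60, seed = 42)
sim <- generate_participant(cfg)
sim$series
#> <hr_series> sim-42: 50401 samples, 35.0 days, 60-s nominal interval

sd(sim$ground_truth$period_min)   # realized day-to-day period SD
#> [1] 76.0

m <- participant_metrics(sim$series, pipeline_config())
round(m$summary[, -(1:2)], 2)
#>   n_segments avg_period var_period avg_acrophase var_acrophase avg_amplitude var_amplitude
#> 1          4    1435.22      55.44        810.17         71.17          20.5           1.7
```

Reading the output: from four 7-cycle segments, this participant's
period averages ~1435 min with an intraindividual variability of
~55 min (the band-limited reconstruction attenuates the realized
76-min jitter), the rhythm peaks around 13:30 local (810 min) with
~71 min day-to-day timing variability, and the cycle peak-to-trough
amplitude averages 20.5 bpm — matching the generating 2 × 10 bpm.

Cohort-level: `generate_cohort()` + `run_pipeline()` produce
per-cycle/per-segment/summary tables, the group comparison, the
subsampling control, the seizure-frequency correlation and the paired
seizure-segment test, plus a manifest of per-stage attrition; see
`vignettes/circavar-methods.Rmd` for the method and its assumptions.

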