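# migstats

Nonlinear statistical analysis of single-cell migration trajectories.

## What this is for

Time-lapse tracking of crawling cells (amoebae, leukocytes, cytoplasts)
produces trajectories whose interesting content is not *where* the cell
went but *how*: are the per-frame move-steps serially correlated, and
over what time span?  Does displacement grow diffusively or
superdiffusively?  Is the step sequence regular or noisy?  Does an
electric field or a chemoattractant gradient bias the direction of
travel?  `migstats` answers these questions for cohorts of tracked
cells and tests every answer against shuffled-surrogate nulls, the way
the systems-biophysics literature on amoeboid migration does.

The package provides:

* **Trajectory ingest** — generic `track_id,frame,x,y` tables and
  TrackMate spot exports, with µm calibration and strict frame-gap
  validation.
* **Fluctuation statistics** — rmsf analysis of the move-step series
  (`F(l) ~ l^α`, α = 0.5 for uncorrelated steps) with a
  correlation-time estimate on a 25-s grid; time-averaged MSD with the
  anomalous-diffusion exponent β (1 = normal diffusion, 2 = ballistic);
  DFA-1 with the memory exponent γ (1.5 = memoryless Brownian class,
  1.5–2 = trend-reinforcing).
* **Approximate entropy** — Pincus ApEn (m = 2, r = 0.2 SD) with the
  82-window growing-length profile and a ≥300-point validity rule;
  C++ kernel, pinned to a naive oracle at 1e-12.
* **Kinematics** — displacement cosine against the stimulus axis,
  45°-sector histograms, intensity of response (mm), directionality
  ratio, average speed (µm/s).
* **Surrogates** — uniform permutation of position order
  (trajectory-level nulls) or step values (series-level nulls), value
  multiset preserved exactly.
* **Cohort statistics** — median/IQR, exact/approximate Wilcoxon
  rank-sum with signed Z, Kruskal–Wallis, KS normality gate, and a
  results table comparing nucleated vs enucleated cohorts on all eight
  metrics.
* **Synthetic motion** — ballistic, Brownian, persistent correlated
  walks (OU heading + OU speed, optional directional bias) and exact
  fractional Gaussian noise (Davies–Harte), so exponent estimators can
  be validated against known ground truth without any raw data.

## Worked example

A persistent walker with a 9-min persistence time, recorded like the
standard protocol (4,100 frames at 2 Hz), analysed end to end:

```r
library(migstats)

tr <- gen_persistent(walker_config("persistent", persistence_time = 540,
                                   seed = 42))
m  <- trajectory_metrics(tr)
round(m[, c("rmsf_alpha", "corr_time_min", "msd_beta", "dfa_gamma",
            "apen", "DR", "AS_um_s")], 4)
#>   rmsf_alpha corr_time_min msd_beta dfa_gamma   apen     DR AS_um_s
#> 1     1.0517        3.3333   1.9573    1.9939 0.1315 0.0755  1.4397

sh <- shuffle_series(step_series(tr), surrogate_spec(seed = 1))[[1]]
fit_scaling_exponent(rmsf_curve(sh), c(8, 512))$exponent  # 0.442
apen(sh)                                                  # 1.929
```

Reading the numbers: the step series is long-range correlated
(α ≈ 1.05 ≫ 0.5) with a correlation regime of ~3.3 min; the path is
strongly superdiffusive (β ≈ 1.96) with trend-reinforcing memory
(γ ≈ 1.99); the step sequence is regular (ApEn ≈ 0.13); and the cell
covers 1.44 µm/s while wandering (DR ≈ 0.08).  Shuffling the same
steps destroys all of it — α collapses to ≈ 0.44 and ApEn jumps to
≈ 1.93 — so none of that structure is a sampling accident.

## The analysis workflow

Numbered drivers under `analysis/` rebuild the full study on synthetic
cohorts and write their tables under `results/`:

1. `01_simulate.R` — four scenarios (no stimulus, galvanotaxis,
   chemotaxis, both) × two cell types × 25 walkers, written as generic
   track files, plus the per-scenario displacement-cosine summary.
2. `02_metrics.R` — the eight metrics per trajectory
   (`results/metrics.csv`) and the growing-window ApEn profile matrix.
3. `03_surrogates.R` — one shuffled surrogate per trajectory and the
   experimental-vs-shuffled contrast (α 1.08 → 0.49, β 1.96 → 1e-4,
   γ 1.99 → 0.51, ApEn 0.15 → 2.06 in the shipped run; all
   |Z| ≈ 17).
4. `04_cohort_stats.R` — the results-table comparison of the two cell
   types (null by construction here) and the Kruskal–Wallis test of
   cosines across scenarios.

Run them in order from the repository root with `Rscript`.

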